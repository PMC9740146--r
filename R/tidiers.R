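#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the ablation trace of a results bundle
#'
#' One row per ablation step: channel count, the channel removed to reach
#' the next step, accuracy, and wall-clock times.
#'
#' @param x An [auth_results()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.auth_results <- function(x, ...) {
  tibble::tibble(
    genuine_subject = x$genuine_subject,
    band = x$band,
    n_channels = x$steps$n_channels,
    removed = x$steps$removed,
    accuracy = x$steps$accuracy,
    train_time = x$steps$train_time,
    classify_time = x$steps$classify_time
  )
}

#' One-row summary of a results bundle
#'
#' @param x An [auth_results()].
#' @param ... Unused.
#' @return A tibble with the benchmark score, the minimum channel count
#'   within the 1-percentage-point tolerance, the accuracy at that count,
#'   and the top-ranked channel.
#' @export
glance.auth_results <- function(x, ...) {
  at_min <- x$steps$accuracy[match(x$min_channels, x$steps$n_channels)]
  tibble::tibble(
    genuine_subject = x$genuine_subject,
    band = x$band,
    benchmark_accuracy = x$benchmark_accuracy,
    min_channels = x$min_channels,
    accuracy_at_min = at_min,
    top_channel = x$ranking$channel[1],
    n_channels = max(x$steps$n_channels)
  )
}

#' Tidy a channel ranking
#'
#' @param x A [channel_ranking()].
#' @param ... Unused.
#' @return A tibble with `channel`, `importance`, `rank`.
#' @export
tidy.channel_ranking <- function(x, ...) {
  tibble::tibble(channel = x$channel, importance = x$importance,
                 rank = x$rank)
}

#' Plot an ablation accuracy curve
#'
#' Accuracy against the number of channels retained, with the full-montage
#' benchmark and the 1-percentage-point tolerance band.
#'
#' @param object An [auth_results()].
#' @param tolerance Percentage points shown below the benchmark (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auth_results <- function(object, tolerance = 1, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_channels, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = object$benchmark_accuracy,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = object$benchmark_accuracy - tolerance / 100,
      linetype = "dotted", colour = "firebrick"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$min_channels,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Channels retained", y = "Authentication accuracy",
      title = sprintf("Channel ablation: subject %s, %s band",
                      as.character(object$genuine_subject), object$band)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a channel importance ranking
#'
#' @param object A [channel_ranking()].
#' @param ... Unused.
#' @return A ggplot bar chart of importance fractions by channel.
#' @export
autoplot.channel_ranking <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = rev(df$channel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$channel)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Impurity importance (fraction)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot subject-averaged accuracy curves per band
#'
#' @param cr A [cohort_results()].
#' @param bands Bands to show (default: all present).
#' @return A ggplot object with one curve per band.
#' @export
plot_band_accuracy <- function(cr, bands = NULL) {
  present <- unique(vapply(cr, function(b) b$band, ""))
  if (is.null(bands)) bands <- present
  df <- dplyr::bind_rows(lapply(bands, function(b) {
    dplyr::mutate(average_band_accuracy(cr, b), band = b)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_channels, y = .data$accuracy,
                                   colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Channels retained", y = "Mean accuracy",
                  colour = "Band") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
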