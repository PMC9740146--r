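#' Construct a results bundle
#'
#' The record of one authentication run for one (genuine subject, band)
#' pair: full-montage benchmark score, impurity channel ranking, per-ablation
#' accuracies with training/classification times, and the hyperparameters
#' used.
#'
#' @param genuine_subject Subject treated as genuine.
#' @param band Band name.
#' @param ranking A [channel_ranking()].
#' @param steps An [ablate()] tibble, ordered by strictly decreasing
#'   `n_channels`; the first (full-montage) step defines the benchmark.
#' @param tuned_params Named list (or `model_params`) of the hyperparameters
#'   used.
#' @param tolerance Percentage-point tolerance for the minimum-channel
#'   criterion (default 1).
#' @return An `auth_results` object with fields `genuine_subject`, `band`,
#'   `benchmark_accuracy`, `ranking`, `steps`, `tuned_params`,
#'   `min_channels`.
#' @export
auth_results <- function(genuine_subject, band, ranking, steps, tuned_params,
                         tolerance = 1) {
  if (nrow(steps) == 0L) {
    abort("`steps` must contain at least one ablation record.",
          class = "eegauth_validation_error")
  }
  if (is.unsorted(rev(steps$n_channels), strictly = TRUE)) {
    abort("`steps` must be ordered by strictly decreasing channel count.",
          class = "eegauth_validation_error")
  }
  benchmark <- steps$accuracy[1]
  if (inherits(tuned_params, "model_params")) {
    tuned_params <- unclass(tuned_params)
    attributes(tuned_params) <- list(names = names(tuned_params))
  }
  structure(
    list(
      genuine_subject = genuine_subject,
      band = band,
      benchmark_accuracy = benchmark,
      ranking = ranking,
      steps = steps,
      tuned_params = tuned_params,
      min_channels = min_channels_before_drop(steps, benchmark, tolerance)
    ),
    class = "auth_results"
  )
}

#' @export
print.auth_results <- function(x, ...) {
  cat(sprintf(
    "<auth_results> subject %s, %s band: benchmark %.4f over %d channels; min channels within 1pp: %d\n",
    as.character(x$genuine_subject), x$band, x$benchmark_accuracy,
    max(x$steps$n_channels), x$min_channels
  ))
  invisible(x)
}

#' Run the full authentication and channel-reduction pipeline
#'
#' For one genuine-user hypothesis on one band's feature table: split
#' 80/10/10, binarize and SMOTE-rebalance training data, optionally tune the
#' forest on the validation split, compute the full-montage benchmark, rank
#' channels by boosted impurity importance, ablate channel by channel with
#' retraining, and assemble the results bundle.
#'
#' @param table A `feature_tbl` for one band (all subjects stacked).
#' @param genuine_subject Subject treated as genuine.
#' @param params A [model_params()]; ignored when `tune = TRUE`.
#' @param tune If `TRUE`, grid-search hyperparameters on the validation
#'   split first.
#' @param grids Grids for tuning (see [default_grids()]).
#' @param smote_k SMOTE neighbour count.
#' @param seed Integer seed driving the split, SMOTE, ranking and model
#'   fits.
#' @param tolerance Percentage-point tolerance for the minimum-channel
#'   criterion.
#' @return An [auth_results()] bundle.
#' @export
run_authentication <- function(table, genuine_subject,
                               params = model_params(n_trees = 50L),
                               tune = FALSE, grids = default_grids(),
                               smote_k = 5L, seed = 1L, tolerance = 1) {
  band <- attr(table, "band")
  if (is.null(band)) band <- NA_character_
  split <- split_dataset(table, seed = child_seed(seed, 11L))
  bsplit <- binarize_split(split, genuine_subject, k = smote_k,
                           seed = child_seed(seed, 12L))
  if (tune) {
    params <- tune_hyperparameters(bsplit$train, bsplit$validation,
                                   grids = grids, seed = child_seed(seed, 13L))
  } else {
    params$seed <- child_seed(seed, 13L)
  }
  ranking <- rank_channels(bsplit$train$X, bsplit$train$y,
                           seed = child_seed(seed, 14L),
                           genuine_subject = genuine_subject, band = band)
  steps <- ablate(bsplit, ranking, params)
  auth_results(
    genuine_subject = genuine_subject,
    band = band,
    ranking = ranking,
    steps = steps,
    tuned_params = params,
    tolerance = tolerance
  )
}

#' Collect results bundles into a cohort set
#'
#' @param bundles List of [auth_results()], at most one per
#'   (genuine subject, band) pair; all must share channel labels.
#' @return A `cohort_results` list.
#' @export
cohort_results <- function(bundles) {
  stopifnot(all(vapply(bundles, inherits, TRUE, "auth_results")))
  keys <- vapply(bundles, function(b) {
    paste(as.character(b$genuine_subject), b$band, sep = "\r")
  }, "")
  if (anyDuplicated(keys)) {
    abort("At most one bundle per (subject, band) pair.", class = "eegauth_validation_error")
  }
  labels <- lapply(bundles, function(b) sort(b$ranking$channel))
  if (length(unique(labels)) > 1L) {
    abort("All bundles must share the same channel labels.", class = "eegauth_validation_error")
  }
  structure(bundles, class = "cohort_results")
}
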