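#' Size of the exhaustive channel-subset search space
#'
#' The number of unordered channel subsets of an n-channel montage,
#' `sum_k C(n, k) = 2^n` — the count that makes exhaustive subset evaluation
#' infeasible (4,294,967,296 models for 32 channels) and motivates ranked
#' sequential ablation instead.
#'
#' @param n_channels Non-negative integer channel count.
#' @return `2^n_channels` as a double (exact for n <= 53).
#' @export
#' @examples
#' search_space_size(32)
search_space_size <- function(n_channels) {
  if (length(n_channels) != 1L || n_channels < 0 ||
      n_channels != round(n_channels)) {
    abort("`n_channels` must be a non-negative integer.", class = "eegauth_domain_error")
  }
  2^as.double(n_channels)
}

#' Construct a channel ranking
#'
#' @param importances Non-negative per-channel importance fractions; they are
#'   renormalized to sum to 1.
#' @param channels Channel labels, one per importance.
#' @param genuine_subject,band Provenance identifiers.
#' @return A `channel_ranking`: tibble with columns `channel`, `importance`,
#'   `rank`, sorted by descending importance (ties keep input order), plus
#'   `genuine_subject` and `band` attributes.
#' @export
channel_ranking <- function(importances, channels, genuine_subject = NA,
                            band = NA_character_) {
  stopifnot(length(importances) == length(channels))
  if (any(importances < 0)) {
    abort("Importances must be non-negative.", class = "eegauth_validation_error")
  }
  tot <- sum(importances)
  importances <- if (tot > 0) importances / tot else {
    rep(1 / length(importances), length(importances))
  }
  ord <- order(-importances)
  structure(
    tibble::tibble(
      channel = as.character(channels)[ord],
      importance = importances[ord],
      rank = seq_along(ord)
    ),
    genuine_subject = genuine_subject,
    band = band,
    class = c("channel_ranking", class(tibble::tibble()))
  )
}

#' Rank channels by gradient-boosted impurity importance
#'
#' Fits a gradient-boosted tree classifier on the balanced genuine/imposter
#' training set, reads per-feature impurity-gain importances, sums them
#' within each channel's column group, and renormalizes to fractions summing
#' to 1. A forest-impurity alternative (`method = "forest"`) is available
#' for comparison.
#'
#' @param X Balanced training matrix with channel-major
#'   `<channel>_<feature>` column names.
#' @param y Binary 0/1 labels.
#' @param seed Integer seed.
#' @param method `"xgboost"` (default) or `"forest"`.
#' @param nrounds Boosting rounds (default 50).
#' @param genuine_subject,band Provenance stored on the ranking.
#' @return A [channel_ranking()].
#' @export
rank_channels <- function(X, y, seed = 1L, method = c("xgboost", "forest"),
                          nrounds = 50L, genuine_subject = NA,
                          band = NA_character_) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    abort("Columns lack the <channel>_<feature> naming needed for channel grouping.",
          class = "eegauth_contract_error")
  }
  idx <- feature_column_index(colnames(X))
  channels <- unique(idx$channel)
  per_feature <- stats::setNames(numeric(ncol(X)), colnames(X))
  if (method == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
    # colsample < 1 spreads importance over redundant discriminative
    # channels instead of crediting only the first separating split
    booster <- with_seed(seed, xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = 6L, eta = 0.3,
        nthread = 1L, subsample = 1, colsample_bytree = 0.25,
        seed = as.integer(seed %% 2147483647)
      ),
      data = dtrain, nrounds = nrounds, verbose = 0
    ))
    imp <- xgboost::xgb.importance(model = booster)
    per_feature[imp$Feature] <- imp$Gain
  } else {
    fit <- ranger::ranger(
      x = X, y = factor(y, levels = c(0L, 1L)), num.trees = nrounds,
      importance = "impurity", splitrule = "gini",
      seed = seed, num.threads = 1L, verbose = FALSE
    )
    per_feature[names(fit$variable.importance)] <- fit$variable.importance
  }
  by_channel <- vapply(channels, function(ch) {
    sum(per_feature[idx$column[idx$channel == ch]])
  }, 0)
  channel_ranking(by_channel, channels, genuine_subject = genuine_subject,
                  band = band)
}

#' Sequential channel ablation with retraining
#'
#' Starting from the full montage, repeatedly drops every feature column of
#' the lowest-ranked remaining channel from both the training and test
#' matrices, retrains the random forest with fixed hyperparameters, and
#' records accuracy and wall-clock times — one record per channel count from
#' the full montage down to a single channel. Removal order follows the one
#' initial ranking (no per-step re-ranking by default).
#'
#' @param bsplit A [binarize_split()] result with all channels present.
#' @param ranking A [rank_channels()] result covering every channel.
#' @param params A [model_params()] (the tuned, thereafter fixed,
#'   hyperparameters).
#' @param rerank If `TRUE`, the remaining channels are re-ranked after every
#'   removal (experimental variant; the default single ranking mirrors the
#'   one stored impurity score list of the results file).
#' @param seed Seed used for re-ranking fits when `rerank = TRUE`.
#' @return An `ablation_steps` tibble: `n_channels`, `channels_used`
#'   (list-column of labels), `removed` (label dropped to reach the *next*
#'   step, `NA` for the last), `accuracy`, `train_time`, `classify_time`;
#'   ordered by strictly decreasing `n_channels`.
#' @export
ablate <- function(bsplit, ranking, params, rerank = FALSE, seed = 1L) {
  stopifnot(inherits(bsplit, "binarized_split"),
            inherits(ranking, "channel_ranking"))
  if (!inherits(params, "model_params")) {
    abort("`params` must be tuned `model_params` before ablation.",
          class = "eegauth_contract_error")
  }
  idx <- feature_column_index(colnames(bsplit$train$X))
  all_channels <- unique(idx$channel)
  if (!setequal(ranking$channel, all_channels)) {
    abort("Ranking does not cover the split's channels.", class = "eegauth_contract_error")
  }
  current <- ranking$channel            # descending importance
  records <- vector("list", length(all_channels))
  for (step in seq_along(all_channels)) {
    keep_cols <- idx$column[idx$channel %in% current]
    Xtr <- bsplit$train$X[, keep_cols, drop = FALSE]
    Xte <- bsplit$test$X[, keep_cols, drop = FALSE]
    model <- train_classifier(Xtr, bsplit$train$y, params)
    acc <- evaluate_accuracy(model, Xte, bsplit$test$y)
    records[[step]] <- tibble::tibble(
      n_channels = length(current),
      channels_used = list(current),
      removed = NA_character_,
      accuracy = as.numeric(acc),
      train_time = model$train_time,
      classify_time = attr(acc, "classify_time")
    )
    if (length(current) > 1L) {
      if (rerank) {
        sub_rank <- rank_channels(Xtr, bsplit$train$y, seed = seed)
        current <- sub_rank$channel
      }
      drop_ch <- current[length(current)]
      records[[step]]$removed <- drop_ch
      current <- current[-length(current)]
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("ablation_steps", class(out))
  out
}

#' Minimum montage size before an accuracy drop
#'
#' Scans the ablation records from the full montage downward and returns the
#' smallest channel count `n` such that every record with count `>= n` keeps
#' accuracy within `tolerance` percentage points of the benchmark. Returns 1
#' when no record violates the tolerance.
#'
#' @param records An [ablate()] result (or any tibble with `n_channels` and
#'   `accuracy` ordered by decreasing `n_channels`).
#' @param benchmark Benchmark accuracy fraction (the full-montage score).
#' @param tolerance Allowed loss in percentage points (default 1).
#' @return Integer channel count.
#' @export
#' @examples
#' recs <- tibble::tibble(n_channels = 5:1,
#'                        accuracy = c(0.9, 0.9, 0.895, 0.85, 0.8))
#' min_channels_before_drop(recs, benchmark = 0.9)  # 3
min_channels_before_drop <- function(records, benchmark, tolerance = 1) {
  if (is.null(records) || nrow(records) == 0L) {
    abort("No ablation records supplied.", class = "eegauth_validation_error")
  }
  if (is.unsorted(rev(records$n_channels), strictly = TRUE)) {
    abort("Records must be ordered by strictly decreasing channel count.",
          class = "eegauth_validation_error")
  }
  ok <- records$accuracy >= benchmark - tolerance / 100
  first_bad <- which(!ok)[1]
  if (is.na(first_bad)) return(1L)
  if (first_bad == 1L) return(as.integer(records$n_channels[1]))
  as.integer(records$n_channels[first_bad - 1L])
}
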