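#' Split a feature table into train / validation / test
#'
#' Per-subject stratified random assignment: each subject's windows are
#' shuffled and allocated 80/10/10 by default, with floor counts for the
#' validation and test splits and the remainder going to training. The
#' default random window-level split deliberately ignores window overlap
#' (neighbouring windows can straddle splits); `method = "blocks"` instead
#' assigns contiguous window segments per subject for leakage-controlled
#' experiments.
#'
#' @param table A `feature_tbl` (or any data frame with a `subject` column).
#' @param fractions Length-3 numeric summing to 1: train, validation, test
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed; splits are deterministic in it.
#' @param method `"random"` (default) or `"blocks"`.
#' @return A `split_set`: list with elements `train`, `validation`, `test`
#'   (row-disjoint tibbles whose union is the input) plus `fractions` and
#'   `seed`.
#' @export
split_dataset <- function(table, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          method = c("random", "blocks")) {
  method <- match.arg(method)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three non-negative numbers summing to 1.",
          class = "eegauth_validation_error")
  }
  counts <- table(table$subject)
  if (any(counts < 10L)) {
    abort("Every subject needs at least 10 rows to split.",
          class = "eegauth_validation_error")
  }
  assign_split <- function(n) {
    n_val <- floor(fractions[2] * n)
    n_test <- floor(fractions[3] * n)
    c(rep("train", n - n_val - n_test), rep("validation", n_val),
      rep("test", n_test))
  }
  groups <- split(seq_len(nrow(table)), table$subject)
  labels <- character(nrow(table))
  with_seed(seed, {
    for (rows in groups) {
      tags <- assign_split(length(rows))
      perm <- if (method == "random") sample(length(rows)) else seq_along(rows)
      # for blocks: contiguous leading segment trains, then validation, test
      labels[rows[perm]] <- tags
    }
  })
  keep_attrs <- function(rows) {
    sub <- dplyr::slice(tibble::as_tibble(table), rows)
    if (inherits(table, "feature_tbl")) {
      sub <- new_feature_tbl(sub, attr(table, "channel_labels"),
                             attr(table, "band"))
    }
    sub
  }
  structure(
    list(
      train = keep_attrs(which(labels == "train")),
      validation = keep_attrs(which(labels == "validation")),
      test = keep_attrs(which(labels == "test")),
      fractions = fractions,
      seed = as.integer(seed)
    ),
    class = "split_set"
  )
}

#' Binarize subject labels for a genuine-user hypothesis
#'
#' The claimed genuine subject's rows become 1, every other subject's 0 —
#' the verification (not identification) framing: with 12 equally
#' represented subjects this yields a 1:11 genuine-to-imposter ratio.
#'
#' @param labels Vector of subject identifiers.
#' @param genuine_subject The identifier to mark genuine; must be present.
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' binarize_labels(c(1, 1, 2, 3), genuine_subject = 1)
binarize_labels <- function(labels, genuine_subject) {
  if (!genuine_subject %in% labels) {
    abort(sprintf("Subject '%s' is absent from the labels.",
                  as.character(genuine_subject)),
          class = "eegauth_key_error")
  }
  as.integer(labels == genuine_subject)
}

#' SMOTE: synthetic minority over-sampling
#'
#' Upsamples the minority class to exactly the majority count. Each synthetic
#' row is a convex combination `x + u * (x_nn - x)` of a minority row `x` and
#' one of its `k` nearest minority neighbours (Euclidean distance), with `u`
#' uniform on `[0, 1]`. Original rows are preserved verbatim and come first;
#' an already balanced input is returned unchanged.
#'
#' @param X Numeric feature matrix (rows are samples).
#' @param y Binary 0/1 label vector, one per row of `X`.
#' @param k Neighbour count (default 5); the minority class must have more
#'   than `k` members.
#' @param seed Integer seed.
#' @param scale_features If `TRUE`, neighbours are found in z-scored feature
#'   space (synthesis still happens in the original space). Default `FALSE`:
#'   the downstream tree ensembles are scale-invariant.
#' @return List with elements `X` and `y`, balanced 50/50.
#' @export
smote_upsample <- function(X, y, k = 5L, seed = 1L, scale_features = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  n_syn <- abs(n0 - n1)
  Xmin <- X[y == minority, , drop = FALSE]
  n_min <- nrow(Xmin)
  if (n_min <= k) {
    abort(sprintf(
      "Minority class has %d members but k = %d; lower `k` below the minority count.",
      n_min, k
    ), class = "eegauth_parameter_error")
  }
  Xdist <- if (scale_features) {
    sds <- apply(Xmin, 2L, stats::sd)
    scale(Xmin, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  } else {
    Xmin
  }
  d <- as.matrix(stats::dist(Xdist))
  diag(d) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  synth <- with_seed(seed, {
    base_idx <- sample.int(n_min, n_syn, replace = TRUE)
    nn_pick <- nn[cbind(base_idx, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    Xmin[base_idx, , drop = FALSE] +
      u * (Xmin[nn_pick, , drop = FALSE] - Xmin[base_idx, , drop = FALSE])
  })
  list(
    X = rbind(X, synth),
    y = c(y, rep(minority, n_syn))
  )
}

# numeric feature matrix + subject labels from a feature table
feature_matrix <- function(ft) {
  cols <- setdiff(names(ft), c("subject", "window"))
  X <- as.matrix(tibble::as_tibble(ft)[cols])
  storage.mode(X) <- "double"
  X
}

#' Binarize a split for one genuine-user hypothesis and rebalance training
#'
#' Applies [binarize_labels()] to all three splits and SMOTE to the training
#' split only; validation and test stay untouched and imbalanced, mirroring
#' real verification where only enrolment data can be augmented.
#'
#' @param split A [split_dataset()] result.
#' @param genuine_subject Subject treated as genuine.
#' @param k SMOTE neighbour count.
#' @param seed Integer seed for SMOTE.
#' @param scale_features Passed to [smote_upsample()].
#' @return A `binarized_split`: list with `train`, `validation`, `test`
#'   (each a list with matrix `X` and 0/1 `y`), `genuine_subject`, and
#'   `balanced = TRUE`.
#' @export
binarize_split <- function(split, genuine_subject, k = 5L, seed = 1L,
                           scale_features = FALSE) {
  stopifnot(inherits(split, "split_set"))
  part <- function(ft) {
    list(X = feature_matrix(ft),
         y = binarize_labels(ft$subject, genuine_subject))
  }
  train <- part(split$train)
  train <- smote_upsample(train$X, train$y, k = k, seed = seed,
                          scale_features = scale_features)
  structure(
    list(
      train = train,
      validation = part(split$validation),
      test = part(split$test),
      genuine_subject = genuine_subject,
      balanced = TRUE
    ),
    class = "binarized_split"
  )
}
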