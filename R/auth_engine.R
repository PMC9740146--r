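#' Random-forest hyperparameters
#'
#' @param n_trees Number of trees (default 100).
#' @param max_depth Maximum tree depth; `Inf` (default) grows unrestricted
#'   trees.
#' @param min_samples_split Minimum node size eligible for splitting
#'   (default 2).
#' @param feature_subsample Fraction of features tried per split, in
#'   `(0, 1]`; `NULL` (default) uses the conventional `sqrt(p)` rule.
#' @param seed Integer seed making the fit deterministic.
#' @return A `model_params` object.
#' @export
model_params <- function(n_trees = 100L, max_depth = Inf,
                         min_samples_split = 2L, feature_subsample = NULL,
                         seed = 1L) {
  if (n_trees < 1L || min_samples_split < 1L) {
    abort("Counts must be >= 1.", class = "eegauth_parameter_error")
  }
  if (!is.null(feature_subsample) &&
      (feature_subsample <= 0 || feature_subsample > 1)) {
    abort("`feature_subsample` must lie in (0, 1].", class = "eegauth_parameter_error")
  }
  if (!(is.infinite(max_depth) || (max_depth >= 1 && max_depth == round(max_depth)))) {
    abort("`max_depth` must be a positive integer or Inf.", class = "eegauth_parameter_error")
  }
  structure(
    list(
      n_trees = as.integer(n_trees), max_depth = max_depth,
      min_samples_split = as.integer(min_samples_split),
      feature_subsample = feature_subsample, seed = as.integer(seed)
    ),
    class = "model_params"
  )
}

#' Default hyperparameter grids
#'
#' Grids centred on the library defaults, spanning small/medium/large
#' ensembles, shallow/deep/unlimited trees and two node-size settings.
#'
#' @return Named list of candidate value vectors.
#' @export
default_grids <- function() {
  list(
    n_trees = c(50, 100, 200),
    max_depth = c(8, 16, Inf),
    min_samples_split = c(2, 8)
  )
}

#' Train the genuine/imposter random forest
#'
#' Fits a bagged ensemble of Gini-impurity decision trees on a balanced
#' binarized training set. The fit is deterministic given `params$seed`
#' (single-threaded).
#'
#' @param X Numeric training matrix (rows = windows, columns =
#'   channel-major features).
#' @param y Binary 0/1 labels.
#' @param params A [model_params()].
#' @return A `trained_model`: the fitted ensemble, its params, the ordered
#'   fit-time feature columns, and the training wall-clock time in seconds
#'   (`train_time`).
#' @export
train_classifier <- function(X, y, params = model_params()) {
  stopifnot(inherits(params, "model_params"))
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) {
    abort("Training labels contain a single class.", class = "eegauth_validation_error")
  }
  if (!all(is.finite(X))) {
    abort("Training matrix contains non-finite values.", class = "eegauth_validation_error")
  }
  mtry <- if (is.null(params$feature_subsample)) {
    max(1L, floor(sqrt(ncol(X))))
  } else {
    max(1L, floor(params$feature_subsample * ncol(X)))
  }
  t0 <- proc.time()[["elapsed"]]
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0L, 1L)),
    num.trees = params$n_trees,
    mtry = mtry,
    min.node.size = params$min_samples_split,
    max.depth = if (is.infinite(params$max_depth)) 0L else params$max_depth,
    splitrule = "gini",
    seed = params$seed,
    num.threads = 1L,
    verbose = FALSE
  )
  structure(
    list(
      fit = fit,
      params = params,
      feature_columns = colnames(X),
      train_time = proc.time()[["elapsed"]] - t0
    ),
    class = "trained_model"
  )
}

#' Authentication accuracy on a held-out set
#'
#' Fraction of test windows whose genuine/imposter prediction (ensemble
#' majority vote) matches the true label. The classification wall-clock time
#' is attached as attribute `"classify_time"`.
#'
#' @param model A [train_classifier()] result.
#' @param X Test matrix; columns must match the fit-time columns in order.
#' @param y True 0/1 labels.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, X, y) {
  stopifnot(inherits(model, "trained_model"))
  X <- as.matrix(X)
  if (!identical(colnames(X), model$feature_columns)) {
    abort("Test columns do not match the model's fit-time feature columns.",
          class = "eegauth_contract_error")
  }
  t0 <- proc.time()[["elapsed"]]
  # ranger resolves split-vote ties by RNG draw; seed it so evaluation is a
  # pure function of (model, data)
  pred <- with_seed(model$params$seed,
                    predict(model$fit, data = X, num.threads = 1L)$predictions)
  acc <- mean(as.integer(as.character(pred)) == as.integer(y))
  attr(acc, "classify_time") <- proc.time()[["elapsed"]] - t0
  acc
}

#' Exhaustive grid search for forest hyperparameters
#'
#' Fits one forest per point of the Cartesian grid on the (balanced)
#' training set, scores authentication accuracy on the validation set, and
#' returns the arg-max. Ties break to the first-encountered grid point, with
#' the grid enumerated in the order given (first parameter varying fastest).
#'
#' @param train,validation Lists with elements `X` and `y` (e.g. from
#'   [binarize_split()]).
#' @param grids Named list of candidate values (see [default_grids()]);
#'   names must be `model_params()` arguments.
#' @param seed Seed fixed into every candidate fit.
#' @return The winning [model_params()], with attributes `n_fits` (number of
#'   fits performed) and `scores` (tibble of every grid point's validation
#'   accuracy).
#' @export
tune_hyperparameters <- function(train, validation, grids = default_grids(),
                                 seed = 1L) {
  if (length(grids) == 0L || any(lengths(grids) == 0L)) {
    abort("`grids` must contain at least one non-empty parameter list.",
          class = "eegauth_parameter_error")
  }
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    args <- as.list(grid[i, , drop = FALSE])
    args$seed <- seed
    params <- do.call(model_params, args)
    model <- train_classifier(train$X, train$y, params)
    as.numeric(evaluate_accuracy(model, validation$X, validation$y))
  }, 0)
  best <- which.max(scores)
  args <- as.list(grid[best, , drop = FALSE])
  args$seed <- seed
  out <- do.call(model_params, args)
  attr(out, "n_fits") <- nrow(grid)
  attr(out, "scores") <- dplyr::bind_cols(
    tibble::as_tibble(grid), tibble::tibble(accuracy = scores)
  )
  out
}

#' Full-montage benchmark accuracy
#'
#' Trains on every channel's features and evaluates on the held-out test
#' set: the reference score that channel ablation is judged against.
#'
#' @param bsplit A [binarize_split()] result.
#' @param params A [model_params()].
#' @return Accuracy fraction with attributes `train_time` and
#'   `classify_time` (seconds).
#' @export
benchmark_full_channels <- function(bsplit, params = model_params()) {
  stopifnot(inherits(bsplit, "binarized_split"))
  model <- train_classifier(bsplit$train$X, bsplit$train$y, params)
  acc <- evaluate_accuracy(model, bsplit$test$X, bsplit$test$y)
  out <- as.numeric(acc)
  attr(out, "train_time") <- model$train_time
  attr(out, "classify_time") <- attr(acc, "classify_time")
  out
}
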