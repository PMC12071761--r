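#' Configure the ordered-target-statistic encoder
#'
#' @param smoothing_a Positive smoothing coefficient `a`.
#' @param prior_p Prior value `p`; defaults (at encode time) to the global
#'   mean of the targets.
#' @param permutation_seed Seed for the random processing order.
#' @return An `ordered_ts_config` list.
#' @export
ordered_ts_config <- function(smoothing_a = 1, prior_p = NULL,
                              permutation_seed = 1) {
  stopifnot(smoothing_a > 0)
  structure(list(smoothing_a = smoothing_a, prior_p = prior_p,
                 permutation_seed = as.integer(permutation_seed)),
            class = "ordered_ts_config")
}

#' Ordered target statistics for a categorical feature
#'
#' Leakage-free target encoding: the samples are processed in a seeded
#' random permutation, and sample `k` is encoded as
#' `(sum of targets of earlier samples with the same category + a p) /
#'  (count of earlier samples with the same category + a)`.
#' Only samples preceding `k` in the permutation contribute, so an
#' encoding never sees its own target (the device that makes ordered
#' boosting unbiased). A sample whose category has no earlier occurrence
#' encodes to the prior `p`.
#'
#' @param category_values Vector of categorical values.
#' @param targets Numeric targets of equal length.
#' @param config An [ordered_ts_config()].
#' @param permutation Optional explicit processing order (a permutation of
#'   `seq_along(targets)`); overrides the seeded draw, useful for testing.
#' @return Numeric encodings in the original sample order.
#' @examples
#' ordered_target_statistic(c("A", "A"), c(1, 0),
#'                          ordered_ts_config(smoothing_a = 1, prior_p = 0.5),
#'                          permutation = 1:2) # 0.5 then (1 + 0.5)/(1 + 1)
#' @export
ordered_target_statistic <- function(category_values, targets,
                                     config = ordered_ts_config(),
                                     permutation = NULL) {
  stopifnot(length(category_values) == length(targets))
  n <- length(targets)
  a <- config$smoothing_a
  p <- config$prior_p %||% mean(targets)
  if (is.null(permutation)) {
    permutation <- with_preserved_seed(config$permutation_seed, sample.int(n))
  }
  stopifnot(length(permutation) == n, all(sort(permutation) == seq_len(n)))
  cat_chr <- as.character(category_values)
  sums <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  out <- numeric(n)
  for (k in permutation) {
    key <- cat_chr[k]
    s <- get0(key, envir = sums, ifnotfound = 0)
    m <- get0(key, envir = counts, ifnotfound = 0)
    out[k] <- (s + a * p) / (m + a)
    assign(key, s + targets[k], envir = sums)
    assign(key, m + 1, envir = counts)
  }
  out
}

#' Configure the boosted-tree classifier
#'
#' @param iterations Number of boosting rounds (trees per class).
#' @param depth Per-tree depth.
#' @param learning_rate Shrinkage in `(0, 1]`.
#' @param seed Integer seed for the training run.
#' @return A `boost_config` list.
#' @export
boost_config <- function(iterations = 500, depth = 6, learning_rate = 0.1,
                         seed = 1) {
  stopifnot(iterations >= 1, learning_rate > 0, learning_rate <= 1, depth >= 1)
  structure(list(iterations = as.integer(iterations), depth = as.integer(depth),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "boost_config")
}

#' Fit a multiclass gradient-boosted decision-tree ensemble
#'
#' Seeded, single-threaded softprob gradient boosting over shallow trees —
#' the strong classifier stage of the pipeline. The ensemble machinery is
#' delegated to xgboost behind this fixed contract; the
#' ordered-target-statistic encoder ([ordered_target_statistic()]) is
#' implemented natively and available for categorical features (the default
#' pipeline's discriminant scores are continuous, so it is not wired in).
#'
#' @param X Numeric feature matrix.
#' @param y Class labels; at least two classes.
#' @param config A [boost_config()].
#' @return A `boosted_model` (booster handle, class levels, config).
#' @export
fit_boosted <- function(X, y, config = boost_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L,
                                 nthread = 1)
  booster <- with_preserved_seed(config$seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes),
                  max_depth = config$depth,
                  eta = config$learning_rate,
                  # exact greedy splitting: thresholds at midpoints between
                  # consecutive training values, which matters when a
                  # discriminant collapses each training class to a point
                  tree_method = "exact",
                  nthread = 1,
                  seed = config$seed,
                  verbosity = 0),
    data = dtrain,
    nrounds = config$iterations,
    verbose = 0
  ))
  structure(list(booster = booster, classes = classes, config = config),
            class = "boosted_model")
}

#' Predict with a boosted ensemble
#'
#' @param model A `boosted_model` from [fit_boosted()].
#' @param X Numeric feature matrix.
#' @return A list with `class` (predicted labels; ties to the lowest class
#'   index) and `prob` (n x K matrix, rows summing to 1).
#' @export
predict_boosted <- function(model, X) {
  X <- as.matrix(X)
  pr <- predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  K <- length(model$classes)
  if (is.null(dim(pr))) pr <- matrix(pr, ncol = K, byrow = TRUE)
  pr <- pr / rowSums(pr)      # booster works in float32; renormalize rows
  colnames(pr) <- model$classes
  list(class = model$classes[max.col(pr, ties.method = "first")],
       prob = pr)
}
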