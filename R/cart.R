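#' Configure the CART classifier
#'
#' Safeguards for recursive Gini splitting and cost-complexity pruning.
#'
#' @param gini_split_threshold Stop splitting a node once its Gini impurity
#'   falls below this value.
#' @param min_samples_split Minimum samples a node needs to be split.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param cv_folds_for_pruning Folds for cross-validated subtree selection.
#' @param seed Seed for the pruning cross-validation split.
#' @return A `cart_config` list.
#' @export
cart_config <- function(gini_split_threshold = 0.01, min_samples_split = 2,
                        max_depth = 20, cv_folds_for_pruning = 5, seed = 1) {
  stopifnot(gini_split_threshold > 0, min_samples_split > 0, max_depth > 0,
            cv_folds_for_pruning > 0)
  structure(list(gini_split_threshold = gini_split_threshold,
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = as.integer(max_depth),
                 cv_folds_for_pruning = as.integer(cv_folds_for_pruning),
                 seed = as.integer(seed)),
            class = "cart_config")
}

#' Gini impurity of a node
#'
#' `1 - sum_k p_k^2` over class proportions; 0 for a pure node and at most
#' `1 - 1/K` for `K` classes.
#'
#' @param class_counts Non-negative per-class counts, positive total.
#' @return The Gini impurity.
#' @examples
#' gini_index(c(10, 0, 0, 0, 0)) # 0: pure
#' gini_index(c(1, 1, 1, 1, 1))  # 0.8: uniform over 5 classes
#' @export
gini_index <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class count", call. = FALSE)
  total <- sum(class_counts)
  if (total <= 0) stop("all-zero class counts", call. = FALSE)
  1 - sum((class_counts / total)^2)
}

#' Best single Gini split of a node
#'
#' Exhaustive search over every feature and every midpoint between
#' consecutive distinct sorted values, minimizing the sample-weighted child
#' Gini `(n_L Gini_L + n_R Gini_R) / n`. Ties are broken by the lowest
#' feature index, then the smallest threshold. Samples with
#' `feature <= threshold` go left.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Integer class indices (`1..K`) or labels.
#' @return A list `(feature, threshold, gini)` or `NULL` when no feature
#'   admits a split (all columns constant).
#' @export
best_split <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) return(NULL)
  yf <- as.integer(factor(y))
  K <- max(yf)
  if (length(unique(yf)) < 2) return(NULL)
  ind <- matrix(0L, n, K)
  ind[cbind(seq_len(n), yf)] <- 1L

  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    cum <- apply(ind[ord, , drop = FALSE], 2, cumsum)
    total <- cum[n, ]
    cut_at <- which(diff(xs) > 0)
    for (i in cut_at) {
      left <- cum[i, ]
      right <- total - left
      w <- 1 - (sum(left^2) / i + sum(right^2) / (n - i)) / n
      if (is.null(best) || w < best$gini) {
        best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                     gini = w)
      }
    }
  }
  best
}

new_cart_node <- function(counts, classes, n_total, depth) {
  pred <- which.max(counts)              # ties -> lowest class index
  list(is_leaf = TRUE, class_counts = counts, n = sum(counts),
       prediction = classes[pred], depth = depth,
       node_error = (sum(counts) - counts[pred]) / n_total,
       split_feature = NULL, split_threshold = NULL,
       left = NULL, right = NULL)
}

grow_node <- function(X, y_int, classes, config, n_total, depth) {
  counts <- tabulate(y_int, nbins = length(classes))
  node <- new_cart_node(counts, classes, n_total, depth)
  if (gini_index(counts) < config$gini_split_threshold ||
      length(y_int) < config$min_samples_split ||
      depth >= config$max_depth) {
    return(node)
  }
  sp <- best_split(X, y_int)
  if (is.null(sp)) return(node)
  go_left <- X[, sp$feature] <= sp$threshold
  if (!any(go_left) || all(go_left)) return(node)
  node$is_leaf <- FALSE
  node$split_feature <- sp$feature
  node$split_threshold <- sp$threshold
  node$left <- grow_node(X[go_left, , drop = FALSE], y_int[go_left],
                         classes, config, n_total, depth + 1L)
  node$right <- grow_node(X[!go_left, , drop = FALSE], y_int[!go_left],
                          classes, config, n_total, depth + 1L)
  node
}

#' Grow an unpruned CART classification tree
#'
#' Binary recursive Gini splitting. A node becomes a leaf when its Gini
#' impurity is below `gini_split_threshold`, it holds fewer than
#' `min_samples_split` samples, `max_depth` is reached, or no feature admits
#' a split. Leaves predict the majority class (ties to the lowest class
#' index). Misclassification costs `R(t)` are stored as proportions of the
#' full training set, as cost-complexity pruning requires.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels.
#' @param config A [cart_config()].
#' @return A `cart_tree`.
#' @seealso [weakest_link_sequence()], [select_subtree_cv()]
#' @export
grow_tree <- function(X, y, config = cart_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 1)
  classes <- unique(y)
  y_int <- match(y, classes)
  root <- grow_node(X, y_int, classes, config, nrow(X), 0L)
  structure(list(root = root, classes = classes, config = config,
                 n_train = nrow(X)),
            class = "cart_tree")
}

n_leaves_node <- function(node) {
  if (node$is_leaf) 1L else n_leaves_node(node$left) + n_leaves_node(node$right)
}

subtree_error_node <- function(node) {
  if (node$is_leaf) node$node_error
  else subtree_error_node(node$left) + subtree_error_node(node$right)
}

#' Number of leaves of a CART tree
#' @param tree A `cart_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) n_leaves_node(tree$root)

#' Resubstitution error of a CART tree
#' @param tree A `cart_tree`.
#' @return Training misclassification proportion (sum of leaf errors).
#' @export
training_error <- function(tree) subtree_error_node(tree$root)

# beta values of every internal node: (R(t) - R(T_t)) / (N_Tt - 1)
node_betas <- function(node) {
  if (node$is_leaf) return(numeric(0))
  beta <- (node$node_error - subtree_error_node(node)) /
    (n_leaves_node(node) - 1)
  c(beta, node_betas(node$left), node_betas(node$right))
}

collapse_at_beta <- function(node, beta_min, tol = 1e-12) {
  if (node$is_leaf) return(node)
  beta <- (node$node_error - subtree_error_node(node)) /
    (n_leaves_node(node) - 1)
  if (beta <= beta_min + tol) {
    node$is_leaf <- TRUE
    node$split_feature <- node$split_threshold <- NULL
    node$left <- node$right <- NULL
    return(node)
  }
  node$left <- collapse_at_beta(node$left, beta_min, tol)
  node$right <- collapse_at_beta(node$right, beta_min, tol)
  node
}

#' Weakest-link cost-complexity pruning sequence
#'
#' Repeatedly computes the pruning threshold
#' `beta_h = (R(t) - R(T_t)) / (N_Tt - 1)` for every internal node `t`
#' (misclassification costs as proportions of the full training set), prunes
#' every node attaining the minimum, and records the resulting tree, until
#' only the root remains. The recorded `beta` values are non-decreasing,
#' training error is non-decreasing and leaf counts strictly decrease along
#' the sequence.
#'
#' @param tree A `cart_tree` from [grow_tree()].
#' @return A list with `trees` (T0 = the input tree, ..., root-only) and
#'   `betas` (`betas[k]` produced `trees[[k + 1]]`).
#' @export
weakest_link_sequence <- function(tree) {
  trees <- list(tree)
  betas <- numeric(0)
  cur <- tree
  while (!cur$root$is_leaf) {
    b <- node_betas(cur$root)
    bmin <- min(b)
    cur$root <- collapse_at_beta(cur$root, bmin)
    trees <- c(trees, list(cur))
    betas <- c(betas, bmin)
  }
  list(trees = trees, betas = betas)
}

prune_to_beta <- function(tree, beta, tol = 1e-12) {
  seqs <- weakest_link_sequence(tree)
  k <- c(TRUE, seqs$betas <= beta + tol)
  seqs$trees[[max(which(k))]]
}

predict_node <- function(node, x) {
  while (!node$is_leaf) {
    node <- if (x[node$split_feature] <= node$split_threshold)
      node$left else node$right
  }
  node$prediction
}

#' Predict classes with a CART tree
#'
#' @param object A `cart_tree`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vapply(seq_len(nrow(newdata)),
         function(i) predict_node(object$root, newdata[i, ]),
         character(1))
}

#' Cross-validated cost-complexity subtree selection
#'
#' Grows the full tree, derives its weakest-link `beta` sequence, and picks
#' the pruning threshold with the highest stratified cross-validated
#' accuracy (per-fold trees are grown and pruned independently). Ties go to
#' the larger threshold, i.e. the smaller tree. Deterministic given
#' `config$seed`.
#'
#' @inheritParams grow_tree
#' @return The selected pruned `cart_tree`; attributes `chosen_beta` and
#'   `cv_accuracy` record the selection.
#' @export
select_subtree_cv <- function(X, y, config = cart_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  full <- grow_tree(X, y, config)
  seqs <- weakest_link_sequence(full)
  candidates <- unique(c(0, seqs$betas))

  plan <- stratified_kfold(y, config$cv_folds_for_pruning, config$seed)
  acc <- matrix(NA_real_, length(candidates), plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$assignments != f
    fold_tree <- grow_tree(X[tr, , drop = FALSE], y[tr], config)
    for (ci in seq_along(candidates)) {
      pruned <- prune_to_beta(fold_tree, candidates[ci])
      pred <- predict(pruned, X[!tr, , drop = FALSE])
      acc[ci, f] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  best_acc <- max(mean_acc)
  chosen <- max(candidates[mean_acc >= best_acc - 1e-12])  # ties -> smaller tree
  out <- prune_to_beta(full, chosen)
  attr(out, "chosen_beta") <- chosen
  attr(out, "cv_accuracy") <- best_acc
  out
}

#' Tidy the nodes of a CART tree
#'
#' @param x A `cart_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node`, `depth`, `is_leaf`,
#'   `split_feature`, `split_threshold`, `n`, `prediction`, `node_error`.
#' @method tidy cart_tree
#' @export
tidy.cart_tree <- function(x, ...) {
  rows <- list()
  walk <- function(nd, id) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node = id, depth = nd$depth, is_leaf = nd$is_leaf,
      split_feature = nd$split_feature %||% NA_integer_,
      split_threshold = nd$split_threshold %||% NA_real_,
      n = nd$n, prediction = nd$prediction,
      node_error = nd$node_error
    )
    if (!nd$is_leaf) {
      walk(nd$left, paste0(id, "L"))
      walk(nd$right, paste0(id, "R"))
    }
  }
  walk(x$root, "0")
  dplyr::bind_rows(rows)
}

#' @export
print.cart_tree <- function(x, ...) {
  cat("<cart_tree> ", n_leaves(x), " leaves, training error ",
      format(training_error(x), digits = 4), "\n", sep = "")
  invisible(x)
}
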