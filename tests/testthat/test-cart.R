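test_that("gini_index matches hand values and stays in bounds", {
  expect_equal(gini_index(c(10, 0, 0, 0, 0)), 0)
  expect_equal(gini_index(c(1, 1, 1, 1, 1)), 0.8)
  expect_equal(gini_index(c(3, 1)), 0.375)   # 1 - (0.75^2 + 0.25^2)
  expect_error(gini_index(c(0, 0)), "all-zero")
  expect_error(gini_index(c(-1, 2)), "negative")
  set.seed(1)
  for (i in 1:25) {
    K <- sample(2:6, 1)
    counts <- rpois(K, 5) + (seq_len(K) == 1)  # ensure positive total
    g <- gini_index(counts)
    expect_gte(g, 0)
    expect_lte(g, 1 - 1 / K)
    if (sum(counts > 0) == 1) expect_equal(g, 0)
  }
})

test_that("best_split finds the separating midpoint and signals no-split", {
  sp <- best_split(matrix(c(1, 2, 9, 10)), c("A", "A", "B", "B"))
  expect_equal(sp$threshold, 5.5)
  expect_equal(sp$gini, 0)
  expect_equal(sp$feature, 1L)
  expect_null(best_split(matrix(rep(3, 6), 6, 2), rep(c("a", "b"), 3)))
  expect_null(best_split(matrix(rnorm(4)), rep("a", 4)))
})

test_that("best_split equals the exhaustive oracle on random data", {
  for (seed in 1:8) {
    set.seed(seed)
    X <- matrix(rnorm(60), 20, 3)
    y <- sample(c("a", "b", "c"), 20, replace = TRUE)
    if (length(unique(y)) < 2) next
    got <- best_split(X, y)
    want <- oracle_best_split(X, y)
    expect_equal(got$gini, want$gini, tolerance = 1e-12)
    expect_equal(got$feature, want$feature)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("grow_tree handles pure, separable and depth-limited cases", {
  X <- matrix(rnorm(10), 5)
  pure <- grow_tree(X, rep("a", 5))
  expect_true(pure$root$is_leaf)
  expect_equal(n_leaves(pure), 1L)

  set.seed(2)
  d <- make_blobs(15, 2, 3, sep = 8, seed = 3)
  tree <- grow_tree(d$X, d$y)
  expect_equal(mean(predict(tree, d$X) == d$y), 1)

  stump <- grow_tree(d$X, d$y, cart_config(max_depth = 1))
  expect_lte(n_leaves(stump), 2L)
  root_split <- best_split(d$X, d$y)
  expect_equal(stump$root$split_feature, root_split$feature)
  expect_equal(stump$root$split_threshold, root_split$threshold)
})

test_that("pruning thresholds match hand-computed beta values", {
  # craft data yielding a known tree: feature 1 splits {A} | {B, C},
  # feature 2 then splits B | C; 8 samples, one B mislabeled region none.
  X <- matrix(c(0, 0, 1, 0, 0, 5, 1, 5, 10, 0, 11, 0, 10, 5, 11, 5),
              ncol = 2, byrow = TRUE)
  y <- c("A", "A", "A", "A", "B", "B", "C", "C")
  tree <- grow_tree(X, y)
  expect_equal(mean(predict(tree, X) == y), 1)
  expect_equal(n_leaves(tree), 3L)

  # root: R(t) = (8 - 4)/8 = 0.5, subtree error 0, 3 leaves -> beta = 0.25
  # internal right node: R(t) = 2/8 = 0.25, 2 leaves -> beta = 0.25
  seqs <- weakest_link_sequence(tree)
  expect_equal(seqs$betas, 0.25)          # both collapse at beta_min = 0.25
  expect_equal(n_leaves(seqs$trees[[2]]), 1L)

  # a stump whose split does not reduce error is pruned at beta = 0
  X2 <- matrix(c(0, 1, 10, 11), 4)
  y2 <- c("A", "A", "A", "B")
  t2 <- grow_tree(X2, y2, cart_config(min_samples_split = 2))
  s2 <- weakest_link_sequence(t2)
  if (!t2$root$is_leaf && length(s2$betas) > 0) {
    expect_gte(min(s2$betas), 0)
  }
})

test_that("pruning sequence is monotone and ends at the root", {
  set.seed(4)
  X <- matrix(rnorm(200), 50, 4)
  y <- sample(c("a", "b", "c"), 50, replace = TRUE)
  tree <- grow_tree(X, y)
  seqs <- weakest_link_sequence(tree)
  leaves <- vapply(seqs$trees, n_leaves, integer(1))
  errors <- vapply(seqs$trees, training_error, numeric(1))
  expect_true(all(diff(leaves) < 0))
  expect_true(all(diff(errors) >= -1e-12))
  expect_true(all(diff(seqs$betas) >= -1e-12))
  expect_true(seqs$trees[[length(seqs$trees)]]$root$is_leaf)
})

test_that("CART predictions are invariant under monotone feature maps", {
  set.seed(5)
  X <- matrix(rnorm(120), 40, 3)
  y <- sample(c("a", "b"), 40, replace = TRUE)
  tree1 <- grow_tree(X, y)
  X2 <- X
  X2[, 2] <- exp(X[, 2])        # strictly increasing transform
  tree2 <- grow_tree(X2, y)
  expect_identical(predict(tree1, X), predict(tree2, X2))
})

test_that("cross-validated subtree selection is sane and deterministic", {
  d <- make_blobs(15, 2, 3, sep = 8, seed = 6)   # noise-free separable
  chosen <- select_subtree_cv(d$X, d$y)
  expect_equal(mean(predict(chosen, d$X) == d$y), 1)

  pure <- select_subtree_cv(matrix(rnorm(40), 20, 2), rep("a", 20))
  expect_true(pure$root$is_leaf)

  set.seed(7)
  X <- matrix(rnorm(240), 60, 4)
  y <- sample(c("a", "b", "c"), 60, replace = TRUE)
  t1 <- select_subtree_cv(X, y, cart_config(seed = 42))
  t2 <- select_subtree_cv(X, y, cart_config(seed = 42))
  expect_identical(tidy(t1), tidy(t2))
  expect_identical(attr(t1, "chosen_beta"), attr(t2, "chosen_beta"))
})

test_that("tidy.cart_tree walks every node once", {
  d <- make_blobs(10, 2, 2, sep = 6, seed = 8)
  tree <- grow_tree(d$X, d$y)
  tb <- tidy(tree)
  expect_equal(sum(tb$is_leaf), n_leaves(tree))
  expect_equal(nrow(tb), 2L * n_leaves(tree) - 1L)  # full binary tree
  expect_equal(tb$n[tb$node == "0"], 20L)
})
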