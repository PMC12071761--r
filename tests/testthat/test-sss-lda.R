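test_that("scatter matrices match the double-loop oracle and decompose", {
  # 6 hand-listed points in 2D, 2 classes
  X <- matrix(c(0, 0, 1, 0, 0, 1,
                4, 4, 5, 4, 4, 5), ncol = 2, byrow = TRUE)
  y <- rep(c("a", "b"), each = 3)
  sc <- compute_scatter(X, y)
  or <- oracle_scatter(X, y)
  expect_equal(sc$Sw, or$Sw, tolerance = 1e-12)
  expect_equal(sc$Sb, or$Sb, tolerance = 1e-12)
  expect_equal(sc$St, or$St, tolerance = 1e-12)

  # identity St = Sw + Sb and PSD on random data
  for (seed in 1:5) {
    d <- make_blobs(6, 4, 3, seed = seed)
    sc <- compute_scatter(d$X, d$y)
    expect_lt(max(abs(sc$St - sc$Sw - sc$Sb)), 1e-6 * norm(sc$St, "F"))
    expect_true(all(eigen(sc$Sw, symmetric = TRUE, only.values = TRUE)$values
                    > -1e-8))
  }

  # one sample per class: no within-class deviation
  sc0 <- compute_scatter(matrix(rnorm(8), 2), c("a", "b"))
  expect_equal(sc0$Sw, matrix(0, 4, 4))
  expect_error(compute_scatter(matrix(rnorm(8), 2), c("a", "a")),
               "two classes")
})

test_that("ALDA agrees with classical Fisher LDA when nothing is replaced", {
  d <- make_blobs(40, 4, 3, sep = 4, seed = 11)   # n >> p, Sw nonsingular
  m <- fit_alda(d$X, d$y, d = 2)
  expect_equal(m$diagnostics$n_replaced, 0)
  expect_lt(max_principal_angle(m$W, oracle_fisher(d$X, d$y, 2)), 1e-6)
})

test_that("ALDA reduces to between-class directions for isotropic Sw", {
  # classes on coordinate axes with exchangeable isotropic noise:
  # construct data whose within-class scatter is exactly c * I
  X <- rbind(diag(4), diag(4) * -1) * 0.3
  X <- rbind(X + matrix(rep(c(5, 0, 0, 0), each = 8), 8),
             X + matrix(rep(c(0, 5, 0, 0), each = 8), 8),
             X + matrix(rep(c(0, 0, 5, 0), each = 8), 8))
  y <- rep(c("a", "b", "c"), each = 8)
  sc <- compute_scatter(X, y)
  expect_equal(sc$Sw, diag(4) * sc$Sw[1, 1], tolerance = 1e-12)
  m <- fit_alda(X, y, d = 2)
  eb <- eigen(sc$Sb, symmetric = TRUE)
  expect_lt(max_principal_angle(m$W, eb$vectors[, 1:2]), 1e-6)
})

test_that("ALDA alpha equals the largest singular-value square root of Sw-hat", {
  d <- make_blobs(3, 20, 3, sep = 2, seed = 13)   # SSS: p=20, n=9
  m <- fit_alda(d$X, d$y, d = 2)
  expect_equal(m$diagnostics$alpha, oracle_alda(d$X, d$y, 2)$alpha,
               tolerance = 1e-8)
})

test_that("CLDA collapses each class to one common vector", {
  d <- make_blobs(4, 30, 3, sep = 2, seed = 17)   # p=30, n=12: Sw singular
  m <- fit_clda(d$X, d$y)
  sc <- compute_scatter(d$X, d$y)

  # common-vector theorem: every sample of a class has the same null-space
  # image, so the choice of representative is immaterial
  rng <- eigen(sc$Sw, symmetric = TRUE)
  r <- m$diagnostics$rank_sw
  Q <- rng$vectors[, seq_len(r), drop = FALSE]
  for (cl in unique(d$y)) {
    rows <- which(d$y == cl)
    imgs <- t(vapply(rows, function(i) {
      x <- d$X[i, ]
      x - Q %*% crossprod(Q, x)
    }, numeric(ncol(d$X))))
    expect_lt(max(dist(imgs)), 1e-6)
  }

  # projected training data has zero within-class variance, and nearest
  # projected common vector classifies training data perfectly
  scores <- project(m, d$X)
  for (cl in unique(d$y)) {
    expect_lt(max(apply(scores[d$y == cl, , drop = FALSE], 2, stats::sd)),
              1e-8)
  }
  com_scores <- crossprod(m$diagnostics$common_vectors -
                            m$grand_mean, m$W)
  pred <- unique(d$y)[apply(scores, 1, function(s) {
    which.min(colSums((t(com_scores) - s)^2))
  })]
  expect_equal(pred, d$y)
})

test_that("CLDA handles singleton classes and rejects nonsingular Sw", {
  # two singleton classes: Sw = 0, common vectors are the samples
  X <- matrix(c(1, 0, 0, 0,
                0, 2, 0, 0), 2, byrow = TRUE)
  m <- fit_clda(X, c("a", "b"))
  expect_equal(m$diagnostics$rank_sw, 0L)
  expect_equal(m$d, 1L)
  dir <- (X[1, ] - X[2, ]) / sqrt(sum((X[1, ] - X[2, ])^2))
  expect_lt(max_principal_angle(m$W, matrix(dir)), 1e-8)

  d <- make_blobs(40, 3, 3, seed = 19)            # n >> p: Sw full rank
  expect_error(fit_clda(d$X, d$y), "not applicable")
})

test_that("MLDA equals Fisher LDA when no eigenvalue is clamped", {
  # isotropic within-class scatter: all S_P eigenvalues equal, clamping is
  # the identity and the criterion reduces to Fisher's
  X <- rbind(diag(4), -diag(4)) * 0.3
  X <- rbind(X + matrix(rep(c(5, 0, 0, 0), each = 8), 8),
             X + matrix(rep(c(0, 5, 0, 0), each = 8), 8),
             X + matrix(rep(c(0, 0, 5, 0), each = 8), 8))
  y <- rep(c("a", "b", "c"), each = 8)
  m <- fit_mlda(X, y, d = 2)
  expect_lt(max_principal_angle(m$W, oracle_fisher(X, y, 2)), 1e-6)
})

test_that("MLDA clamps the spectrum at lambda_bar and matches the oracle", {
  d <- make_blobs(3, 10, 3, sep = 2, seed = 23)   # p=10, n=9: Sw singular
  m <- fit_mlda(d$X, d$y, d = 2)
  or <- oracle_mlda(d$X, d$y, 2)
  expect_equal(m$diagnostics$lambda_bar, or$lambda_bar, tolerance = 1e-10)
  expect_lt(max_principal_angle(m$W, or$W), 1e-6)
  # clamping floor: the rebuilt within-class scatter is safely nonsingular
  ev <- eigen(or$SW_star, symmetric = TRUE, only.values = TRUE)$values
  n <- nrow(d$X); K <- 3
  expect_gte(min(ev), or$lambda_bar * (n - K) - 1e-10)

  expect_error(fit_mlda(matrix(rnorm(8), 2), c("a", "b")), "n >")
  X0 <- rbind(diag(2), diag(2), diag(2))
  expect_error(fit_mlda(X0, rep(c("a", "b"), 3), d = 1), "zero")
})

test_that("NLDA annihilates within-class scatter and matches the oracle", {
  d <- make_blobs(3, 25, 4, sep = 2, seed = 29)   # p=25, n=12, 4 classes
  m <- fit_nlda(d$X, d$y, d = 3)
  sc <- compute_scatter(d$X, d$y)
  expect_lt(max(abs(t(m$W) %*% sc$Sw %*% m$W)), 1e-8)
  expect_lt(max_principal_angle(m$W, oracle_nlda(d$X, d$y, 3)$W), 1e-6)
  # orthonormal columns
  expect_equal(crossprod(m$W), diag(3), tolerance = 1e-10)
})

test_that("NLDA degenerate and full-rank paths behave as defined", {
  # 3 singleton classes in 4D: Sw = 0, null space is everything, so the
  # directions are the top eigenvectors of Sb itself
  X <- matrix(c(1, 0, 0, 0,
                0, 2, 0, 0,
                0, 0, 3, 0), 3, byrow = TRUE)
  y <- c("a", "b", "c")
  m <- fit_nlda(X, y, d = 2)
  sc <- compute_scatter(X, y)
  eb <- eigen(sc$Sb, symmetric = TRUE)
  expect_lt(max_principal_angle(m$W, eb$vectors[, 1:2]), 1e-6)

  # full-rank fallback agrees with the (Sb+Sw)^-1 Sb criterion, which spans
  # the same subspace as classical Fisher LDA
  d <- make_blobs(40, 4, 3, sep = 4, seed = 31)
  m2 <- fit_nlda(d$X, d$y, d = 2)
  expect_true(m2$diagnostics$fallback)
  expect_lt(max_principal_angle(m2$W, oracle_fisher(d$X, d$y, 2)), 1e-4)
})

test_that("fitters are deterministic with a fixed sign convention", {
  d <- make_blobs(3, 20, 3, seed = 37)
  for (method in extractor_methods()) {
    m1 <- fit_extractor(method, d$X, d$y)
    m2 <- fit_extractor(method, d$X, d$y)
    expect_identical(m1$W, m2$W)
    expect_true(all(apply(m1$W, 2,
                          function(w) w[which.max(abs(w))] > 0)))
  }
  expect_error(fit_extractor("PCA", d$X, d$y), "unknown")
})

test_that("requesting too many components truncates with a recorded warning", {
  d <- make_blobs(3, 12, 3, seed = 41)
  m <- fit_nlda(d$X, d$y, d = 4)   # rank(Sb) = K - 1 = 2
  expect_equal(m$d, 2L)
  expect_match(m$diagnostics$warnings, "requested 4")
})

test_that("projection centers on the training grand mean", {
  d <- make_blobs(4, 15, 3, seed = 43)
  m <- fit_nlda(d$X, d$y)
  expect_equal(as.vector(project(m, matrix(m$grand_mean, 1))),
               rep(0, m$d), tolerance = 1e-10)
  scores <- project(m, d$X)
  manual <- sweep(d$X, 2, m$grand_mean) %*% m$W
  expect_equal(scores, manual, tolerance = 1e-10, ignore_attr = TRUE)
  # orthonormal W contracts norms
  centered <- sweep(d$X, 2, m$grand_mean)
  expect_true(all(sqrt(rowSums(scores^2)) <=
                    sqrt(rowSums(centered^2)) + 1e-10))
  expect_error(project(m, d$X[, 1:5]), "columns")
})

test_that("on well-separated nonsingular data ALDA and NLDA meet Fisher", {
  # (MLDA only coincides with Fisher when no eigenvalue is clamped, which
  # its dedicated isotropic test covers; on sampled blobs roughly half the
  # pooled-covariance spectrum sits below the mean and is raised to it)
  d <- make_blobs(30, 5, 3, sep = 5, seed = 47)
  fisher <- oracle_fisher(d$X, d$y, 2)
  for (method in c("ALDA", "NLDA")) {
    m <- fit_extractor(method, d$X, d$y, d = 2)
    expect_lt(max_principal_angle(m$W, fisher), 1e-4)
  }
})
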