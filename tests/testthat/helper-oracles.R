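# Independent dense oracles: literal step-by-step implementations using full
# p x p eigendecompositions, kept deliberately separate from the package's
# Gram-factorized code paths.

oracle_scatter <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  p <- ncol(X)
  classes <- unique(y)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  St <- matrix(0, p, p)
  for (cl in classes) {
    idx <- which(y == cl)
    mc <- colMeans(X[idx, , drop = FALSE])
    for (i in idx) Sw <- Sw + tcrossprod(X[i, ] - mc)
    Sb <- Sb + length(idx) * tcrossprod(mc - mu)
  }
  for (i in seq_len(nrow(X))) St <- St + tcrossprod(X[i, ] - mu)
  list(Sw = Sw, Sb = Sb, St = St)
}

dense_tol <- function(M, n, p) max(p, n) * .Machine$double.eps

top_re_eigvecs <- function(M, d) {
  eg <- eigen(M)
  ord <- order(Re(eg$values), decreasing = TRUE)
  Re(eg$vectors[, ord[seq_len(d)], drop = FALSE])
}

oracle_fisher <- function(X, y, d) {
  sc <- oracle_scatter(X, y)
  top_re_eigvecs(solve(sc$Sw) %*% sc$Sb, d)
}

oracle_alda <- function(X, y, d, tol = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(tol)) tol <- max(p, n) * .Machine$double.eps
  sc <- oracle_scatter(X, y)
  est <- eigen(sc$St, symmetric = TRUE)
  keep <- est$values > tol * max(est$values)
  Ut <- est$vectors[, keep, drop = FALSE]
  mu <- colMeans(X)
  Y <- sweep(X, 2, mu) %*% Ut
  scy <- oracle_scatter(Y, y)
  ew <- eigen(scy$Sw, symmetric = TRUE)
  D_W <- sqrt(pmax(ew$values, 0))
  alpha <- max(D_W)
  D_alpha <- ifelse(D_W < sqrt(tol) * alpha, alpha, D_W)  # sqrt-scale cut
  S_alpha_inv <- ew$vectors %*% diag(1 / D_alpha^2, length(D_alpha)) %*%
    t(ew$vectors)
  w <- top_re_eigvecs(S_alpha_inv %*% scy$Sb, d)
  list(W = Ut %*% w, alpha = alpha)
}

oracle_mlda <- function(X, y, d, tol = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  K <- length(unique(y))
  sc <- oracle_scatter(X, y)
  S_P <- sc$Sw / (n - K)
  ep <- eigen(S_P, symmetric = TRUE)
  lambda_bar <- mean(ep$values)
  lam_star <- pmax(ep$values, lambda_bar)
  SW_star <- ep$vectors %*% diag(lam_star, p) %*% t(ep$vectors) * (n - K)
  list(W = top_re_eigvecs(solve(SW_star) %*% sc$Sb, d),
       lambda_bar = lambda_bar, SW_star = SW_star)
}

oracle_nlda <- function(X, y, d, tol = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(tol)) tol <- max(p, n) * .Machine$double.eps
  sc <- oracle_scatter(X, y)
  sv <- eigen(sc$Sw, symmetric = TRUE)
  r <- sum(sv$values > tol * max(sv$values, 0))
  if (r == p) {
    return(list(W = top_re_eigvecs(solve(sc$Sb + sc$Sw) %*% sc$Sb, d),
                rank = r))
  }
  Q <- sv$vectors[, (r + 1):p, drop = FALSE]
  Sb_tilde <- t(Q) %*% sc$Sb %*% Q
  eb <- eigen((Sb_tilde + t(Sb_tilde)) / 2, symmetric = TRUE)
  list(W = Q %*% eb$vectors[, seq_len(d), drop = FALSE], rank = r)
}

# largest principal angle (radians) between the column spaces of A and B
max_principal_angle <- function(A, B) {
  QA <- qr.Q(qr(A))
  QB <- qr.Q(qr(B))
  s <- svd(crossprod(QA, QB))$d
  max(acos(pmin(1, pmax(-1, s))))
}

# exhaustive (feature, midpoint) search minimizing weighted child Gini
oracle_best_split <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  gini <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (k in seq_len(length(vals) - 1)) {
      thr <- (vals[k] + vals[k + 1]) / 2
      left <- X[, j] <= thr
      w <- (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
      if (is.null(best) || w < best$gini - 1e-15) {
        best <- list(feature = j, threshold = thr, gini = w)
      }
    }
  }
  best
}

# per-window polynomial least-squares fit evaluated at the window center
oracle_sg <- function(x, window, polyorder) {
  h <- (window - 1) / 2
  n <- length(x)
  padded <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- padded[i:(i + window - 1)]
    t <- seq(-h, h)
    fit <- stats::lm(win ~ poly(t, degree = polyorder, raw = TRUE))
    out[i] <- unname(predict(fit, newdata = data.frame(t = 0)))
  }
  out
}

# small Gaussian-blob class data; sep scales the class-mean spread
make_blobs <- function(n_per, p, K, sep = 3, seed = 1, sd = 1) {
  set.seed(seed)
  means <- matrix(rnorm(K * p, 0, sep), K, p)
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(rnorm(n_per * p, 0, sd), n_per, p) +
      matrix(means[k, ], n_per, p, byrow = TRUE)
  }))
  list(X = X, y = rep(paste0("c", seq_len(K)), each = n_per))
}
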