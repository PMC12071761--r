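#' Within-, between- and total-class scatter matrices
#'
#' Computes `Sw = sum_c sum_{i in c} (x_i - mu_c)(x_i - mu_c)'`,
#' `Sb = sum_c n_c (mu_c - mu)(mu_c - mu)'` and
#' `St = sum_i (x_i - mu)(x_i - mu)'`, which satisfy `St = Sw + Sb`.
#' In the small-sample-size regime (`p > n`) all three are singular; the
#' discriminant fitters in this package are built around that fact.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels, one per row; at least two classes.
#' @return A `scatter_set` list: `Sw`, `Sb`, `St` (p x p), `class_means`
#'   (p x K matrix, one column per class, in label order of first
#'   appearance), `grand_mean`, `class_counts`, `classes`.
#' @examples
#' X <- matrix(rnorm(20), nrow = 10)
#' sc <- compute_scatter(X, rep(c("a", "b"), each = 5))
#' max(abs(sc$St - (sc$Sw + sc$Sb)))
#' @export
compute_scatter <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  p <- ncol(X)
  mu <- colMeans(X)
  class_means <- vapply(classes,
                        function(cl) colMeans(X[y == cl, , drop = FALSE]),
                        numeric(p))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))

  Xw <- X - t(class_means)[match(y, classes), , drop = FALSE]
  Sw <- crossprod(Xw)
  Mb <- sweep(class_means - mu, 2, sqrt(counts), "*")
  Sb <- tcrossprod(Mb)
  Xc <- sweep(X, 2, mu)
  St <- crossprod(Xc)
  structure(list(Sw = Sw, Sb = Sb, St = St,
                 class_means = class_means, grand_mean = mu,
                 class_counts = counts, classes = classes),
            class = "scatter_set")
}

# Shared per-fit quantities, computed without forming any p x p matrix:
# within-class centered data Xw (n x p), sqrt(n_c)-scaled class-mean
# deviations Mb (p x K), grand-mean centered data Xc (n x p).
scatter_parts <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- unique(y)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  p <- ncol(X)
  mu <- colMeans(X)
  class_means <- vapply(classes,
                        function(cl) colMeans(X[y == cl, , drop = FALSE]),
                        numeric(p))
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  list(
    Xw = X - t(class_means)[match(y, classes), , drop = FALSE],
    Mb = sweep(class_means - mu, 2, sqrt(counts), "*"),
    Xc = sweep(X, 2, mu),
    class_means = class_means, grand_mean = mu,
    class_counts = counts, classes = classes,
    n = nrow(X), p = p, K = length(classes)
  )
}

# Orthonormal basis of the row space of A (n x p) via the n x n Gram matrix.
# The eigenvalues of A'A (= the scatter matrix built from A) equal those of
# AA', so the rank cut lambda > rel_tol * lambda_max matches a cut on the
# scatter matrix's own eigenvalues/singular values.
gram_range <- function(A, rel_tol) {
  G <- tcrossprod(A)                      # n x n
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (!length(lam) || max(lam) == 0) {
    return(list(U = matrix(0, ncol(A), 0), sigma2 = numeric(0)))
  }
  keep <- lam > rel_tol * max(lam)
  U <- crossprod(A, eg$vectors[, keep, drop = FALSE])
  U <- sweep(U, 2, sqrt(lam[keep]), "/")
  list(U = U, sigma2 = lam[keep])
}
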