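new_projection_model <- function(method, W, eigenvalues, grand_mean,
                                 rank_tolerance, diagnostics, classes) {
  W <- fix_signs(W)
  structure(
    list(method = method, W = W, d = ncol(W),
         eigenvalues = eigenvalues, grand_mean = grand_mean,
         rank_tolerance = rank_tolerance, diagnostics = diagnostics,
         classes = classes),
    class = "projection_model"
  )
}

#' @export
print.projection_model <- function(x, ...) {
  cat("<projection_model> ", x$method, ": ", length(x$grand_mean),
      " -> ", x$d, " dimensions\n", sep = "")
  cat("criterion values:", format(x$eigenvalues, digits = 4), "\n")
  if (length(x$diagnostics$warnings)) {
    cat("warnings:", paste(x$diagnostics$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname tidy_projection
#' @method tidy projection_model
#' @export
tidy.projection_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$d), eigenvalue = x$eigenvalues)
}

#' Tidy and summarize a fitted discriminant projection
#'
#' `tidy()` returns one row per discriminant component with its criterion
#' value (eigenvalue); `glance()` returns a one-row model summary.
#'
#' @param x A `projection_model`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_projection
#' @method glance projection_model
#' @export
glance.projection_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_components = x$d,
    p = length(x$grand_mean),
    rank_sw = x$diagnostics$rank_sw %||% NA_integer_,
    null_dim = x$diagnostics$null_dim %||% NA_integer_,
    truncated = length(x$diagnostics$warnings) > 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_d <- function(requested, available, method, diagnostics) {
  if (available < 1) {
    stop(method, ": no usable discriminant direction (between-class scatter ",
         "has rank 0 in the working space)", call. = FALSE)
  }
  if (requested > available) {
    diagnostics$warnings <- c(
      diagnostics$warnings,
      paste0("requested ", requested, " components but only ", available,
             " usable; returning ", available)
    )
    requested <- available
  }
  list(d = requested, diagnostics = diagnostics)
}

#' Approximate linear discriminant analysis (ALDA)
#'
#' Handles singular within-class scatter by (1) projecting the data onto the
#' range space of the total scatter `St`, (2) eigendecomposing the reduced
#' within-class scatter `Sw_hat` to get its eigenvalue square roots `D_W`,
#' (3) replacing (near-)zero entries of `D_W` by the largest one,
#' `alpha = max(D_W)`, to form the approximate inverse
#' `S_alpha^-1 = U_W D_alpha^-2 U_W'`, and (4) solving
#' `S_alpha^-1 Sb_hat w = lambda w` for the leading directions, mapped back
#' to the original wavenumber space.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels (>= 2 classes).
#' @param d Number of discriminant components; default one fewer than the
#'   number of classes. Truncated (with a recorded warning) when fewer
#'   usable directions exist.
#' @param rank_tolerance Relative tolerance deciding which eigenvalues count
#'   as nonzero; default `max(p, n) * .Machine$double.eps`.
#' @return A `projection_model` with fields `W` (p x d, unit columns),
#'   `eigenvalues`, `grand_mean`, and `diagnostics` (`alpha`, number of
#'   replaced entries, range-space dimension).
#' @family sss-discriminants
#' @export
fit_alda <- function(X, y, d = NULL, rank_tolerance = NULL) {
  parts <- scatter_parts(X, y)
  rel_tol <- rank_tolerance %||% default_rank_tol(parts$n, parts$p)
  if (is.null(d)) d <- parts$K - 1L

  rng <- gram_range(parts$Xc, rel_tol)      # range space of St
  Ut <- rng$U                               # p x m
  if (ncol(Ut) == 0) stop("total scatter is zero", call. = FALSE)
  Y <- parts$Xc %*% Ut                      # n x m reduced data

  partsY <- scatter_parts(Y, y)
  Sw_hat <- crossprod(partsY$Xw)
  Sb_hat <- tcrossprod(partsY$Mb)

  ew <- eigen(Sw_hat, symmetric = TRUE)
  D_W <- sqrt(pmax(ew$values, 0))
  alpha <- max(D_W)
  if (alpha == 0) {
    # no within-class spread at all: S_alpha undefined; fall back to the
    # between-class directions (limit of the criterion as Sw -> 0)
    D_alpha <- rep(1, length(D_W))
    n_replaced <- length(D_W)
  } else {
    # D_W holds eigenvalue square roots, so the rank cut moves to the sqrt
    # scale: D < sqrt(tol) * alpha <=> eigenvalue < tol * alpha^2
    replaced <- D_W < sqrt(rel_tol) * alpha
    D_alpha <- ifelse(replaced, alpha, D_W)
    n_replaced <- sum(replaced)
  }
  M <- ew$vectors %*% (t(ew$vectors) / D_alpha)   # S_alpha^{-1/2}
  S_sym <- M %*% Sb_hat %*% M
  S_sym <- (S_sym + t(S_sym)) / 2
  es <- eigen(S_sym, symmetric = TRUE)
  usable <- sum(es$values > rel_tol * max(es$values, 0))

  diagnostics <- list(alpha = alpha, n_replaced = n_replaced,
                      range_dim = ncol(Ut), rank_sw = sum(D_W > rel_tol * alpha),
                      warnings = character(0))
  res <- resolve_d(d, min(usable, parts$K - 1L), "ALDA", diagnostics)
  w <- M %*% es$vectors[, seq_len(res$d), drop = FALSE]
  W <- unit_cols(Ut %*% w)
  new_projection_model("ALDA", W, es$values[seq_len(res$d)],
                       parts$grand_mean, rel_tol, res$diagnostics,
                       parts$classes)
}

#' Common-vector linear discriminant analysis (CLDA)
#'
#' Requires a singular within-class scatter. Each sample is projected onto
#' the null space of `Sw`; within a class all samples share one image there
#' (the class common vector), so one sample per class suffices. The
#' discriminant directions are the nonzero-eigenvalue eigenvectors of the
#' scatter of the common vectors about their mean.
#'
#' @inheritParams fit_alda
#' @param d Number of components; defaults to all usable directions (at most
#'   one fewer than the number of classes).
#' @return A `projection_model`; `diagnostics` holds the rank and
#'   null-space dimension of `Sw` and the common vectors (p x K).
#' @family sss-discriminants
#' @export
fit_clda <- function(X, y, d = NULL, rank_tolerance = NULL) {
  parts <- scatter_parts(X, y)
  rel_tol <- rank_tolerance %||% default_rank_tol(parts$n, parts$p)

  rng <- gram_range(parts$Xw, rel_tol)      # range space of Sw
  Q <- rng$U
  r <- ncol(Q)
  if (r >= parts$p) {
    stop("CLDA not applicable: within-class scatter is nonsingular ",
         "(empty null space); use ALDA, MLDA or the NLDA full-rank path",
         call. = FALSE)
  }
  X <- as.matrix(X)
  first_idx <- match(parts$classes, as.character(y))
  Xfirst <- X[first_idx, , drop = FALSE]            # K x p
  Xcom <- Xfirst - (Xfirst %*% Q) %*% t(Q)          # common vectors, K x p
  Acom <- sweep(Xcom, 2, colMeans(Xcom))
  com_rng <- gram_range(Acom, rel_tol)

  diagnostics <- list(rank_sw = r, null_dim = parts$p - r,
                      common_vectors = t(Xcom), warnings = character(0))
  avail <- min(ncol(com_rng$U), parts$K - 1L)
  if (is.null(d)) d <- avail
  res <- resolve_d(d, avail, "CLDA", diagnostics)
  W <- com_rng$U[, seq_len(res$d), drop = FALSE]
  new_projection_model("CLDA", W, com_rng$sigma2[seq_len(res$d)],
                       parts$grand_mean, rel_tol, res$diagnostics,
                       parts$classes)
}

#' Maximum-uncertainty linear discriminant analysis (MLDA)
#'
#' Regularizes the pooled covariance `S_P = Sw / (n - K)` by raising every
#' eigenvalue below the average eigenvalue `lambda_bar = trace(S_P) / p` up
#' to `lambda_bar`, rebuilding a nonsingular `Sw* = V Lambda* V' (n - K)`,
#' and solving the Fisher criterion `(Sw*)^-1 Sb w = lambda w`.
#'
#' @inheritParams fit_alda
#' @return A `projection_model`; `diagnostics` holds `lambda_bar`, the count
#'   of clamped eigenvalues and the rank of `Sw`.
#' @family sss-discriminants
#' @export
fit_mlda <- function(X, y, d = NULL, rank_tolerance = NULL) {
  parts <- scatter_parts(X, y)
  rel_tol <- rank_tolerance %||% default_rank_tol(parts$n, parts$p)
  if (is.null(d)) d <- parts$K - 1L
  if (parts$n <= parts$K) stop("MLDA needs n > number of classes", call. = FALSE)
  dof <- parts$n - parts$K

  tr_sw <- sum(parts$Xw^2)
  if (tr_sw == 0) {
    stop("within-class scatter is exactly zero: lambda_bar = 0 gives no ",
         "regularization; MLDA not applicable", call. = FALSE)
  }
  lambda_bar <- tr_sw / dof / parts$p       # mean over all p eigenvalues of S_P

  rng <- gram_range(parts$Xw, rel_tol)
  Vr <- rng$U                               # p x r basis of range(Sw)
  lam_P <- rng$sigma2 / dof                 # nonzero eigenvalues of S_P
  lam_star <- pmax(lam_P, lambda_bar)       # clamped; null directions get lambda_bar

  # B = (Sw*)^-1 Mb without forming any p x p matrix
  t1 <- crossprod(Vr, parts$Mb)             # r x K
  B <- (Vr %*% (t1 / lam_star) + (parts$Mb - Vr %*% t1) / lambda_bar) / dof
  C <- crossprod(parts$Mb, B)               # K x K, symmetric
  C <- (C + t(C)) / 2
  es <- eigen(C, symmetric = TRUE)
  usable <- sum(es$values > rel_tol * max(es$values, 0))

  diagnostics <- list(lambda_bar = lambda_bar,
                      n_clamped = sum(lam_P < lambda_bar) + (parts$p - length(lam_P)),
                      rank_sw = length(lam_P), null_dim = parts$p - length(lam_P),
                      warnings = character(0))
  res <- resolve_d(d, min(usable, parts$K - 1L), "MLDA", diagnostics)
  W <- unit_cols(B %*% es$vectors[, seq_len(res$d), drop = FALSE])
  new_projection_model("MLDA", W, es$values[seq_len(res$d)],
                       parts$grand_mean, rel_tol, res$diagnostics,
                       parts$classes)
}

#' Null-space linear discriminant analysis (NLDA)
#'
#' When `Sw` is singular (the small-sample-size case), the between-class
#' scatter is projected onto the null space of `Sw`, where within-class
#' spread vanishes but class-mean differences survive; the leading
#' eigenvectors of the projected `Sb` are the discriminant directions. When
#' `Sw` has full rank, the classical Fisher solution via
#' `(Sb + Sw)^-1 Sb` is used instead.
#'
#' @inheritParams fit_alda
#' @return A `projection_model` with orthonormal `W` in the singular case;
#'   `diagnostics` records the rank of `Sw`, the null-space dimension and
#'   whether the full-rank fallback ran.
#' @family sss-discriminants
#' @export
fit_nlda <- function(X, y, d = NULL, rank_tolerance = NULL) {
  parts <- scatter_parts(X, y)
  rel_tol <- rank_tolerance %||% default_rank_tol(parts$n, parts$p)
  if (is.null(d)) d <- parts$K - 1L

  rng <- gram_range(parts$Xw, rel_tol)
  r <- ncol(rng$U)

  if (r >= parts$p) {
    # full-rank path: Fisher criterion through the total scatter
    St <- crossprod(parts$Xw) + tcrossprod(parts$Mb)
    est <- eigen((St + t(St)) / 2, symmetric = TRUE)
    keep <- est$values > rel_tol * max(est$values)
    Mhalf <- est$vectors[, keep, drop = FALSE] %*%
      (t(est$vectors[, keep, drop = FALSE]) / sqrt(est$values[keep]))
    S_sym <- Mhalf %*% tcrossprod(parts$Mb) %*% Mhalf
    es <- eigen((S_sym + t(S_sym)) / 2, symmetric = TRUE)
    usable <- sum(es$values > rel_tol * max(es$values, 0))
    diagnostics <- list(rank_sw = r, null_dim = 0L, fallback = TRUE,
                        warnings = character(0))
    res <- resolve_d(d, min(usable, parts$K - 1L), "NLDA", diagnostics)
    W <- unit_cols(Mhalf %*% es$vectors[, seq_len(res$d), drop = FALSE])
    return(new_projection_model("NLDA", W, es$values[seq_len(res$d)],
                                parts$grand_mean, rel_tol, res$diagnostics,
                                parts$classes))
  }

  # null-space path: project class-mean deviations onto null(Sw)
  Pm <- parts$Mb - rng$U %*% crossprod(rng$U, parts$Mb)   # p x K
  G <- crossprod(Pm)                                      # = Mb' Q Q' Mb
  G <- (G + t(G)) / 2
  es <- eigen(G, symmetric = TRUE)
  gmax <- max(es$values, 0)
  if (gmax <= 0 || all(es$values <= rel_tol * gmax)) {
    stop("NLDA: no discriminant information — all class means coincide in ",
         "the null space of Sw", call. = FALSE)
  }
  usable <- sum(es$values > rel_tol * gmax)
  diagnostics <- list(rank_sw = r, null_dim = parts$p - r, fallback = FALSE,
                      warnings = character(0))
  res <- resolve_d(d, min(usable, parts$K - 1L), "NLDA", diagnostics)
  idx <- seq_len(res$d)
  W <- Pm %*% sweep(es$vectors[, idx, drop = FALSE], 2,
                    sqrt(es$values[idx]), "/")
  new_projection_model("NLDA", W, es$values[idx],
                       parts$grand_mean, rel_tol, res$diagnostics,
                       parts$classes)
}

#' Fit one of the four small-sample-size discriminant extractors by name
#'
#' @param method One of `"ALDA"`, `"CLDA"`, `"MLDA"`, `"NLDA"`.
#' @inheritParams fit_alda
#' @return A `projection_model`.
#' @export
fit_extractor <- function(method, X, y, d = NULL, rank_tolerance = NULL) {
  method <- toupper(method)
  switch(method,
         ALDA = fit_alda(X, y, d, rank_tolerance),
         CLDA = fit_clda(X, y, d, rank_tolerance),
         MLDA = fit_mlda(X, y, d, rank_tolerance),
         NLDA = fit_nlda(X, y, d, rank_tolerance),
         stop("unknown extractor: ", method, call. = FALSE))
}

#' Extractor method names
#' @return `c("ALDA", "CLDA", "MLDA", "NLDA")`.
#' @export
extractor_methods <- function() c("ALDA", "CLDA", "MLDA", "NLDA")

#' Project samples onto fitted discriminant directions
#'
#' Scores are `(X - grand_mean_train) W`: the centering uses the training
#' grand mean stored in the model, matching the fit.
#'
#' @param model A `projection_model`.
#' @param X Numeric matrix (or [spectra_set()]) with the training wavenumber
#'   count.
#' @return An `n x d` score matrix with columns `comp_1 ... comp_d`.
#' @export
project <- function(model, X) UseMethod("project")

#' @export
project.projection_model <- function(model, X) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X)
  if (ncol(X) != length(model$grand_mean)) {
    stop("X has ", ncol(X), " columns; model was fitted on ",
         length(model$grand_mean), call. = FALSE)
  }
  scores <- sweep(X, 2, model$grand_mean) %*% model$W
  colnames(scores) <- paste0("comp_", seq_len(ncol(scores)))
  scores
}

#' Projected scores as a tidy table
#'
#' @param model A `projection_model`.
#' @param data A [spectra_set()].
#' @return A tibble with `sample_id`, `label` and one `comp_*` column per
#'   discriminant component — the data behind score scatter plots.
#' @export
project_scores <- function(model, data) {
  validate_spectra_set(data)
  scores <- project(model, data$absorbance)
  dplyr::bind_cols(
    tibble::tibble(sample_id = data$sample_ids, label = data$labels),
    tibble::as_tibble(scores)
  )
}
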