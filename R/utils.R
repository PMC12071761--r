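#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Run `code` under a given seed, restoring the caller's RNG state afterwards,
# so library functions never clobber user-level reproducibility.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fix eigenvector sign: largest-magnitude entry of each column made positive.
# Deterministic tie-break: the first of the tied entries decides.
fix_signs <- function(W) {
  if (!length(W)) return(W)
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Normalize matrix columns to unit Euclidean length.
unit_cols <- function(W) {
  if (!length(W)) return(W)
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# Default relative rank tolerance: a singular value sigma is treated as zero
# when sigma <= rank_tolerance * sigma_max, with rank_tolerance =
# max(p, n) * .Machine$double.eps unless overridden.
default_rank_tol <- function(n, p) max(p, n) * .Machine$double.eps
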