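#' Construct a labeled spectra set
#'
#' The universal exchange object of the package: a wavenumber grid, an
#' absorbance matrix (one row per sample), a storage-time class label per
#' sample and a unique sample identifier per sample.
#'
#' @param wavenumbers Numeric vector of strictly increasing wavenumbers
#'   (cm^-1), one per absorbance column.
#' @param absorbance Numeric matrix, `n_samples x n_wavenumbers`, unitless
#'   absorbance. All values must be finite.
#' @param labels Character (or factor) vector of per-sample class labels.
#' @param sample_ids Character vector of unique per-sample identifiers.
#'   Defaults to `"s1", "s2", ...`.
#'
#' @return An object of class `spectra_set`.
#' @examples
#' s <- spectra_set(c(4000, 4100, 4200),
#'                  matrix(rnorm(6), nrow = 2),
#'                  labels = c("0h", "6h"))
#' n_samples(s)
#' @export
spectra_set <- function(wavenumbers, absorbance, labels,
                        sample_ids = paste0("s", seq_len(nrow(absorbance)))) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  x <- structure(
    list(
      wavenumbers = as.numeric(wavenumbers),
      absorbance = absorbance,
      labels = as.character(labels),
      sample_ids = as.character(sample_ids)
    ),
    class = "spectra_set"
  )
  validate_spectra_set(x)
}

#' Validate a spectra set's invariants
#'
#' Checks the shape agreement between grid, matrix, labels and ids, the
#' strict monotonicity of the wavenumber grid, finiteness of absorbances and
#' uniqueness of sample identifiers.
#'
#' @param x A `spectra_set`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  n <- nrow(x$absorbance)
  p <- ncol(x$absorbance)
  if (length(x$wavenumbers) != p) {
    stop("absorbance has ", p, " columns but there are ",
         length(x$wavenumbers), " wavenumbers", call. = FALSE)
  }
  if (length(x$labels) != n || length(x$sample_ids) != n) {
    stop("labels (", length(x$labels), ") and sample_ids (",
         length(x$sample_ids), ") must both have length ", n, call. = FALSE)
  }
  if (p >= 2 && any(diff(x$wavenumbers) <= 0)) {
    bad <- which(diff(x$wavenumbers) <= 0)[1]
    stop("non-increasing wavenumbers at position ", bad + 1,
         " (", x$wavenumbers[bad], " then ", x$wavenumbers[bad + 1], ")",
         call. = FALSE)
  }
  if (n > 0 && !all(is.finite(x$absorbance))) {
    bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance at row ", bad[1], ", column ", bad[2],
         call. = FALSE)
  }
  if (anyDuplicated(x$sample_ids)) {
    stop("duplicate sample_id: ",
         x$sample_ids[anyDuplicated(x$sample_ids)], call. = FALSE)
  }
  x
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " wavenumbers", sep = "")
  if (length(x$wavenumbers)) {
    cat(" (", min(x$wavenumbers), "-", max(x$wavenumbers), " cm-1)", sep = "")
  }
  cat("\n")
  tab <- table(x$labels)
  if (length(tab)) {
    cat("classes:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
n_samples <- function(x) UseMethod("n_samples")
#' @export
n_samples.spectra_set <- function(x) nrow(x$absorbance)

#' Subset a spectra set by sample index
#' @param x A `spectra_set`.
#' @param i Integer or logical row index.
#' @param ... Unused.
#' @return A `spectra_set` containing the selected samples, in order.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
              x$labels[i], x$sample_ids[i])
}

#' Tidy a spectra set into long format
#'
#' @param x A `spectra_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `label`, `wavenumber`,
#'   `absorbance`, one row per (sample, wavenumber) pair.
#' @importFrom tibble as_tibble
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  n <- nrow(x$absorbance)
  p <- ncol(x$absorbance)
  tibble::tibble(
    sample_id = rep(x$sample_ids, each = p),
    label = rep(x$labels, each = p),
    wavenumber = rep(x$wavenumbers, times = n),
    absorbance = as.vector(t(x$absorbance))
  )
}

fmt_wavenumber <- function(w) {
  # headers carry at most 3 decimals; trailing zeros dropped
  sub("\\.?0+$", "", formatC(w, format = "f", digits = 3))
}

#' Read a labeled spectra CSV
#'
#' Expects a header `sample_id,label,<wn1>,<wn2>,...` where the remaining
#' column names are numeric wavenumbers in cm^-1, strictly increasing.
#'
#' @param path Path to a CSV file.
#' @return A validated [spectra_set()]; row order of the file is preserved.
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "sample_id" || header[2] != "label") {
    stop("malformed header: expected it to start with 'sample_id,label'",
         call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wn)) {
    bad <- which(is.na(wn))[1]
    stop("malformed header: non-numeric wavenumber in column ", bad + 2,
         " ('", header[bad + 2], "')", call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = c("character", "character",
                                       rep("numeric", length(wn))))
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(mat) <- NULL
  if (nrow(df) > 0 && !all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing cell at data row ", bad[1], ", column ",
         bad[2] + 2, call. = FALSE)
  }
  spectra_set(wn, mat, df$label, df$sample_id)
}

#' Write a labeled spectra CSV
#'
#' Deterministic byte output for identical input: wavenumber headers are
#' printed with up to 3 decimals, data values with full decimal precision
#' (17 significant digits) so values round-trip bit-exactly.
#'
#' @param data A [spectra_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(data, path) {
  validate_spectra_set(data)
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("sample_id", "label", fmt_wavenumber(data$wavenumbers)),
                  collapse = ",")
  writeLines(header, con)
  n <- nrow(data$absorbance)
  if (n > 0) {
    vals <- matrix(formatC(data$absorbance, format = "g", digits = 17),
                   nrow = n)
    lines <- paste(data$sample_ids, data$labels,
                   apply(vals, 1, paste, collapse = ","), sep = ",")
    writeLines(lines, con)
  }
  invisible(path)
}
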