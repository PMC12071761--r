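#' Specify a preprocessing treatment
#'
#' The six treatments in common chemometric use here are single steps `"SG"`,
#' `"SNV"`, `"MSC"` and the pairwise combinations `"MSC+SG"`, `"SNV+SG"`,
#' `"SNV+MSC"`, applied left to right. `"none"` is the identity.
#'
#' @param method Treatment name (case-insensitive; `" + "` and `"+"` both
#'   accepted), or a character vector of at most two distinct steps.
#' @param sg_window Savitzky-Golay window length in points; odd, >= 3.
#' @param sg_polyorder Savitzky-Golay polynomial degree; `< sg_window`.
#' @param snv_denominator `"sample"` (n-1, the default) or `"population"` (n)
#'   standard deviation in the SNV step.
#' @return A `preprocess_spec` with the ordered step list.
#' @examples
#' preprocess_spec("SNV+MSC")
#' preprocess_spec("SG", sg_window = 15, sg_polyorder = 3)
#' @export
preprocess_spec <- function(method = "none", sg_window = 11, sg_polyorder = 2,
                            snv_denominator = c("sample", "population")) {
  snv_denominator <- match.arg(snv_denominator)
  if (length(method) == 1) {
    steps <- toupper(gsub(" ", "", method))
    steps <- if (steps %in% c("NONE", "")) character(0) else
      strsplit(steps, "+", fixed = TRUE)[[1]]
  } else {
    steps <- toupper(method)
  }
  bad <- setdiff(steps, c("SG", "SNV", "MSC"))
  if (length(bad)) {
    stop("unknown preprocessing step(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(steps) > 2) stop("at most two steps may be combined", call. = FALSE)
  if (anyDuplicated(steps)) stop("repeated preprocessing step", call. = FALSE)
  if (sg_window %% 2 == 0 || sg_window < 3) {
    stop("sg_window must be odd and >= 3", call. = FALSE)
  }
  if (sg_polyorder >= sg_window || sg_polyorder < 0) {
    stop("sg_polyorder must be in [0, sg_window)", call. = FALSE)
  }
  structure(list(steps = steps, sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 snv_denominator = snv_denominator),
            class = "preprocess_spec")
}

#' The six standard preprocessing treatments plus the identity
#' @return Character vector of treatment names accepted by [preprocess_spec()].
#' @export
preprocess_methods <- function() {
  c("SG", "SNV", "MSC", "MSC+SG", "SNV+SG", "SNV+MSC")
}

#' Standard normal variate transform of one spectrum
#'
#' Centers and scales a single spectrum to zero mean and unit standard
#' deviation, removing per-sample additive offsets and multiplicative gains
#' caused by light scattering.
#'
#' @param x Numeric spectrum of length >= 2.
#' @param denominator `"sample"` (n-1) or `"population"` (n) SD.
#' @return The standardized spectrum.
#' @export
snv_transform <- function(x, denominator = c("sample", "population")) {
  denominator <- match.arg(denominator)
  if (length(x) < 2) stop("spectrum must have length >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (denominator == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) {
    stop("degenerate spectrum: zero variance, SNV undefined", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Fit an MSC reference spectrum
#'
#' The multiplicative scatter correction reference is the column mean of the
#' training absorbance matrix. Fitting on the training fold only keeps the
#' train/test contract leak-free.
#'
#' @param train A [spectra_set()] with at least one spectrum.
#' @return Numeric reference spectrum (length = wavenumber count).
#' @export
msc_fit <- function(train) {
  validate_spectra_set(train)
  if (nrow(train$absorbance) < 1) stop("need >= 1 training spectrum", call. = FALSE)
  colMeans(train$absorbance)
}

#' Apply multiplicative scatter correction to one spectrum
#'
#' Ordinary least squares of the spectrum on the reference,
#' `x ~ a + b * reference`, then inversion of the fitted affine distortion:
#' `(x - a) / b`.
#'
#' @param x Numeric spectrum.
#' @param reference Reference spectrum of equal length, non-constant.
#' @return The corrected spectrum.
#' @export
msc_apply <- function(x, reference) {
  if (length(x) != length(reference)) {
    stop("spectrum and reference lengths differ", call. = FALSE)
  }
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) stop("constant reference spectrum", call. = FALSE)
  b <- sum(rc * (x - mean(x))) / den
  a <- mean(x) - b * mean(reference)
  if (abs(b) < 1e-8) {
    stop("uncorrectable spectrum: fitted slope ", format(b),
         " too close to zero", call. = FALSE)
  }
  (x - a) / b
}

#' Savitzky-Golay smoothing of one spectrum
#'
#' Each point is replaced by the center value of a least-squares polynomial
#' fit over a sliding window. Boundaries are handled by mirror padding
#' (reflection about the end points, excluding the end point itself) by
#' `(window - 1)/2` points, so output length equals input length.
#'
#' @param x Numeric spectrum.
#' @param window Odd window length, `3 <= window <= length(x)`.
#' @param polyorder Polynomial degree, `< window`.
#' @return The smoothed spectrum.
#' @export
sg_smooth <- function(x, window = 11, polyorder = 2) {
  n <- length(x)
  if (window %% 2 == 0 || window < 3 || window > n) {
    stop("window must be odd and in [3, length(x)]", call. = FALSE)
  }
  if (polyorder >= window || polyorder < 0) {
    stop("polyorder must be in [0, window)", call. = FALSE)
  }
  h <- (window - 1L) / 2L
  # center row of the least-squares projection matrix
  kernel <- signal::sgolay(p = polyorder, n = window)[h + 1L, ]
  padded <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  smoothed <- stats::filter(padded, rev(kernel), sides = 2)
  as.numeric(smoothed[(h + 1L):(h + n)])
}

#' Fit a preprocessing chain on a training fold and apply it to both folds
#'
#' Steps run in the listed order. Any MSC reference is fitted on the training
#' fold only and reused for the test fold — transforming the same test set
#' against different training folds therefore gives different outputs, and no
#' test information reaches the fit.
#'
#' @param spec A [preprocess_spec()].
#' @param train,test [spectra_set()] objects sharing the same wavenumber grid
#'   (`test` may be `NULL`).
#' @return A list with elements `train`, `test` (transformed spectra sets)
#'   and `fit` (a `fitted_preprocessor` holding the spec and, when MSC is in
#'   the chain, the training-mean reference spectrum).
#' @examples
#' s <- simulate_spectra(sim_config(n_classes = 2, samples_per_class = 4,
#'                                  grid_points = 60))
#' out <- fit_apply_chain(preprocess_spec("SNV"), s, s)
#' rowMeans(out$train$absorbance) # ~0 per row
#' @export
fit_apply_chain <- function(spec, train, test = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  validate_spectra_set(train)
  if (!is.null(test)) {
    validate_spectra_set(test)
    if (length(test$wavenumbers) != length(train$wavenumbers) ||
        any(test$wavenumbers != train$wavenumbers)) {
      stop("train and test wavenumber grids differ", call. = FALSE)
    }
  }
  msc_reference <- NULL
  cur_train <- train
  cur_test <- test
  apply_rows <- function(set, f) {
    out <- set
    for (i in seq_len(nrow(set$absorbance))) {
      res <- tryCatch(f(set$absorbance[i, ]), error = function(e) {
        stop("preprocessing failed for sample '", set$sample_ids[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
      out$absorbance[i, ] <- res
    }
    out
  }
  for (step in spec$steps) {
    f <- switch(step,
      SNV = function(x) snv_transform(x, spec$snv_denominator),
      SG = function(x) sg_smooth(x, spec$sg_window, spec$sg_polyorder),
      MSC = {
        msc_reference <- msc_fit(cur_train)
        function(x) msc_apply(x, msc_reference)
      }
    )
    cur_train <- apply_rows(cur_train, f)
    if (!is.null(cur_test)) cur_test <- apply_rows(cur_test, f)
  }
  fit <- structure(list(spec = spec, msc_reference = msc_reference),
                   class = "fitted_preprocessor")
  list(train = cur_train, test = cur_test, fit = fit)
}
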