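#' Specify one Gaussian absorption band
#'
#' A band contributes `base_amplitude * (1 - class_decay)^c` (class index
#' `c = 0, 1, ...`) times a Gaussian profile `exp(-(nu - center)^2 / (2 width^2))`
#' to every spectrum. Decaying amplitudes across classes emulate the loss of
#' water (combination band near 5100 cm^-1) and protein (N-H first overtone,
#' 6000-7000 cm^-1) during cold storage of leafy tissue.
#'
#' @param center Band center, cm^-1.
#' @param width Gaussian sigma, cm^-1; must be positive.
#' @param base_amplitude Class-0 peak absorbance; must be non-negative.
#' @param class_decay Fractional amplitude decrease per class step, in `[0, 1)`.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, width, base_amplitude, class_decay = 0) {
  stopifnot(width > 0, base_amplitude >= 0,
            class_decay >= 0, class_decay < 1)
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude, class_decay = class_decay),
            class = "band_spec")
}

#' Configure the synthetic NIR spectra generator
#'
#' Defaults emulate the study design the package targets: 5 storage-time
#' classes of 60 leaves each, spectra on a 1577-point grid starting at
#' 4000 cm^-1 with 3.856 cm^-1 spacing, and a small-sample-size structure in
#' which discriminative information is reproducible while most within-class
#' variation is broad and unstructured. The signal model has four parts:
#'
#' * **Main bands** — a water combination band near 5100 cm^-1 and an N-H
#'   overtone band near 6500 cm^-1 whose amplitudes decay geometrically with
#'   storage time (monotone moisture/protein loss).
#' * **Stage fingerprints** — a fixed set of narrow bands whose amplitudes
#'   are small, class-specific and non-monotone, emulating stage-specific
#'   composition differences; they give the five classes genuinely
#'   multi-dimensional geometry.
#' * **Constituent variability** (off by default) — per-sample
#'   multiplicative jitter of the main band amplitudes, emulating
#'   leaf-to-leaf variation in water and protein content; a sensitivity
#'   knob that shifts discriminative weight from the main-band trend onto
#'   the fingerprints.
#' * **Smooth backgrounds** — per-sample broad random bumps emulating
#'   wavelength-dependent scatter and tissue heterogeneity that an affine
#'   correction (SNV/MSC) cannot fully remove.
#' * **Scatter artifacts** — per-sample multiplicative gain, linear baseline
#'   drift, additive offset, and per-point noise.
#'
#' @param n_classes Number of storage-time classes.
#' @param samples_per_class Samples per class.
#' @param grid_start First wavenumber, cm^-1.
#' @param grid_spacing Grid spacing, cm^-1; positive.
#' @param grid_points Number of wavenumber points.
#' @param bands List of [band_spec()] objects (the main decaying bands).
#' @param gain_sd SD of the multiplicative scatter gain (gain = 1 + N(0, sd)).
#' @param offset_sd SD of the per-sample additive offset (absorbance).
#' @param drift_sd SD of the per-sample linear baseline slope, absorbance per
#'   1000 cm^-1.
#' @param noise_sd SD of independent per-point additive noise (absorbance).
#' @param band_jitter_sd SD of the per-sample fractional amplitude jitter of
#'   each main band (unitless; amplitude is multiplied by `1 + N(0, sd)`).
#' @param fingerprint_sd SD of the class-specific fingerprint band
#'   amplitudes (absorbance); 0 disables fingerprints.
#' @param fingerprint_bands Number of fingerprint bands.
#' @param fingerprint_width Two-element range (cm^-1) for fingerprint band
#'   sigmas.
#' @param bg_sd SD of the per-sample smooth background bump amplitudes
#'   (absorbance); 0 disables backgrounds.
#' @param bg_bumps Number of background bumps per sample.
#' @param bg_width Two-element range (cm^-1) for background bump sigmas.
#' @param seed Integer seed; the whole generation consumes one seeded stream.
#' @return A `synthetic_config` list.
#' @examples
#' cfg <- sim_config()
#' cfg$n_classes * cfg$samples_per_class # 300 spectra
#' @export
sim_config <- function(n_classes = 5,
                       samples_per_class = 60,
                       grid_start = 4000,
                       grid_spacing = 3.856,
                       grid_points = 1577,
                       bands = list(
                         band_spec(5100, 150, 0.80, class_decay = 0.06),
                         band_spec(6500, 300, 0.40, class_decay = 0.04)
                       ),
                       gain_sd = 0.10,
                       offset_sd = 0.05,
                       drift_sd = 0.02,
                       noise_sd = 0.002,
                       band_jitter_sd = 0,
                       fingerprint_sd = 0.008,
                       fingerprint_bands = 8,
                       fingerprint_width = c(80, 250),
                       bg_sd = 0.06,
                       bg_bumps = 6,
                       bg_width = c(300, 900),
                       seed = 20250101) {
  stopifnot(n_classes >= 1, samples_per_class >= 1, grid_points >= 1,
            grid_spacing > 0, gain_sd >= 0, offset_sd >= 0,
            drift_sd >= 0, noise_sd >= 0, band_jitter_sd >= 0,
            fingerprint_sd >= 0,
            bg_sd >= 0, fingerprint_bands >= 0, bg_bumps >= 0,
            length(fingerprint_width) == 2, length(bg_width) == 2)
  stopifnot(length(bands) >= 1,
            all(vapply(bands, inherits, logical(1), "band_spec")))
  structure(
    list(n_classes = as.integer(n_classes),
         samples_per_class = as.integer(samples_per_class),
         grid_start = grid_start, grid_spacing = grid_spacing,
         grid_points = as.integer(grid_points), bands = bands,
         gain_sd = gain_sd, offset_sd = offset_sd, drift_sd = drift_sd,
         noise_sd = noise_sd, band_jitter_sd = band_jitter_sd,
         fingerprint_sd = fingerprint_sd,
         fingerprint_bands = as.integer(fingerprint_bands),
         fingerprint_width = as.numeric(fingerprint_width),
         bg_sd = bg_sd, bg_bumps = as.integer(bg_bumps),
         bg_width = as.numeric(bg_width),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Low-artifact variant of a generator configuration
#'
#' Scales every stochastic artifact magnitude (gain, offset, drift, noise,
#' background) by `scale`, leaving the class structure (bands, fingerprints)
#' untouched — the near-ideal-instrument condition.
#'
#' @param config A [sim_config()].
#' @param scale Multiplier applied to the artifact SDs.
#' @return A `synthetic_config`.
#' @export
low_noise_config <- function(config = sim_config(), scale = 0.1) {
  for (f in c("gain_sd", "offset_sd", "drift_sd", "noise_sd", "bg_sd")) {
    config[[f]] <- config[[f]] * scale
  }
  config
}

grid_wavenumbers <- function(config) {
  config$grid_start + config$grid_spacing * (seq_len(config$grid_points) - 1)
}

# Fingerprint geometry and class amplitudes are the FIRST draws of the
# generator's seeded stream, so they can be reproduced independently of the
# per-sample draws that follow.
draw_fingerprints <- function(config, nu) {
  Fb <- config$fingerprint_bands
  if (Fb == 0 || config$fingerprint_sd == 0) {
    # keep the stream aligned with configs that disable fingerprints
    return(matrix(0, config$n_classes, length(nu)))
  }
  span <- max(nu) - min(nu)
  centers <- stats::runif(Fb, min(nu) + 0.1 * span, max(nu) - 0.1 * span)
  widths <- stats::runif(Fb, config$fingerprint_width[1],
                         config$fingerprint_width[2])
  kappa <- matrix(stats::rnorm(config$n_classes * Fb, 0,
                               config$fingerprint_sd),
                  config$n_classes, Fb)
  H <- exp(-outer(centers, nu, function(c, x) (x - c)^2) / (2 * widths^2))
  kappa %*% H                                   # n_classes x p
}

band_profiles <- function(config, nu) {
  vapply(config$bands,
         function(b) exp(-(nu - b$center)^2 / (2 * b$width^2)),
         numeric(length(nu)))                   # p x n_bands
}

band_amplitudes <- function(config, class_index) {
  vapply(config$bands,
         function(b) b$base_amplitude * (1 - b$class_decay)^class_index,
         numeric(1))
}

band_signal <- function(config, nu, class_index) {
  as.vector(band_profiles(config, nu) %*% band_amplitudes(config, class_index))
}

#' Noise-free class mean spectrum of a generator configuration
#'
#' The analytic expected spectrum of a class: decaying main bands plus the
#' class's fingerprint (re-derived from the config seed). This is the signal
#' that [simulate_spectra()] perturbs with per-sample artifacts; useful for
#' oracle checks.
#'
#' @param config A [sim_config()].
#' @param class_index Zero-based class index.
#' @return Numeric vector of length `grid_points`.
#' @export
class_mean_spectrum <- function(config, class_index) {
  nu <- grid_wavenumbers(config)
  fp <- with_preserved_seed(config$seed, draw_fingerprints(config, nu))
  band_signal(config, nu, class_index) + fp[class_index + 1L, ]
}

storage_labels <- function(n_classes) paste0(6 * (seq_len(n_classes) - 1), "h")

#' Generate a synthetic labeled NIR spectra set
#'
#' For sample i of class c (zero-based), the spectrum is
#' `gain_i * signal_c(nu) + slope_i * (nu - grid_start)/1000 + offset_i +
#' bg_i(nu) + eps_i(nu)`, where `signal_c` is the class mean of
#' [class_mean_spectrum()] (main bands plus class fingerprint),
#' `gain ~ 1 + N(0, gain_sd)`, `slope ~ N(0, drift_sd)`,
#' `offset ~ N(0, offset_sd)`, each main band amplitude additionally
#' multiplied by its own `1 + N(0, band_jitter_sd)` draw, `bg_i` is a sum
#' of `bg_bumps` broad Gaussian
#' bumps with random centers/widths and `N(0, bg_sd)` amplitudes, and
#' `eps ~ N(0, noise_sd)` per point. All randomness comes from one stream
#' seeded by `config$seed`, consumed in the fixed order: fingerprints,
#' gains, band jitter, slopes, offsets, background (centers, widths,
#' amplitudes), noise (row-wise) — identical configs give bit-identical output. Labels are
#' storage times `"0h", "6h", ...` in class order.
#'
#' @param config A [sim_config()].
#' @return A [spectra_set()] with `n_classes * samples_per_class` rows.
#' @examples
#' quiet <- sim_config(n_classes = 2, samples_per_class = 3, grid_points = 50,
#'                     gain_sd = 0, offset_sd = 0, drift_sd = 0, noise_sd = 0,
#'                     fingerprint_sd = 0, bg_sd = 0)
#' s <- simulate_spectra(quiet)
#' table(s$labels)
#' @export
simulate_spectra <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_classes * config$samples_per_class
  p <- config$grid_points
  nu <- grid_wavenumbers(config)
  cls <- rep(seq_len(config$n_classes) - 1L, each = config$samples_per_class)

  n_bands <- length(config$bands)
  draws <- with_preserved_seed(config$seed, {
    fp <- draw_fingerprints(config, nu)
    gains <- 1 + stats::rnorm(n, 0, config$gain_sd)
    jitter <- 1 + matrix(stats::rnorm(n * n_bands, 0, config$band_jitter_sd),
                         n, n_bands, byrow = TRUE)
    slopes <- stats::rnorm(n, 0, config$drift_sd)
    offsets <- stats::rnorm(n, 0, config$offset_sd)
    B <- config$bg_bumps
    bg <- matrix(0, n, p)
    if (B > 0 && config$bg_sd > 0) {
      for (i in seq_len(n)) {
        centers <- stats::runif(B, min(nu), max(nu))
        widths <- stats::runif(B, config$bg_width[1], config$bg_width[2])
        coefs <- stats::rnorm(B, 0, config$bg_sd)
        bg[i, ] <- colSums(
          coefs * exp(-outer(centers, nu, function(c, x) (x - c)^2) /
                        (2 * widths^2)))
      }
    }
    noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd), nrow = n,
                    byrow = TRUE)
    list(fp = fp, gains = gains, jitter = jitter, slopes = slopes,
         offsets = offsets, bg = bg, noise = noise)
  })

  profiles <- band_profiles(config, nu)          # p x n_bands
  amp_by_class <- vapply(seq_len(config$n_classes) - 1L,
                         function(c) band_amplitudes(config, c),
                         numeric(n_bands))       # n_bands x K
  amp_by_class <- matrix(amp_by_class, nrow = n_bands)
  # per-sample jittered band amplitudes, then bands recombined
  sample_amps <- t(amp_by_class[, cls + 1L, drop = FALSE]) * draws$jitter
  class_signal <- sample_amps %*% t(profiles) +
    draws$fp[cls + 1L, , drop = FALSE]

  drift_basis <- (nu - config$grid_start) / 1000
  absorb <- draws$gains * class_signal +
    outer(draws$slopes, drift_basis) +
    draws$offsets +
    draws$bg +
    draws$noise

  lab <- storage_labels(config$n_classes)[cls + 1L]
  ids <- sprintf("%s_%02d", lab, rep(seq_len(config$samples_per_class),
                                     times = config$n_classes))
  spectra_set(nu, absorb, lab, ids)
}
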