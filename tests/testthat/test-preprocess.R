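test_that("SNV standardizes a spectrum and is scatter-invariant", {
  expect_equal(snv_transform(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv_transform(rep(2, 10)), "zero variance")
  expect_error(snv_transform(3), "length")

  set.seed(1)
  x <- rnorm(200)
  out <- snv_transform(x)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(stats::sd(out), 1, tolerance = 1e-12)
  # affine invariance: snv(a + b x) == snv(x) for b > 0
  expect_equal(snv_transform(2.5 + 1.7 * x), out, tolerance = 1e-10)
  # population-SD variant differs by the finite-sample factor
  expect_equal(snv_transform(x, "population"),
               out * sqrt(200 / 199), tolerance = 1e-12)
})

test_that("MSC reference is the training column mean", {
  r <- seq(0.1, 1, length.out = 20)
  one <- spectra_set(seq_len(20), matrix(r, nrow = 1), labels = "a")
  expect_equal(msc_fit(one), r)
  two <- spectra_set(seq_len(20), rbind(r, 3 * r), labels = c("a", "b"))
  expect_equal(msc_fit(two), 2 * r)

  set.seed(2)
  many <- spectra_set(seq_len(15), matrix(rnorm(90), nrow = 6),
                      labels = rep(c("a", "b"), 3))
  expect_equal(msc_fit(many), apply(many$absorbance, 2, mean))
})

test_that("MSC inverts affine distortions and matches the OLS oracle", {
  set.seed(3)
  ref <- 0.5 * exp(-(seq(4000, 6000, length.out = 80) - 5100)^2 / (2 * 150^2))
  expect_equal(msc_apply(ref, ref), ref, tolerance = 1e-12)
  expect_equal(msc_apply(2 * ref + 3, ref), ref, tolerance = 1e-12)

  distorted <- 1.4 * ref + 0.2 + rnorm(80, 0, 0.005)
  corrected <- msc_apply(distorted, ref)
  fit <- stats::lm(distorted ~ ref)
  expect_equal(corrected, (distorted - coef(fit)[1]) / coef(fit)[2],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(corrected - ref)), 0.02)

  expect_error(msc_apply(rnorm(80), rep(1, 80)), "constant reference")
  expect_error(msc_apply(rnorm(3), rnorm(4)), "lengths")
})

test_that("MSC is idempotent for a fixed reference", {
  set.seed(4)
  ref <- cumsum(rnorm(60))
  x <- 1.3 * ref + 0.5 + rnorm(60, 0, 0.1)
  once <- msc_apply(x, ref)
  expect_equal(msc_apply(once, ref), once, tolerance = 1e-8)
})

test_that("Savitzky-Golay reproduces polynomials and matches the oracle", {
  ramp <- seq(0, 5, length.out = 40)
  interior <- 6:35
  expect_equal(sg_smooth(ramp, 11, 2)[interior], ramp[interior],
               tolerance = 1e-10)
  expect_equal(sg_smooth(rep(1.5, 40), 11, 2), rep(1.5, 40),
               tolerance = 1e-10)
  # interpolating fit (polyorder = window - 1) is the identity on interior
  set.seed(5)
  x <- rnorm(30)
  expect_equal(sg_smooth(x, 5, 4)[3:28], x[3:28], tolerance = 1e-8)

  # brute-force per-window least squares, including mirrored edges
  x <- rnorm(50)
  expect_equal(sg_smooth(x, 11, 2), oracle_sg(x, 11, 2), tolerance = 1e-9)
  expect_equal(sg_smooth(x, 7, 3), oracle_sg(x, 7, 3), tolerance = 1e-9)

  expect_error(sg_smooth(x, 10, 2), "odd")
  expect_error(sg_smooth(x, 11, 11), "polyorder")
  expect_error(sg_smooth(x[1:5], 7, 2), "odd|length")
})

test_that("preprocess_spec parses treatment names and validates", {
  expect_equal(preprocess_spec("SNV+MSC")$steps, c("SNV", "MSC"))
  expect_equal(preprocess_spec("msc + sg")$steps, c("MSC", "SG"))
  expect_equal(preprocess_spec("none")$steps, character(0))
  expect_error(preprocess_spec("SNV+SNV"), "repeated")
  expect_error(preprocess_spec("OSC"), "unknown")
  expect_error(preprocess_spec("SG", sg_window = 8), "odd")
  expect_length(preprocess_methods(), 6L)
})

test_that("fit_apply_chain applies steps in order with train-only fitting", {
  cfg <- sim_config(samples_per_class = 6, grid_points = 150)
  s <- simulate_spectra(cfg)
  plan <- stratified_kfold(s$labels, 3, seed = 7)
  tr <- s[plan$assignments != 1]
  te <- s[plan$assignments == 1]

  out <- fit_apply_chain(preprocess_spec("SNV"), tr, te)
  expect_equal(unname(rowMeans(out$train$absorbance)),
               rep(0, n_samples(tr)), tolerance = 1e-10)
  expect_equal(unname(apply(out$test$absorbance, 1, stats::sd)),
               rep(1, n_samples(te)), tolerance = 1e-10)

  # MSC + SG equals msc_apply then sg_smooth composed row-wise
  spec <- preprocess_spec("MSC+SG")
  out2 <- fit_apply_chain(spec, tr, te)
  ref <- msc_fit(tr)
  manual <- t(apply(te$absorbance, 1,
                    function(x) sg_smooth(msc_apply(x, ref), 11, 2)))
  expect_equal(out2$test$absorbance, manual, tolerance = 1e-12)
  expect_equal(out2$fit$msc_reference, ref)

  # leakage check: the same test fold transformed against two different
  # training folds gives different outputs (train-fitted MSC reference)
  tr2 <- s[plan$assignments != 2]
  alt <- fit_apply_chain(preprocess_spec("MSC"), tr2, te)
  base <- fit_apply_chain(preprocess_spec("MSC"), tr, te)
  expect_gt(max(abs(alt$test$absorbance - base$test$absorbance)), 0)

  # errors are annotated with the offending sample
  bad <- tr
  bad$absorbance[3, ] <- 1
  expect_error(fit_apply_chain(preprocess_spec("SNV"), bad),
               bad$sample_ids[3])
})
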