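# Stimulus synthesis: pink-noise statistics, Gaussian bandpass calibration,
# RMS-contrast normalization, spatial envelope, radial spectra.

test_that("pink noise is seeded-deterministic, zero-mean and unit-RMS", {
  p1 <- make_pink_noise(64, 6.5 / 64, seed = 1)
  p2 <- make_pink_noise(64, 6.5 / 64, seed = 1)
  p3 <- make_pink_noise(64, 6.5 / 64, seed = 2)
  expect_identical(p1$pixels, p2$pixels)
  expect_false(identical(p1$pixels, p3$pixels))
  expect_lt(abs(mean(p1$pixels)), 1e-12)
  expect_equal(sqrt(mean(p1$pixels^2)), 1, tolerance = 1e-12)
  expect_error(make_pink_noise(4), class = "fovealmask_invalid_argument")
  expect_error(make_pink_noise(64, -1), class = "fovealmask_invalid_argument")
})

test_that("pink noise has ~1/f radial amplitude spectrum", {
  slopes <- vapply(1:20, function(s) {
    p <- make_pink_noise(64, 6.5 / 64, seed = s)
    sp <- radial_amplitude_spectrum(p)
    nyq <- 1 / (2 * p$deg_per_px)
    sp <- sp[sp$freq_cpd > 0 & sp$freq_cpd < 0.8 * nyq, ]
    unname(coef(lm(log(amplitude) ~ log(freq_cpd), data = sp))[2])
  }, numeric(1))
  expect_equal(mean(slopes), -1, tolerance = 0.1)
})

test_that("band gain is 1 at center and halves at the 0.8-octave edges", {
  expect_equal(band_gain(3.6, 3.6), 1)
  expect_equal(band_gain(3.6 * 2^0.8, 3.6, 1.6), 0.5, tolerance = 1e-12)
  expect_equal(band_gain(3.6 * 2^-0.8, 3.6, 1.6), 0.5, tolerance = 1e-12)
  expect_equal(band_gain(0, 3.6), 0)
  # alternative +-1 SD convention
  expect_equal(band_gain(3.6 * 2^0.8, 3.6, 1.6, convention = "sd"),
               exp(-1 / 2), tolerance = 1e-12)
  # measured FWHM on a dense grid is the configured bandwidth
  up <- uniroot(function(f) band_gain(f, 3.6) - 0.5, c(3.6, 20), tol = 1e-12)$root
  lo <- uniroot(function(f) band_gain(f, 3.6) - 0.5, c(0.5, 3.6), tol = 1e-12)$root
  expect_equal(log2(up / lo), 1.6, tolerance = 1e-8)
})

test_that("extreme bands have negligible gain overlap", {
  # geometric middle region between the LSF and HSF centers
  f_mid <- sqrt(0.9 * 12.5) * 2^seq(-0.5, 0.5, length.out = 101)
  prod_gain <- band_gain(f_mid, 0.9) * band_gain(f_mid, 12.5)
  expect_lt(max(prod_gain), 1e-3)
  # overlap energy below 1% of either band's energy (log2-frequency axis)
  u <- seq(-8, 8, by = 0.001)
  g_l <- band_gain(2^u, 0.9); g_h <- band_gain(2^u, 12.5)
  expect_lt(sum(g_l * g_h) / sqrt(sum(g_l^2) * sum(g_h^2)), 0.01)
})

test_that("bandpass rejects center frequencies at or above Nyquist", {
  p <- make_pink_noise(32, 6.5 / 32, seed = 1)
  expect_error(bandpass_gaussian_log2(p, 1 / (2 * p$deg_per_px)),
               class = "fovealmask_invalid_argument")
})

test_that("RMS-contrast calibration is exact, idempotent and guarded", {
  p <- make_pink_noise(64, 6.5 / 64, seed = 3)
  q <- set_rms_contrast(p, 0.20, 71)
  n <- length(q$pixels)
  rms <- sqrt(mean((q$pixels - mean(q$pixels))^2)) / 71
  expect_equal(rms, 0.20, tolerance = 1e-9)
  expect_equal(mean(q$pixels), 71, tolerance = 1e-9)
  q2 <- set_rms_contrast(q, 0.20, 71)
  expect_equal(q$pixels, q2$pixels, tolerance = 1e-12)
  flat <- set_rms_contrast(p, 0, 71)
  expect_true(all(flat$pixels == 71))
  expect_error(set_rms_contrast(flat, 0.2, 71),
               class = "fovealmask_degenerate_input")
})

test_that("Gaussian envelope attenuates deviations by exp(-r^2/2sd^2)", {
  n <- 65
  dpp <- 6.5 / n
  p <- set_rms_contrast(make_pink_noise(n, dpp, seed = 4), 0.2, 71)
  e <- apply_gaussian_envelope(p, sd_deg = 1)
  dev0 <- p$pixels - 71; dev1 <- e$pixels - 71
  c0 <- floor(n / 2) + 1
  expect_equal(dev1[c0, c0], dev0[c0, c0])  # center untouched
  # pixel one envelope SD to the right of center
  j <- c0 + round(1 / dpp)
  r <- (j - c0) * dpp
  expect_equal(dev1[c0, j], dev0[c0, j] * exp(-r^2 / 2), tolerance = 1e-12)
  # corner of a 6.5 deg patch: gain < 1%
  expect_lt(abs(dev1[1, 1] / dev0[1, 1]), 0.01)
  expect_error(apply_gaussian_envelope(p, 0), class = "fovealmask_invalid_argument")
})

test_that("radial spectrum localizes a pure grating and is flat for white noise", {
  n <- 65; dpp <- 0.1
  f0 <- 20 / (n * dpp)  # exactly on the annulus grid, ~3 cpd
  xdeg <- (seq_len(n) - 1) * dpp
  g <- noise_patch(matrix(sin(2 * pi * f0 * xdeg), n, n, byrow = TRUE), dpp)
  sp <- radial_amplitude_spectrum(g)
  expect_equal(radial_spectrum_peak(sp), f0, tolerance = 1e-9)
  # white noise: annulus means deviate little from their average
  amp <- NULL
  for (s in 1:20) {
    w <- noise_patch(matrix(rnorm(32 * 32), 32, 32), 6.5 / 32)
    r <- radial_amplitude_spectrum(w)
    amp <- if (is.null(amp)) r$amplitude else amp + r$amplitude
  }
  a <- amp[r$freq_cpd > 0] / 20
  expect_lt(sd(a) / mean(a), 0.1)
})

test_that("calibrated band patches peak at their nominal center frequency", {
  sum_amp <- NULL
  for (s in 1:20) {
    p <- make_band_noise("msf", seed = s, envelope_sd_deg = NULL)
    r <- radial_amplitude_spectrum(p)
    sum_amp <- if (is.null(sum_amp)) r$amplitude else sum_amp + r$amplitude
  }
  r$amplitude <- sum_amp
  annulus <- 1 / 6.5
  expect_lt(abs(radial_spectrum_peak(r, refine = "quadratic") - 3.6), annulus)
})

test_that("noise patches round-trip to PNG with a calibration sidecar", {
  p <- make_band_noise("lsf", seed = 1, side_px = 64, rms = 0.2)
  path <- file.path(withr::local_tempdir(), "lsf.png")
  write_noise_patch(p, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$center_freq_cpd, 0.9)
  expect_equal(meta$rms_contrast, 0.2)
  expect_equal(meta$side_px, 64)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(64, 64))
})
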