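# Behavioral-oscillation spectra: taper, DFT against a direct-summation
# oracle, frequency-grid contract, Parseval, and the permutation tests.

# independent direct-summation DFT amplitude (no fft), amplitude scale
direct_amplitude <- function(x, w, pad_n, k) {
  xt <- c(x * w, rep(0, pad_n - length(x)))
  n <- length(xt)
  a <- vapply(k, function(kk) {
    re <- sum(xt * cos(2 * pi * kk * (0:(n - 1)) / n))
    im <- -sum(xt * sin(2 * pi * kk * (0:(n - 1)) / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  2 * a / sum(w)
}

test_that("the Hanning taper matches the signal-processing reference", {
  skip_if_not_installed("signal")
  for (n in c(8, 34, 151)) {
    expect_equal(hanning_taper(n), as.numeric(signal::hanning(n)),
                 tolerance = 1e-12)
  }
})

test_that("amplitude spectrum follows its contracts", {
  fm <- 25 / 3
  expect_equal(amplitude_spectrum(rep(0, 34), fm)$amplitude, rep(0, 26))
  expect_error(amplitude_spectrum(rnorm(34) - 10, fm),
               class = "fovealmask_invalid_argument")  # not centered
  expect_error(amplitude_spectrum(mean_center(rnorm(5)), fm),
               class = "fovealmask_invalid_argument")
  # default grid: ~0.79 Hz spacing, capped at 20 Hz
  x <- mean_center(rnorm(34))
  sp <- amplitude_spectrum(x, fm)
  expect_true(diff(sp$freq_hz[1:2]) > 0.78 && diff(sp$freq_hz[1:2]) < 0.80)
  expect_lte(max(sp$freq_hz), 20)
  expect_true(all(sp$amplitude >= 0))
})

test_that("a grid-frequency cosine without taper/pad yields one spectral line", {
  fm <- 25 / 3; n <- 34
  f0 <- 4 / (n * fm / 1000)
  x <- mean_center(cos(2 * pi * f0 * (0:(n - 1)) * fm / 1000))
  sp <- amplitude_spectrum(x, fm, pad_to_frames = n, taper = "none",
                           max_freq_hz = Inf)
  on_line <- abs(sp$freq_hz - f0) < 1e-9
  expect_equal(sp$amplitude[on_line], 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[!on_line]), 1e-9)
})

test_that("tapered padded amplitudes match a direct-summation DFT oracle", {
  set.seed(3)
  x <- mean_center(rnorm(34))
  sp <- amplitude_spectrum(x, 25 / 3)
  oracle <- direct_amplitude(x, hanning_taper(34), 151,
                             seq_along(sp$freq_hz) - 1)
  oracle[1] <- oracle[1] / 2
  expect_equal(sp$amplitude, oracle, tolerance = 1e-9)
})

test_that("a 5 Hz modulation on the TPO grid is recovered at the peak", {
  fm <- 25 / 3
  t <- (0:33) * fm / 1000
  x <- mean_center(cos(2 * pi * 5 * t))
  sp <- amplitude_spectrum(x, fm)
  expect_lt(abs(spectrum_peak_freq(sp) - 5), diff(sp$freq_hz[1:2]) + 1e-9)
})

test_that("untapered unpadded energy spectrum satisfies Parseval", {
  x <- mean_center(rnorm(32))
  sp <- amplitude_spectrum(x, 25 / 3, pad_to_frames = 32, taper = "none",
                           max_freq_hz = Inf, scale = "energy")
  expect_equal(sum(sp$amplitude^2), sum(x^2), tolerance = 1e-9)
})

test_that("spectrum permutation test flags a strong generative oscillation", {
  d <- tiny_design(n_per_noise = 600)
  tr <- simulate_sessions(d, osc_only_observer(amp = 1.2), 12, seed = 6)
  r <- spectrum_permutation_test(tr, "lsf", design = d, n_perm = 300, seed = 7)
  r2 <- spectrum_permutation_test(tr, "lsf", design = d, n_perm = 300, seed = 7)
  expect_equal(r$p, r2$p)  # deterministic
  step <- diff(r$freq_hz[1:2])
  near5 <- abs(r$freq_hz - 5) <= step + 1e-9
  expect_true(any(r$significant[near5]))
  expect_gte(min(r$p), 1 / (300 + 1))
})

test_that("spectral peak comparison is antisymmetric and detects asymmetry", {
  d <- tiny_design(n_per_noise = 150, bands = c("lsf", "msf"))
  tr <- simulate_sessions(d, flat_observer(), 6, seed = 8)
  ab <- compare_spectrum_peaks(tr, "lsf", "msf", design = d, n_perm = 200,
                               seed = 9)
  ba <- compare_spectrum_peaks(tr, "msf", "lsf", design = d, n_perm = 200,
                               seed = 9)
  expect_equal(ab$observed_diff, -ba$observed_diff)
  expect_equal(ab$p_scalar, ba$p_scalar)
  expect_gt(ab$p_scalar, 0.2)
  # a band with a strong oscillation beats a flat band in peak amplitude
  d2 <- tiny_design(n_per_noise = 600, bands = c("lsf", "msf"))
  pp <- observer_params(dip_depth = 0, osc_amp = c(lsf = 1.2, msf = 0, hsf = 0),
                        simultaneity_cost = 0, lapse = 0)
  hits <- 0
  for (i in 1:5) {
    tr2 <- simulate_sessions(d2, pp, 10, seed = 60 + i)
    r <- compare_spectrum_peaks(tr2, "lsf", "msf", design = d2, n_perm = 300,
                                seed = 70 + i)
    hits <- hits + (r$p_scalar <= 0.05 && r$observed_diff > 0)
  }
  expect_gte(hits, 4)
})
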