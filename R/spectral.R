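# Behavioral-oscillation analysis: Hanning-tapered, zero-padded amplitude
# spectra of centered TPO series, permutation tests on the amplitudes, and
# between-band peak-amplitude comparisons.

#' Hanning (raised-cosine) taper
#'
#' @param n taper length
#' @return numeric vector `0.5 * (1 - cos(2 pi k / (n - 1)))`, k = 0..n-1
#' @export
hanning_taper <- function(n) {
  if (n < 2) return(rep(1, n))
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# complex DFT operator restricted to the first `nk` frequencies of an
# n-point transform, acting on a series of length L (i.e. implicit zero
# padding to n); optionally pre-multiplied by a taper
dft_operator <- function(L, pad_n, nk, taper_w = rep(1, L)) {
  k <- 0:(nk - 1)
  M <- exp(-2i * pi * outer(k, 0:(L - 1)) / pad_n)
  sweep(M, 2, taper_w, `*`)
}

#' Amplitude spectrum of a centered TPO series
#'
#' The series is multiplied by a Hanning taper of its own length,
#' zero-padded, discrete-Fourier transformed, and the modulus reported on
#' the grid k / (pad * frame) up to `max_freq_hz`. The default padding of
#' 151 frames at 8.33 ms gives a grid spacing of ~0.79 Hz. The default
#' `"amplitude"` scale is 2|X|/sum(taper) (the amplitude of a unit cosine;
#' DC is |X|/sum(taper)); `"raw"` is the plain modulus and `"power"` its
#' square; `"energy"` is |X|/sqrt(n), for which the sum of squares over a
#' full unpadded, untapered grid equals the series energy.
#'
#' @param values mean-centered series (|mean| <= 1e-9), at least 8 bins
#' @param frame_ms bin spacing in ms
#' @param pad_to_frames zero-padded transform length (default 151)
#' @param taper "hanning" or "none"
#' @param max_freq_hz highest reported frequency (default 20)
#' @param scale "amplitude", "raw", "power" or "energy"
#' @return a `spectrum_result` tibble with columns `freq_hz`, `amplitude`,
#'   and attributes `taper`, `pad_length_frames`, `frame_ms`
#' @export
amplitude_spectrum <- function(values, frame_ms = 25 / 3, pad_to_frames = 151,
                               taper = c("hanning", "none"),
                               max_freq_hz = 20,
                               scale = c("amplitude", "raw", "power", "energy")) {
  taper <- match.arg(taper); scale <- match.arg(scale)
  L <- length(values)
  if (L < 8) stop_invalid("need at least 8 TPO bins for a spectrum")
  if (abs(mean(values)) > 1e-9)
    stop_invalid("series must be mean-centered before spectral analysis")
  pad_n <- max(pad_to_frames, L)
  w <- if (taper == "hanning") hanning_taper(L) else rep(1, L)
  X <- fft(c(values * w, rep(0, pad_n - L)))
  freq <- (seq_len(pad_n) - 1) / (pad_n * frame_ms / 1000)
  # "energy" keeps the whole transform (so its squared sum is the series
  # energy); other scales report the one-sided grid
  keep <- freq <= max_freq_hz &
    (scale == "energy" | seq_len(pad_n) <= floor(pad_n / 2) + 1)
  amp <- Mod(X[keep])
  amp <- switch(scale,
    amplitude = { a <- 2 * amp / sum(w); a[1] <- a[1] / 2; a },
    raw = amp,
    power = amp^2,
    energy = amp / sqrt(pad_n))
  out <- tibble::tibble(freq_hz = freq[keep], amplitude = amp)
  attr(out, "taper") <- taper
  attr(out, "pad_length_frames") <- pad_n
  attr(out, "frame_ms") <- frame_ms
  class(out) <- c("spectrum_result", class(out))
  out
}

#' Peak frequency of a spectrum (DC excluded)
#'
#' @param spec a `spectrum_result` (or any table with `freq_hz`, `amplitude`)
#' @return frequency in Hz with the maximal amplitude, DC bin excluded
#' @export
spectrum_peak_freq <- function(spec) {
  s <- spec[spec$freq_hz > 0, ]
  s$freq_hz[which.max(s$amplitude)]
}

# amplitude matrix (freq x B) of curve columns, shared by the permutation
# spectral tests
curve_spectra <- function(curves, frame_ms, pad_to_frames, max_freq_hz) {
  L <- nrow(curves)
  pad_n <- max(pad_to_frames, L)
  freq <- (seq_len(pad_n) - 1) / (pad_n * frame_ms / 1000)
  keep <- which(freq <= max_freq_hz & seq_len(pad_n) <= floor(pad_n / 2) + 1)
  w <- hanning_taper(L)
  M <- dft_operator(L, pad_n, length(keep), w)
  amp <- Mod(M %*% curves) * 2 / sum(w)
  amp[1, ] <- amp[1, ] / 2
  list(freq_hz = freq[keep], amp = amp)
}

#' Permutation test on behavioral-oscillation amplitudes
#'
#' The observed statistic is the Hanning-tapered amplitude spectrum of the
#' group centered TPO series; the null spectra come from the same stratified
#' permutation stream as [dip_test()]. Each frequency's critical value is
#' the (1 - alpha) quantile of its permuted amplitudes (one-tailed upper).
#'
#' @inheritParams dip_test
#' @param pad_to_frames zero-padded transform length
#' @param max_freq_hz highest analysed frequency
#' @return a `permutation_result` with `freq_hz`, `observed` amplitudes,
#'   per-frequency `crit` and `p`, and `significant` flags
#' @export
spectrum_permutation_test <- function(trials, noise_band, character_set = NULL,
                                      design = design_spec(), n_perm = 10000,
                                      alpha = 0.05,
                                      perm_mode = c("shuffle_responses",
                                                    "shuffle_soa_labels"),
                                      window_frames = design$noise_dur_frames,
                                      pad_to_frames = 151, max_freq_hz = 20,
                                      min_trials_per_frame = NULL, seed = 1) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 1) stop_invalid("n_perm must be at least 1")
  pc <- perm_condition_curves(trials, noise_band, character_set, design,
                              n_perm, seed, perm_mode, window_frames,
                              min_trials_per_frame)
  sp_obs <- curve_spectra(matrix(pc$observed, ncol = 1), design$frame_ms,
                          pad_to_frames, max_freq_hz)
  sp_null <- curve_spectra(pc$curves, design$frame_ms, pad_to_frames,
                           max_freq_hz)
  obs <- drop(sp_obs$amp)
  crit <- apply(sp_null$amp, 1, quantile, probs = 1 - alpha, names = FALSE)
  p <- vapply(seq_along(obs), function(k)
    perm_p(sp_null$amp[k, ], obs[k], "upper"), numeric(1))
  structure(list(
    statistic = "Hanning-tapered amplitude spectrum of the group centered TPO series",
    noise_band = noise_band, character_set = character_set,
    freq_hz = sp_obs$freq_hz, observed = obs, crit = crit, p = p,
    significant = obs > crit, n_perm = n_perm, alpha = alpha,
    side = "one_tailed_upper", perm_mode = perm_mode, seed = seed,
    n_observers = pc$n_observers
  ), class = "permutation_result")
}

#' Compare peak oscillation amplitudes between two noise bands
#'
#' Statistic: maximum amplitude (DC excluded) of band A's spectrum minus
#' band B's. The null shuffles band labels within observer (the same
#' stream as [compare_noise_strength()]) and recomputes both spectral
#' maxima; the decision uses the central (1 - alpha) interval.
#'
#' @inheritParams compare_noise_strength
#' @param pad_to_frames,max_freq_hz see [spectrum_permutation_test()]
#' @return a `permutation_result` with scalar `observed_diff`, `p_scalar`,
#'   two-sided `crit`, and per-band observed peak amplitudes
#' @export
compare_spectrum_peaks <- function(trials, band_a, band_b,
                                   character_set = NULL,
                                   design = design_spec(), n_perm = 10000,
                                   alpha = 0.05,
                                   window_frames = design$noise_dur_frames,
                                   pad_to_frames = 151, max_freq_hz = 20,
                                   min_trials_per_frame = NULL, seed = 1) {
  if (identical(band_a, band_b)) stop_invalid("band_a and band_b must differ")
  flip <- band_a > band_b
  bands <- if (flip) c(band_b, band_a) else c(band_a, band_b)
  pc <- perm_band_pair_curves(trials, bands[1], bands[2], character_set,
                              design, n_perm, seed, window_frames,
                              min_trials_per_frame)
  if (flip) {
    pc[c("observed_a", "observed_b")] <- pc[c("observed_b", "observed_a")]
    pc[c("curves_a", "curves_b")] <- pc[c("curves_b", "curves_a")]
  }
  fm <- design$frame_ms
  peak_amp <- function(curves) {
    sp <- curve_spectra(curves, fm, pad_to_frames, max_freq_hz)
    col_maxs(sp$amp[sp$freq_hz > 0, , drop = FALSE])
  }
  obs_a <- peak_amp(matrix(pc$observed_a, ncol = 1))
  obs_b <- peak_amp(matrix(pc$observed_b, ncol = 1))
  null_diff <- peak_amp(pc$curves_a) - peak_amp(pc$curves_b)
  stat_obs <- obs_a - obs_b
  structure(list(
    statistic = "peak spectral amplitude difference (band_a - band_b)",
    band_a = band_a, band_b = band_b, character_set = character_set,
    observed_diff = stat_obs, observed_peak_a = obs_a, observed_peak_b = obs_b,
    crit = quantile(null_diff, c(alpha / 2, 1 - alpha / 2), names = FALSE),
    p_scalar = perm_p(null_diff, stat_obs, "two_tailed"),
    null_diff = null_diff, n_perm = n_perm, alpha = alpha,
    side = "two_tailed", seed = seed, n_observers = pc$n_observers
  ), class = "permutation_result")
}
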