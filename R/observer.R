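# Generative observers: an equal-variance SDT observer whose sensitivity is
# transiently (Gaussian dip) and periodically (cosine) reduced by foveal
# noise, and smooth psychometric observers for adaptive-procedure simulation.

#' Parameters of the generative SDT observer
#'
#' The observer performs a same-different judgment under equal-variance
#' signal detection: on "different" trials decision evidence is
#' Normal(d', 1), on "same" trials Normal(0, 1), and the observer responds
#' "different" when evidence exceeds the criterion. Foveal noise reduces the
#' effective d' through a band-specific masking kernel with a transient
#' Gaussian dip (the foveal-feedback window, strongest for low-frequency
#' noise around 220 ms) plus a nonnegative cosine modulation (a ~5 Hz
#' behavioral oscillation), and through a simultaneity cost while noise and
#' target physically overlap.
#'
#' Per-band kernel parameters are given as named numeric vectors with
#' entries `lsf`, `msf`, `hsf` (scalars are recycled).
#'
#' @param d_base baseline sensitivity (d' units, >= 0)
#' @param criterion decision criterion c (evidence units)
#' @param lapse probability of replacing the response with a fair coin
#'   (in [0, 0.2])
#' @param dip_depth peak d' reduction of the transient dip, per band
#' @param dip_center_ms dip center, ms relative to peripheral onset
#' @param dip_sd_ms dip SD in ms
#' @param osc_freq_hz oscillation frequency, per band
#' @param osc_amp peak-to-trough oscillation amplitude in d' units, per band
#' @param osc_phase_rad oscillation phase at t = 0, per band
#' @param simultaneity_cost d' reduction scaled by the fraction of the noise
#'   interval overlapping the target presentation
#' @return an `observer_params` list
#' @export
observer_params <- function(d_base = 1.8, criterion = 0.2, lapse = 0.02,
                            dip_depth = c(lsf = 0.6, msf = 0.2, hsf = 0.2),
                            dip_center_ms = c(lsf = 220, msf = 185, hsf = 190),
                            dip_sd_ms = c(lsf = 25, msf = 25, hsf = 25),
                            osc_freq_hz = c(lsf = 5, msf = 5, hsf = 5),
                            osc_amp = c(lsf = 0.5, msf = 0.25, hsf = 0.1),
                            osc_phase_rad = c(lsf = 0, msf = 0, hsf = 0),
                            simultaneity_cost = 0.4) {
  if (d_base < 0) stop_invalid("d_base must be nonnegative")
  if (lapse < 0 || lapse > 0.2) stop_invalid("lapse must lie in [0, 0.2]")
  per_band <- function(x) {
    bands <- c("lsf", "msf", "hsf")
    if (is.null(names(x))) x <- setNames(rep_len(x, 3), bands)
    if (!all(bands %in% names(x))) stop_invalid("per-band parameter must name lsf, msf, hsf")
    x[bands]
  }
  structure(list(
    d_base = d_base, criterion = criterion, lapse = lapse,
    dip_depth = per_band(dip_depth), dip_center_ms = per_band(dip_center_ms),
    dip_sd_ms = per_band(dip_sd_ms), osc_freq_hz = per_band(osc_freq_hz),
    osc_amp = per_band(osc_amp), osc_phase_rad = per_band(osc_phase_rad),
    simultaneity_cost = simultaneity_cost
  ), class = "observer_params")
}

#' A null observer: flat sensitivity, no masking
#'
#' Convenience constructor for calibration studies: all kernel parameters
#' and the simultaneity cost are zero, so effective d' is constant across
#' SOA. Used to check the false-positive rate of the permutation tests.
#'
#' @inheritParams observer_params
#' @return an `observer_params` list with no masking
#' @export
null_observer <- function(d_base = 1.8, criterion = 0.2, lapse = 0.02) {
  observer_params(d_base = d_base, criterion = criterion, lapse = lapse,
                  dip_depth = 0, osc_amp = 0, simultaneity_cost = 0)
}

#' Instantaneous masking kernel
#'
#' d' reduction exerted by foveal noise of a given band present at time `t_ms`
#' relative to peripheral onset:
#' `dip_depth * exp(-(t - dip_center)^2 / (2 dip_sd^2)) +
#'  osc_amp * (1 + cos(2 pi osc_freq t / 1000 + phase)) / 2`.
#' Both terms are nonnegative.
#'
#' @param params an [observer_params()]
#' @param band "lsf", "msf" or "hsf"
#' @param t_ms time (ms) relative to peripheral onset; vectorized
#' @return d' reduction at each `t_ms`
#' @export
masking_kernel <- function(params, band, t_ms) {
  band <- match.arg(band, c("lsf", "msf", "hsf"))
  dip <- params$dip_depth[band] *
    exp(-(t_ms - params$dip_center_ms[band])^2 / (2 * params$dip_sd_ms[band]^2))
  osc <- params$osc_amp[band] *
    (1 + cos(2 * pi * params$osc_freq_hz[band] * t_ms / 1000 +
               params$osc_phase_rad[band])) / 2
  unname(dip + osc)
}

#' Effective d' on a single trial
#'
#' For a noise trial, the masking kernel is averaged over the noise
#' presentation (sampled at its `noise_dur_frames` frame onsets, mirroring
#' the frame-based pooling of the analysis), a simultaneity cost is added in
#' proportion to the temporal overlap between noise and target, and the
#' result is subtracted from baseline d', clipped at zero. Without a band
#' (`band = "none"`) the baseline d' is returned.
#'
#' @param params an [observer_params()]
#' @param band "none", "lsf", "msf" or "hsf"
#' @param soa_frame noise onset in frames relative to peripheral onset;
#'   vectorized
#' @param design a [design_spec()]
#' @return effective d' (same length as `soa_frame`)
#' @export
trial_dprime <- function(params, band, soa_frame, design = design_spec()) {
  if (identical(band, "none")) return(rep(params$d_base, length(soa_frame)))
  band <- match.arg(band, c("lsf", "msf", "hsf"))
  fr <- design$frame_ms
  dur <- noise_duration_ms(design)
  offsets <- (seq_len(design$noise_dur_frames) - 1) * fr
  soa_ms <- soa_frame * fr
  k <- vapply(soa_ms, function(s) mean(masking_kernel(params, band, s + offsets)),
              numeric(1))
  overlap <- pmax(0, pmin(soa_ms + dur, dur) - pmax(soa_ms, 0)) / dur
  pmax(0, params$d_base - k - params$simultaneity_cost * overlap)
}

#' A smooth psychometric observer for adaptive procedures
#'
#' Accuracy rises monotonically with stimulus contrast from the guess rate
#' to 1 - lapse, following either a Weibull or a cumulative-Gaussian (in
#' log10 contrast) function. The observer is parameterized by the contrast
#' at a stated target accuracy, so simulated procedures can be validated
#' against the known inverse.
#'
#' @param threshold contrast at `target_p` accuracy
#' @param target_p accuracy the threshold refers to (default 0.75)
#' @param slope shape parameter (Weibull beta, or 1/sigma of the Gaussian
#'   in log10 contrast)
#' @param guess_rate lower asymptote (0.5 for same-different)
#' @param lapse upper-asymptote shortfall
#' @param family "weibull" or "cumulative_gaussian"
#' @return a `psych_observer` list
#' @export
psych_observer <- function(threshold = 0.05, target_p = 0.75, slope = 3.5,
                           guess_rate = 0.5, lapse = 0,
                           family = c("weibull", "cumulative_gaussian")) {
  family <- match.arg(family)
  if (threshold <= 0) stop_invalid("threshold must be positive")
  if (target_p <= guess_rate || target_p >= 1 - lapse)
    stop_invalid("target_p must lie strictly between guess_rate and 1 - lapse")
  q <- (target_p - guess_rate) / (1 - guess_rate - lapse)
  scale <- switch(family,
    weibull = threshold / (-log(1 - q))^(1 / slope),
    # location of the Gaussian in log10 contrast
    cumulative_gaussian = log10(threshold) - qnorm(q) / slope
  )
  structure(list(threshold = threshold, target_p = target_p, slope = slope,
                 guess_rate = guess_rate, lapse = lapse, family = family,
                 scale = scale),
            class = "psych_observer")
}

#' True accuracy of a psychometric observer at given contrasts
#'
#' @param observer a [psych_observer()]
#' @param contrast stimulus contrast(s), > 0
#' @return probability correct in [guess_rate, 1 - lapse]
#' @export
observer_accuracy <- function(observer, contrast) {
  g <- observer$guess_rate; l <- observer$lapse
  q <- switch(observer$family,
    weibull = 1 - exp(-(contrast / observer$scale)^observer$slope),
    cumulative_gaussian = pnorm((log10(contrast) - observer$scale) * observer$slope)
  )
  g + (1 - g - l) * q
}

#' Contrast at which a psychometric observer reaches a target accuracy
#'
#' @param observer a [psych_observer()]
#' @param p target accuracy, strictly between guess_rate and 1 - lapse
#' @return contrast
#' @export
observer_inverse <- function(observer, p) {
  g <- observer$guess_rate; l <- observer$lapse
  if (any(p <= g) || any(p >= 1 - l))
    stop_unattainable("target accuracy outside the observer's attainable range")
  q <- (p - g) / (1 - g - l)
  switch(observer$family,
    weibull = observer$scale * (-log(1 - q))^(1 / observer$slope),
    cumulative_gaussian = 10^(observer$scale + qnorm(q) / observer$slope)
  )
}
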