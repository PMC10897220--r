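# From trial records to d' time courses over time relative to peripheral
# onset (TPO): SOA binning, Hautus-corrected d', a 7-frame trailing moving
# average, per-observer mean-centering, and group averaging.

#' Hautus-corrected sensitivity index (d')
#'
#' Log-linear (Hautus) correction applied to the hit and false-alarm rates:
#' `d' = z((hits + 0.5) / (hits + misses + 1)) -
#'       z((false_alarms + 0.5) / (false_alarms + correct_rejections + 1))`
#' with z the standard-normal quantile function. Finite for every count
#' combination, including empty cells (both corrected rates 0.5, d' = 0).
#'
#' @param hits,misses,false_alarms,correct_rejections nonnegative counts;
#'   vectorized
#' @return d' values
#' @examples
#' compute_dprime(50, 50, 50, 50)  # 0
#' compute_dprime(100, 0, 0, 100)  # ~5.17
#' @export
compute_dprime <- function(hits, misses, false_alarms, correct_rejections) {
  if (any(c(hits, misses, false_alarms, correct_rejections) < 0, na.rm = TRUE))
    stop_invalid("counts must be nonnegative")
  qnorm((hits + 0.5) / (hits + misses + 1)) -
    qnorm((false_alarms + 0.5) / (false_alarms + correct_rejections + 1))
}

#' Bin noise trials into per-frame response counts
#'
#' One cell per observer x character condition x noise band x SOA frame,
#' holding hit/miss/false-alarm/correct-rejection counts ("different" is the
#' signal class). Fixation-invalid trials are discarded. Frames whose pooled
#' (across observers) trial count within a condition falls below
#' `min_trials_per_frame` are dropped from all observers symmetrically —
#' the rule generalizes the discarding of an SOA that the display's refresh
#' cycle undersampled.
#'
#' @param trials tibble of trial records (see [simulate_sessions()])
#' @param design a [design_spec()]
#' @param min_trials_per_frame pooled-count threshold; default half the
#'   median pooled per-frame count of the condition
#' @param drop_invalid_fixation discard trials with `fixation_ok = FALSE`
#' @return tibble of SOA cells with count columns `n_hit`, `n_miss`,
#'   `n_fa`, `n_cr`
#' @export
bin_by_soa <- function(trials, design = design_spec(),
                       min_trials_per_frame = NULL,
                       drop_invalid_fixation = TRUE) {
  if (nrow(trials) == 0) {
    warning("no trials to bin; returning empty cell table")
    return(tibble::tibble(observer_id = character(), character_set = character(),
                          noise_band = character(), soa_frame = integer(),
                          n_hit = integer(), n_miss = integer(),
                          n_fa = integer(), n_cr = integer()))
  }
  x <- trials[trials$noise_band != "none", , drop = FALSE]
  if (drop_invalid_fixation) x <- x[x$fixation_ok, , drop = FALSE]
  x <- x[x$soa_frame %in% design$soa_frames, , drop = FALSE]
  cells <- x |>
    dplyr::group_by(.data$observer_id, .data$character_set, .data$noise_band,
                    .data$soa_frame) |>
    dplyr::summarise(
      n_hit = sum(.data$truth == "different" & .data$response == "different"),
      n_miss = sum(.data$truth == "different" & .data$response == "same"),
      n_fa = sum(.data$truth == "same" & .data$response == "different"),
      n_cr = sum(.data$truth == "same" & .data$response == "same"),
      .groups = "drop")
  # symmetric undersampled-frame rule, per condition
  pooled <- cells |>
    dplyr::group_by(.data$character_set, .data$noise_band, .data$soa_frame) |>
    dplyr::summarise(n = sum(.data$n_hit + .data$n_miss + .data$n_fa + .data$n_cr),
                     .groups = "drop_last") |>
    dplyr::mutate(thr = if (is.null(min_trials_per_frame))
      0.5 * median(.data$n) else min_trials_per_frame) |>
    dplyr::ungroup()
  keep <- pooled[pooled$n >= pooled$thr,
                 c("character_set", "noise_band", "soa_frame")]
  dplyr::inner_join(cells, keep,
                    by = c("character_set", "noise_band", "soa_frame"))
}

#' Trailing moving average over TPO
#'
#' Bin t is the unweighted mean of the per-frame series over frames
#' t .. t + window - 1 (a forward/trailing window: the bin labelled 50 ms
#' pools noise onsets from 50 to 108.33 ms). Only full windows are emitted,
#' so a 40-frame series yields 34 bins labelled by their window-start frame.
#'
#' @param values per-frame values, sorted by ascending frame
#' @param window_frames window length in frames (default 7)
#' @return vector of length `length(values) - window_frames + 1` (empty,
#'   with a warning, if the series is shorter than the window)
#' @export
moving_average_tpo <- function(values, window_frames = 7) {
  n <- length(values)
  if (n < window_frames) {
    warning("series shorter than the moving-average window; returning empty")
    return(numeric(0))
  }
  cs <- cumsum(c(0, values))
  (cs[(window_frames + 1):(n + 1)] - cs[1:(n - window_frames + 1)]) / window_frames
}

#' Mean-center a series
#'
#' Subtracts the mean so reductions relative to each observer's overall
#' performance read as negative values.
#'
#' @param values numeric vector with at least one element
#' @return centered vector (mean 0 within 1e-12)
#' @export
mean_center <- function(values) {
  if (length(values) < 1) stop_invalid("need at least one bin to center")
  values - mean(values)
}

#' Unweighted group average of observer time courses
#'
#' @param tc tibble of observer-level time courses with columns
#'   `observer_id`, `character_set`, `noise_band`, `tpo_frame`, `tpo_ms`,
#'   `value` (and optionally `n_trials`)
#' @return group-level tibble (one row per condition x TPO bin) with
#'   `value` the mean across observers
#' @export
group_average <- function(tc) {
  grids <- tc |>
    dplyr::group_by(.data$observer_id, .data$character_set, .data$noise_band) |>
    dplyr::summarise(g = paste(.data$tpo_frame, collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) != 1)
    stop_invalid("observer time courses are on different TPO grids")
  has_n <- "n_trials" %in% names(tc)
  tc |>
    dplyr::group_by(.data$character_set, .data$noise_band, .data$tpo_frame,
                    .data$tpo_ms) |>
    dplyr::summarise(value = mean(.data$value),
                     n_trials = if (has_n) sum(.data$n_trials) else NA_integer_,
                     n_observers = dplyr::n(), .groups = "drop")
}

#' Full d' time-course pipeline
#'
#' Per observer and condition: Hautus d' per SOA frame, a trailing 7-frame
#' moving average pooling temporally overlapping noise presentations into
#' TPO bins, per-observer mean-centering, and an unweighted group average.
#' In `"pooled_counts"` mode the window's trial counts are pooled before a
#' single d' is computed per bin (alternative order of operations).
#'
#' @param trials tibble of trial records
#' @param design a [design_spec()]
#' @param window_frames moving-average window (defaults to the noise
#'   duration in frames)
#' @param center mean-center each observer's TPO series (default TRUE)
#' @param dprime_mode "per_frame" (d' first, then moving average; the
#'   default order) or "pooled_counts"
#' @param min_trials_per_frame see [bin_by_soa()]
#' @return list with `observer` and `group` time-course tibbles
#' @export
dprime_timecourse <- function(trials, design = design_spec(),
                              window_frames = design$noise_dur_frames,
                              center = TRUE,
                              dprime_mode = c("per_frame", "pooled_counts"),
                              min_trials_per_frame = NULL) {
  dprime_mode <- match.arg(dprime_mode)
  cells <- bin_by_soa(trials, design, min_trials_per_frame)
  obs_tc <- cells |>
    dplyr::group_by(.data$observer_id, .data$character_set, .data$noise_band) |>
    dplyr::arrange(.data$soa_frame, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      n_bin <- nrow(d) - window_frames + 1
      if (n_bin < 1) return(tibble::tibble())
      if (dprime_mode == "per_frame") {
        dp <- compute_dprime(d$n_hit, d$n_miss, d$n_fa, d$n_cr)
        v <- moving_average_tpo(dp, window_frames)
      } else {
        w <- function(x) moving_average_tpo(x, window_frames) * window_frames
        v <- compute_dprime(w(d$n_hit), w(d$n_miss), w(d$n_fa), w(d$n_cr))
      }
      nt <- moving_average_tpo(d$n_hit + d$n_miss + d$n_fa + d$n_cr,
                               window_frames) * window_frames
      tibble::tibble(tpo_frame = d$soa_frame[seq_len(n_bin)],
                     value = if (center) mean_center(v) else v,
                     dprime_raw = v, n_trials = as.integer(round(nt)))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(tpo_ms = .data$tpo_frame * design$frame_ms, level = "observer")
  grp <- group_average(obs_tc)
  grp$level <- "group"
  list(observer = obs_tc, group = grp)
}
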