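#' Experiment 1 session design
#'
#' Describes the trial structure of a dense-SOA foveal-masking session:
#' a 120 Hz frame clock, foveal noise presented for 7 frames (58.33 ms),
#' SOAs drawn from a uniform frame grid spanning -25 to 300 ms, and
#' 620 test trials per session (20 no-noise plus 200 per noise band).
#'
#' @param frame_ms display frame duration in ms (default 25/3, i.e. 120 Hz)
#' @param soa_min_ms,soa_max_ms SOA range in ms relative to peripheral onset
#'   (negative = noise first)
#' @param noise_dur_frames foveal noise duration in frames
#' @param n_no_noise no-noise (baseline) trials per session
#' @param n_per_noise trials per noise band per session
#' @param noise_bands character vector of noise bands used
#' @param n_sessions number of sessions per observer
#' @return a `design_spec` list with the above fields plus `soa_frames`,
#'   the integer SOA frame grid
#' @examples
#' d <- design_spec()
#' length(d$soa_frames)  # 40 frames from -25 to 300 ms
#' @export
design_spec <- function(frame_ms = 25 / 3,
                        soa_min_ms = -25, soa_max_ms = 300,
                        noise_dur_frames = 7L,
                        n_no_noise = 20L, n_per_noise = 200L,
                        noise_bands = c("lsf", "msf", "hsf"),
                        n_sessions = 3L) {
  if (frame_ms <= 0) stop_invalid("frame_ms must be positive")
  if (soa_max_ms <= soa_min_ms) stop_invalid("soa_max_ms must exceed soa_min_ms")
  bands <- match.arg(noise_bands, c("lsf", "msf", "hsf"), several.ok = TRUE)
  frames <- seq.int(round(soa_min_ms / frame_ms), round(soa_max_ms / frame_ms))
  structure(list(
    frame_ms = frame_ms,
    soa_min_ms = soa_min_ms, soa_max_ms = soa_max_ms,
    noise_dur_frames = as.integer(noise_dur_frames),
    n_no_noise = as.integer(n_no_noise),
    n_per_noise = as.integer(n_per_noise),
    noise_bands = bands,
    n_sessions = as.integer(n_sessions),
    soa_frames = as.integer(frames)
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Session design:", length(x$soa_frames), "SOA frames of", round(x$frame_ms, 3),
      "ms spanning [", x$soa_min_ms, ",", x$soa_max_ms, "] ms\n")
  cat("  per session:", x$n_no_noise, "no-noise +",
      x$n_per_noise, "x", length(x$noise_bands),
      paste0("(", paste(x$noise_bands, collapse = ", "), ")"),
      "noise trials;", x$n_sessions, "session(s)\n")
  invisible(x)
}

#' Noise duration of a design in ms
#' @param design a [design_spec()]
#' @return scalar ms
#' @export
noise_duration_ms <- function(design) design$noise_dur_frames * design$frame_ms
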