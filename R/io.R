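# Readers/writers, run configuration and the end-to-end pipeline driver.

trial_schema <- c("observer_id", "character_set", "noise_band", "soa_frame",
                  "truth", "response", "fixation_ok")

#' Read a trial table from delimited text
#'
#' Schema-validated reader for trial records. Mandatory columns are
#' `observer_id`, `character_set`, `noise_band`, `soa_frame`, `truth`,
#' `response`, `fixation_ok`; unknown columns are preserved. Rows that fail
#' validation (unparseable SOA, labels outside their domain) are dropped
#' with a warning and attached as the `"rejected"` attribute.
#'
#' @param path file path
#' @param delim field delimiter (default tab)
#' @return tibble of validated trial records
#' @export
read_trials <- function(path, delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(trial_schema, names(raw))
  if (length(missing) > 0)
    stop_invalid(paste("missing mandatory column(s):",
                       paste(missing, collapse = ", ")))
  soa <- suppressWarnings(as.integer(raw$soa_frame))
  fix <- toupper(raw$fixation_ok) %in% c("TRUE", "T", "1")
  fix_ok <- toupper(raw$fixation_ok) %in%
    c("TRUE", "T", "1", "FALSE", "F", "0")
  valid <- raw$noise_band %in% c("none", "lsf", "msf", "hsf") &
    raw$truth %in% c("same", "different") &
    raw$response %in% c("same", "different") &
    fix_ok &
    (raw$noise_band == "none" | !is.na(soa))
  out <- raw[valid, , drop = FALSE]
  out$soa_frame <- soa[valid]
  out$fixation_ok <- fix[valid]
  for (col in setdiff(names(out), trial_schema)) {
    out[[col]] <- utils::type.convert(out[[col]], as.is = TRUE)
  }
  if (any(!valid)) {
    warning(sum(!valid), " malformed row(s) rejected")
    attr(out, "rejected") <- raw[!valid, , drop = FALSE]
  }
  out
}

#' Write a trial table as delimited text
#'
#' @param trials tibble of trial records
#' @param path output path
#' @param delim field delimiter
#' @return `path`, invisibly
#' @export
write_trials <- function(trials, path, delim = "\t") {
  readr::write_delim(trials, path, delim = delim)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' All knobs of a full synthetic-data analysis run. Every stochastic stage
#' receives a seed derived deterministically from the master seed. The
#' configuration survives a JSON round trip via [write_config()] /
#' [read_config()].
#'
#' @param seed master seed
#' @param n_permutations permutations per test (>= 1)
#' @param alpha test level
#' @param n_observers simulated observers
#' @param character_set character condition label
#' @param observer "paperlike" (masking dip + oscillation defaults) or
#'   "null" (flat sensitivity)
#' @param design_args list of arguments to [design_spec()]
#' @param dprime_mode,perm_mode,dip_mode analysis flags (see
#'   [dprime_timecourse()], [dip_test()])
#' @param pad_to_frames,max_freq_hz spectral options
#' @param out_dir output directory
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1, n_permutations = 1000, alpha = 0.05,
                       n_observers = 8, character_set = "latin",
                       observer = c("paperlike", "null"),
                       design_args = list(),
                       dprime_mode = "per_frame",
                       perm_mode = "shuffle_responses",
                       dip_mode = "pointwise",
                       pad_to_frames = 151, max_freq_hz = 20,
                       out_dir = "results") {
  structure(list(
    seed = seed, n_permutations = n_permutations, alpha = alpha,
    n_observers = n_observers, character_set = character_set,
    observer = match.arg(observer), design_args = design_args,
    dprime_mode = dprime_mode, perm_mode = perm_mode, dip_mode = dip_mode,
    pad_to_frames = pad_to_frames, max_freq_hz = max_freq_hz,
    out_dir = out_dir
  ), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path JSON path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$design_args <- as.list(x$design_args)
  structure(x, class = "run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates sessions, computes d' time courses, runs the dip permutation
#' test and the oscillation spectrum test for every noise band, and writes
#' tidy delimited outputs plus a JSON manifest (package version, derived
#' seeds, config echo, per-stage row counts). Output bytes are a pure
#' function of the configuration.
#'
#' @param config a [run_config()]
#' @return (invisibly) list with the written file paths and the in-memory
#'   results
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_invalid("config must be a run_config")
  if (config$n_permutations < 1)
    stop_invalid("n_permutations must be at least 1")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- do.call(design_spec, config$design_args)
  params <- if (config$observer == "null") null_observer() else observer_params()

  message("stage simulate: ", config$n_observers, " observer(s)")
  trials <- simulate_sessions(design, params, config$n_observers,
                              seed = derive_seed(config$seed, 1),
                              character_set = config$character_set)
  f_trials <- file.path(config$out_dir, "trials.tsv")
  write_trials(trials, f_trials)

  message("stage timecourse")
  tc <- dprime_timecourse(trials, design, dprime_mode = config$dprime_mode)
  f_tc <- file.path(config$out_dir, "timecourse_group.tsv")
  readr::write_delim(tc$group, f_tc, delim = "\t")

  message("stage resampling (dip tests)")
  dips <- lapply(seq_along(design$noise_bands), function(i) {
    b <- design$noise_bands[i]
    r <- dip_test(trials, b, design = design, n_perm = config$n_permutations,
                  alpha = config$alpha, mode = config$dip_mode,
                  perm_mode = config$perm_mode,
                  seed = derive_seed(config$seed, 10 + i))
    tibble::tibble(noise_band = b, tpo_ms = r$tpo_ms, observed = r$observed,
                   crit = if (config$dip_mode == "pointwise") r$crit
                          else r$crit_omnibus,
                   p = if (config$dip_mode == "pointwise") r$p
                       else r$p_omnibus,
                   significant = r$significant)
  })
  f_dip <- file.path(config$out_dir, "dip_tests.tsv")
  readr::write_delim(dplyr::bind_rows(dips), f_dip, delim = "\t")

  message("stage spectral")
  specs <- lapply(seq_along(design$noise_bands), function(i) {
    b <- design$noise_bands[i]
    r <- spectrum_permutation_test(
      trials, b, design = design, n_perm = config$n_permutations,
      alpha = config$alpha, perm_mode = config$perm_mode,
      pad_to_frames = config$pad_to_frames, max_freq_hz = config$max_freq_hz,
      seed = derive_seed(config$seed, 20 + i))
    tibble::tibble(noise_band = b, freq_hz = r$freq_hz, amplitude = r$observed,
                   critical = r$crit, p = r$p, significant = r$significant)
  })
  f_spec <- file.path(config$out_dir, "spectra.tsv")
  readr::write_delim(dplyr::bind_rows(specs), f_spec, delim = "\t")

  f_cfg <- file.path(config$out_dir, "config.json")
  write_config(config, f_cfg)
  manifest <- list(
    package = "fovealmask",
    version = as.character(utils::packageVersion("fovealmask")),
    stages = c("simulate", "timecourse", "resampling", "spectral"),
    seeds = list(simulate = derive_seed(config$seed, 1),
                 dip = derive_seed(config$seed, 11),
                 spectrum = derive_seed(config$seed, 21)),
    n_trials = nrow(trials),
    n_rows = list(timecourse = nrow(tc$group),
                  dip_tests = sum(vapply(dips, nrow, integer(1))),
                  spectra = sum(vapply(specs, nrow, integer(1)))),
    config_hash = unname(tools::md5sum(f_cfg)),
    files = c("trials.tsv", "timecourse_group.tsv", "dip_tests.tsv",
              "spectra.tsv", "config.json")
  )
  f_man <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA)
  invisible(list(
    files = c(trials = f_trials, timecourse = f_tc, dip = f_dip,
              spectra = f_spec, config = f_cfg, manifest = f_man),
    trials = trials, timecourse = tc,
    dip_tests = dplyr::bind_rows(dips), spectra = dplyr::bind_rows(specs)
  ))
}
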