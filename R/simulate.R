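# Trial-level simulators: dense-SOA sessions from the generative SDT
# observer, 2-up-1-down staircases and QUEST runs from smooth psychometric
# observers, and a full synthetic threshold experiment.

#' Simulate dense-SOA sessions for the masking experiment
#'
#' Per observer and session, emits `n_no_noise` baseline trials plus
#' `n_per_noise` trials per noise band. SOA frames are repeated equally
#' across the design grid (a balanced shuffle), truth (same/different) is
#' balanced within each band, and responses follow the equal-variance SDT
#' rule: evidence ~ Normal(effective d', 1) on "different" trials and
#' Normal(0, 1) on "same" trials, "different" reported when evidence exceeds
#' the criterion; with probability `lapse` the response is a fair coin.
#'
#' @param design a [design_spec()]
#' @param params an [observer_params()]
#' @param n_observers number of observers
#' @param seed integer seed (bit-reproducible output)
#' @param character_set label attached to all trials ("latin" or "korean")
#' @return a tibble of trial records with columns `observer_id`,
#'   `character_set`, `session`, `noise_band`, `soa_frame` (NA for no-noise
#'   trials), `truth`, `response`, `fixation_ok`
#' @examples
#' d <- design_spec(n_sessions = 1)
#' trials <- simulate_sessions(d, null_observer(), n_observers = 2, seed = 1)
#' nrow(trials)  # 2 observers x 620 trials
#' @export
simulate_sessions <- function(design = design_spec(), params = observer_params(),
                              n_observers = 1, seed = NULL,
                              character_set = "latin") {
  grid <- design$soa_frames
  nb <- length(design$noise_bands)
  # effective d' lookup per band x frame (deterministic given params/design)
  dp_band <- lapply(design$noise_bands, function(b)
    trial_dprime(params, b, grid, design))
  names(dp_band) <- design$noise_bands

  one_session <- function() {
    per_frame <- design$n_per_noise %/% length(grid)
    extra <- design$n_per_noise %% length(grid)
    band_frames <- function() {
      f <- rep(grid, per_frame)
      if (extra > 0) f <- c(f, sample(grid, extra))
      sample(f)
    }
    bands <- c(rep("none", design$n_no_noise),
               rep(design$noise_bands, each = design$n_per_noise))
    frames <- c(rep(NA_integer_, design$n_no_noise),
                unlist(lapply(seq_len(nb), function(i) band_frames())))
    n <- length(bands)
    balanced_truth <- function(m) sample(rep(c("different", "same"), length.out = m))
    truth <- character(n)
    truth[bands == "none"] <- balanced_truth(design$n_no_noise)
    for (b in design$noise_bands)
      truth[bands == b] <- balanced_truth(design$n_per_noise)
    dp <- rep(params$d_base, n)
    for (b in design$noise_bands) {
      idx <- bands == b
      dp[idx] <- dp_band[[b]][match(frames[idx], grid)]
    }
    ev <- rnorm(n, mean = ifelse(truth == "different", dp, 0))
    resp <- ifelse(ev > params$criterion, "different", "same")
    if (params$lapse > 0) {
      lp <- runif(n) < params$lapse
      resp[lp] <- sample(c("same", "different"), sum(lp), replace = TRUE)
    }
    tibble::tibble(noise_band = bands, soa_frame = frames, truth = truth,
                   response = resp)
  }

  with_seed(seed, {
    out <- vector("list", n_observers * design$n_sessions)
    k <- 0
    for (o in seq_len(n_observers)) {
      for (s in seq_len(design$n_sessions)) {
        k <- k + 1
        tr <- one_session()
        tr$observer_id <- sprintf("obs%02d", o)
        tr$session <- s
        out[[k]] <- tr
      }
    }
    res <- dplyr::bind_rows(out)
    res$character_set <- character_set
    res$fixation_ok <- TRUE
    res[, c("observer_id", "character_set", "session", "noise_band",
            "soa_frame", "truth", "response", "fixation_ok")]
  })
}

#' Simulate a transformed 2-up-1-down staircase
#'
#' Contrast is reduced after two consecutive correct responses and increased
#' after every incorrect response (converging on the ~70.7%-correct level).
#' Steps are multiplicative; the log step size is halved after each of the
#' first `n_halvings` reversals and then held fixed.
#'
#' @param observer a [psych_observer()]
#' @param start_contrast starting contrast
#' @param n_trials number of trials
#' @param step_factor initial multiplicative step (> 1)
#' @param n_halvings number of early reversals after which the step halves
#' @param bounds contrast floor and ceiling
#' @param seed integer seed
#' @return tibble with columns `trial`, `contrast`, `correct`, `reversal`
#' @export
simulate_staircase <- function(observer, start_contrast = 0.2, n_trials = 100,
                               step_factor = 1.5, n_halvings = 3,
                               bounds = c(1e-4, 1), seed = NULL) {
  if (start_contrast < bounds[1] || start_contrast > bounds[2])
    stop_invalid("start_contrast outside bounds")
  with_seed(seed, {
    contrast <- numeric(n_trials)
    correct <- logical(n_trials)
    reversal <- logical(n_trials)
    c_now <- start_contrast
    log_step <- log(step_factor)
    n_correct <- 0L
    last_dir <- 0L      # -1 down, +1 up
    n_rev <- 0L
    for (t in seq_len(n_trials)) {
      contrast[t] <- c_now
      correct[t] <- runif(1) < observer_accuracy(observer, c_now)
      dir <- 0L
      if (correct[t]) {
        n_correct <- n_correct + 1L
        if (n_correct >= 2L) { dir <- -1L; n_correct <- 0L }
      } else {
        dir <- 1L
        n_correct <- 0L
      }
      if (dir != 0L) {
        if (last_dir != 0L && dir != last_dir) {
          reversal[t] <- TRUE
          n_rev <- n_rev + 1L
          if (n_rev <= n_halvings) log_step <- log_step / 2
        }
        last_dir <- dir
        c_now <- min(max(c_now * exp(dir * log_step), bounds[1]), bounds[2])
      }
    }
    tibble::tibble(trial = seq_len(n_trials), contrast = contrast,
                   correct = correct, reversal = reversal)
  })
}

#' Interleaved ascending/descending staircase pair
#'
#' Runs two staircases (one starting below, one above the expected
#' threshold) whose trials are randomly interleaved, as in a blocked
#' threshold measurement.
#'
#' @inheritParams simulate_staircase
#' @param start_low,start_high starting contrasts of the ascending and
#'   descending staircase
#' @param n_trials total trials (split evenly)
#' @return tibble as [simulate_staircase()] plus a `staircase` column
#'   ("ascending"/"descending"); `trial` numbers the interleaved sequence
#' @export
simulate_staircase_pair <- function(observer, start_low = 0.01, start_high = 0.8,
                                    n_trials = 80, step_factor = 1.5,
                                    n_halvings = 3, bounds = c(1e-4, 1),
                                    seed = NULL) {
  with_seed(seed, {
    n1 <- n_trials %/% 2; n2 <- n_trials - n1
    a <- simulate_staircase(observer, start_low, n1, step_factor, n_halvings, bounds)
    d <- simulate_staircase(observer, start_high, n2, step_factor, n_halvings, bounds)
    a$staircase <- "ascending"; d$staircase <- "descending"
    ord <- sample(rep(c(1L, 2L), c(n1, n2)))
    both <- list(a, d); ix <- c(0L, 0L)
    rows <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      s <- ord[t]; ix[s] <- ix[s] + 1L
      rows[[t]] <- both[[s]][ix[s], ]
    }
    out <- dplyr::bind_rows(rows)
    out$trial <- seq_len(n_trials)
    out
  })
}

#' Converged level of a staircase run
#'
#' Mean contrast over reversals after a burn-in (the early reversals during
#' which the step size is still shrinking), trimmed to an even count so
#' upward and downward reversals contribute equally — the standard reversal
#' average for transformed up-down staircases.
#'
#' @param staircase tibble from [simulate_staircase()]
#' @param discard_reversals number of initial reversals to discard
#' @return contrast at the converged level
#' @export
staircase_converged_level <- function(staircase, discard_reversals = 4) {
  rev_c <- staircase$contrast[staircase$reversal]
  if (length(rev_c) <= discard_reversals + 1)
    stop_invalid("too few reversals to estimate a converged level")
  rev_c <- rev_c[-seq_len(discard_reversals)]
  if (length(rev_c) %% 2 == 1) rev_c <- rev_c[-1]
  mean(rev_c)
}

#' Simulate a QUEST threshold run
#'
#' Bayesian adaptive estimation with a Weibull likelihood in log10 contrast:
#' a grid posterior over the threshold location is updated after every
#' Bernoulli outcome, each trial is placed at the contrast the current
#' posterior mean maps to the target accuracy, and the final estimate is
#' that same mapping of the posterior mean.
#'
#' @param observer a [psych_observer()] generating the responses
#' @param target_p accuracy the returned contrast should yield (default
#'   0.75); must lie strictly between the model's guess rate and 1 - lapse
#' @param n_trials number of trials
#' @param beta Weibull slope assumed by the procedure
#' @param guess_rate,lapse asymptotes assumed by the procedure
#' @param prior_mean_log10,prior_sd_log10 Gaussian prior on the log10
#'   threshold location
#' @param grid_n posterior grid resolution
#' @param seed integer seed
#' @return list with `threshold` (contrast at `target_p`), `posterior_mean`
#'   (log10 scale location), and the trial-by-trial `contrast`/`correct`
#' @export
simulate_quest <- function(observer, target_p = 0.75, n_trials = 80,
                           beta = 3.5, guess_rate = 0.5, lapse = 0.02,
                           prior_mean_log10 = -1.3, prior_sd_log10 = 1,
                           grid_n = 201, seed = NULL) {
  if (target_p <= guess_rate || target_p >= 1 - lapse)
    stop_invalid("target_p must lie strictly between guess_rate and 1 - lapse")
  q_target <- (target_p - guess_rate) / (1 - guess_rate - lapse)
  # offset from the scale location to the target-p contrast, in log10 units
  x_off <- log10(-log(1 - q_target)) / beta
  tgrid <- seq(prior_mean_log10 - 3 * prior_sd_log10,
               prior_mean_log10 + 3 * prior_sd_log10, length.out = grid_n)
  with_seed(seed, {
    log_post <- dnorm(tgrid, prior_mean_log10, prior_sd_log10, log = TRUE)
    contrast <- numeric(n_trials); correct <- logical(n_trials)
    for (t in seq_len(n_trials)) {
      t_hat <- sum(tgrid * exp(log_post - max(log_post))) /
        sum(exp(log_post - max(log_post)))
      x <- t_hat + x_off
      contrast[t] <- 10^x
      correct[t] <- runif(1) < observer_accuracy(observer, contrast[t])
      p_grid <- guess_rate + (1 - guess_rate - lapse) *
        (1 - exp(-10^(beta * (x - tgrid))))
      log_post <- log_post +
        if (correct[t]) log(p_grid) else log1p(-p_grid)
    }
    w <- exp(log_post - max(log_post))
    t_hat <- sum(tgrid * w) / sum(w)
    list(threshold = 10^(t_hat + x_off), posterior_mean = t_hat,
         contrast = contrast, correct = correct)
  })
}

#' Mean threshold of two independent QUEST runs
#'
#' Mirrors the thresholding block of the masking experiment: two QUESTs are
#' run and the mean of their suggested contrasts is used.
#'
#' @inheritParams simulate_quest
#' @return mean of the two runs' threshold estimates
#' @export
quest_pair <- function(observer, target_p = 0.75, n_trials = 80, seed = NULL, ...) {
  r1 <- simulate_quest(observer, target_p, n_trials,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 1), ...)
  r2 <- simulate_quest(observer, target_p, n_trials,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, 2), ...)
  (r1$threshold + r2$threshold) / 2
}

#' Default generative contrast thresholds for the threshold experiment
#'
#' Qualitative pattern carried by the synthetic observers: thresholds are
#' far higher at 10 deg than at fixation; at fixation MSF background noise
#' masks characters more than LSF noise, while at 10 deg the ordering
#' reverses (LSF > MSF).
#'
#' @return tibble with columns `eccentricity`, `noise_band`, `threshold`
#' @export
exp2_true_thresholds <- function() {
  tibble::tibble(
    eccentricity = c(0, 0, 10, 10),
    noise_band = c("lsf", "msf", "lsf", "msf"),
    threshold = c(0.020, 0.035, 0.25, 0.15)
  )
}

#' Simulate the character-in-noise threshold experiment
#'
#' For each observer, character set (latin, korean), eccentricity (0, 10
#' deg) and background noise band (LSF, MSF), runs an interleaved
#' ascending/descending 2-up-1-down staircase pair on a Weibull observer
#' whose true threshold follows [exp2_true_thresholds()] scaled by
#' per-observer lognormal variability. Defaults give 640 trials per
#' observer (8 conditions x 80 trials).
#'
#' @param n_observers number of observers
#' @param trials_per_cond staircase trials per condition
#' @param true_thresholds tibble as [exp2_true_thresholds()]
#' @param observer_sd SD of per-observer lognormal threshold scaling
#' @param slope,lapse Weibull observer shape and lapse
#' @param seed integer seed
#' @return tibble of staircase trials with columns `observer_id`,
#'   `character_set`, `eccentricity`, `noise_band`, `trial`, `contrast`,
#'   `correct`, `staircase`; true per-cell thresholds are attached as the
#'   `"true_thresholds"` attribute
#' @export
simulate_exp2 <- function(n_observers = 26, trials_per_cond = 80,
                          true_thresholds = exp2_true_thresholds(),
                          observer_sd = 0.15, slope = 3.5, lapse = 0.02,
                          seed = NULL) {
  with_seed(seed, {
    rows <- list(); truths <- list(); k <- 0
    for (o in seq_len(n_observers)) {
      obs_scale <- exp(rnorm(1, 0, observer_sd))
      for (chr in c("latin", "korean")) {
        for (i in seq_len(nrow(true_thresholds))) {
          k <- k + 1
          th <- true_thresholds$threshold[i] * obs_scale * exp(rnorm(1, 0, 0.05))
          obs <- psych_observer(threshold = th, target_p = 0.707,
                                slope = slope, lapse = lapse)
          sc <- simulate_staircase_pair(
            obs, start_low = th / 8, start_high = min(1, th * 8),
            n_trials = trials_per_cond)
          sc$observer_id <- sprintf("obs%02d", o)
          sc$character_set <- chr
          sc$eccentricity <- true_thresholds$eccentricity[i]
          sc$noise_band <- true_thresholds$noise_band[i]
          rows[[k]] <- sc
          truths[[k]] <- tibble::tibble(
            observer_id = sc$observer_id[1], character_set = chr,
            eccentricity = sc$eccentricity[1], noise_band = sc$noise_band[1],
            true_threshold = th)
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    out <- out[, c("observer_id", "character_set", "eccentricity", "noise_band",
                   "trial", "contrast", "correct", "staircase")]
    attr(out, "true_thresholds") <- dplyr::bind_rows(truths)
    out
  })
}
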