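# Threshold-experiment analysis: binomial maximum-likelihood psychometric
# fits, 70.7%-accuracy contrast thresholds, per-character-condition
# exclusion rules, Holm-Bonferroni post-hocs, and a self-contained paired
# permutation test for within-observer comparisons.

#' Fit a psychometric function by maximum likelihood
#'
#' Binomial likelihood with a fixed guess rate and a bounded lapse rate,
#' either a cumulative Gaussian in log10 contrast or a Weibull in linear
#' contrast. A fixed multi-start grid feeds `optim` (L-BFGS-B), so the fit
#' is deterministic given the data. Degenerate data (all correct or all
#' wrong) yields `converged = FALSE` rather than an error.
#'
#' @param contrasts stimulus contrasts (> 0)
#' @param correct logical (or 0/1) response correctness
#' @param family "cumulative_gaussian" or "weibull"
#' @param guess_rate lower asymptote (0.5 for same-different)
#' @param lapse_bounds bounds for the lapse rate (default c(0, 0.1))
#' @return a `psychometric_fit`: `family`, `threshold_param` (log10 location
#'   or Weibull scale), `slope_param`, `lapse`, `guess_rate`,
#'   `log_likelihood`, `converged`
#' @export
fit_psychometric <- function(contrasts, correct,
                             family = c("cumulative_gaussian", "weibull"),
                             guess_rate = 0.5, lapse_bounds = c(0, 0.1)) {
  family <- match.arg(family)
  correct <- as.logical(correct)
  ok <- is.finite(contrasts) & contrasts > 0 & !is.na(correct)
  contrasts <- contrasts[ok]; correct <- correct[ok]
  if (length(contrasts) < 20)
    stop_invalid("need at least 20 trials to fit a psychometric function")
  if (length(unique(contrasts)) < 3)
    stop_invalid("need at least 3 distinct contrast levels")
  g <- guess_rate
  lx <- log10(contrasts)
  degenerate <- all(correct) || all(!correct)

  pfun <- function(par, cc) {
    q <- if (family == "cumulative_gaussian") {
      pnorm((log10(cc) - par[1]) / exp(par[2]))
    } else {
      1 - exp(-(cc / 10^par[1])^exp(par[2]))
    }
    g + (1 - g - par[3]) * q
  }
  nll <- function(par) {
    p <- pmin(pmax(pfun(par, contrasts), 1e-10), 1 - 1e-10)
    -sum(ifelse(correct, log(p), log1p(-p)))
  }
  loc_grid <- quantile(lx, c(0.15, 0.5, 0.85), names = FALSE)
  shape_grid <- if (family == "cumulative_gaussian") log(c(0.15, 0.5))
                else log(c(1.5, 4))
  lapse_grid <- pmin(pmax(0.02, lapse_bounds[1]), lapse_bounds[2])
  lower <- c(min(lx) - 2, log(1e-3), lapse_bounds[1])
  upper <- c(max(lx) + 2, log(50), lapse_bounds[2])
  best <- NULL
  for (m in loc_grid) for (s in shape_grid) for (l in unique(lapse_grid)) {
    fit <- tryCatch(
      optim(c(m, s, l), nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_invalid("psychometric optimization failed for all starts")
  structure(list(
    family = family,
    threshold_param = best$par[1],
    # slope: 1/sigma for the Gaussian (log10 units), Weibull beta otherwise
    slope_param = if (family == "cumulative_gaussian") 1 / exp(best$par[2])
                  else exp(best$par[2]),
    lapse = best$par[3],
    guess_rate = g,
    log_likelihood = -best$value,
    converged = !degenerate && best$convergence == 0,
    n_trials = length(contrasts),
    contrast_range = range(contrasts)
  ), class = "psychometric_fit")
}

#' Accuracy predicted by a psychometric fit
#'
#' @param fit a `psychometric_fit`
#' @param contrast contrasts (> 0); vectorized
#' @return predicted probability correct
#' @export
predict_accuracy <- function(fit, contrast) {
  q <- if (fit$family == "cumulative_gaussian") {
    pnorm((log10(contrast) - fit$threshold_param) * fit$slope_param)
  } else {
    1 - exp(-(contrast / 10^fit$threshold_param)^fit$slope_param)
  }
  fit$guess_rate + (1 - fit$guess_rate - fit$lapse) * q
}

#' Contrast at a target accuracy under a fitted psychometric function
#'
#' Inverse of the fitted accuracy function, the threshold definition used
#' for the threshold experiment (70.7% accuracy by default, the level a
#' 2-up-1-down staircase converges to). Signals an unattainable-accuracy
#' error — the machine-readable basis of the exclusion rule — if the fit
#' did not converge or the target lies outside (guess, 1 - lapse).
#'
#' @param fit a `psychometric_fit`
#' @param target_accuracy accuracy to invert at (default 0.707)
#' @return contrast
#' @export
threshold_at <- function(fit, target_accuracy = 0.707) {
  if (!isTRUE(fit$converged))
    stop_unattainable("fit did not converge; threshold undefined")
  g <- fit$guess_rate
  if (target_accuracy <= g || target_accuracy >= 1 - fit$lapse)
    stop_unattainable(sprintf(
      "target accuracy %.3f outside the fitted range (%.3f, %.3f)",
      target_accuracy, g, 1 - fit$lapse))
  q <- (target_accuracy - g) / (1 - g - fit$lapse)
  if (fit$family == "cumulative_gaussian") {
    10^(fit$threshold_param + qnorm(q) / fit$slope_param)
  } else {
    10^fit$threshold_param * (-log(1 - q))^(1 / fit$slope_param)
  }
}

#' Fit thresholds for every observer x condition cell
#'
#' Fits a psychometric function per observer, character set, eccentricity
#' and background noise band, and inverts it at the target accuracy. Cells
#' whose fit fails or whose target accuracy is unattainable get an NA
#' threshold (picked up by [apply_exclusions()]).
#'
#' @param trials staircase trial table (see [simulate_exp2()]) with columns
#'   `observer_id`, `character_set`, `eccentricity`, `noise_band`,
#'   `contrast`, `correct`
#' @param target_accuracy threshold accuracy (default 0.707)
#' @inheritParams fit_psychometric
#' @return a threshold table tibble (one row per cell) with
#'   `threshold_contrast` and fit diagnostics; the fits are attached as the
#'   `"fits"` attribute
#' @export
fit_thresholds <- function(trials, target_accuracy = 0.707,
                           family = c("cumulative_gaussian", "weibull"),
                           guess_rate = 0.5, lapse_bounds = c(0, 0.1)) {
  family <- match.arg(family)
  keys <- trials |>
    dplyr::distinct(.data$observer_id, .data$character_set,
                    .data$eccentricity, .data$noise_band) |>
    dplyr::arrange(.data$observer_id, .data$character_set,
                   .data$eccentricity, .data$noise_band)
  fits <- vector("list", nrow(keys))
  th <- rep(NA_real_, nrow(keys)); conv <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    d <- dplyr::semi_join(trials, keys[i, ],
                          by = c("observer_id", "character_set",
                                 "eccentricity", "noise_band"))
    fit <- tryCatch(
      fit_psychometric(d$contrast, d$correct, family, guess_rate, lapse_bounds),
      fovealmask_invalid_argument = function(e) NULL)
    fits[[i]] <- fit
    conv[i] <- !is.null(fit) && isTRUE(fit$converged)
    th[i] <- tryCatch(threshold_at(fit, target_accuracy),
                      error = function(e) NA_real_)
  }
  out <- keys
  out$threshold_contrast <- th
  out$converged <- conv
  attr(out, "fits") <- fits
  out
}

#' Apply the threshold-experiment exclusion rules
#'
#' An observer whose fitted function fails to reach the target accuracy in
#' any cell of a character condition is excluded from that character
#' condition only (not globally). An optional list of observers can be
#' excluded outright, mirroring exclusion for poor fixation.
#'
#' @param table threshold table from [fit_thresholds()]
#' @param exclude_observers observer ids excluded globally (e.g. for poor
#'   fixation quality)
#' @return the table with `included` flags and machine-readable
#'   `exclusion_reason`
#' @export
apply_exclusions <- function(table, exclude_observers = character()) {
  if (nrow(table) == 0) {
    table$included <- logical(0); table$exclusion_reason <- character(0)
    return(table)
  }
  bad_cells <- is.na(table$threshold_contrast)
  bad_chr <- unique(table[bad_cells, c("observer_id", "character_set")])
  table$included <- TRUE
  table$exclusion_reason <- NA_character_
  if (nrow(bad_chr) > 0) {
    hit <- paste(table$observer_id, table$character_set) %in%
      paste(bad_chr$observer_id, bad_chr$character_set)
    table$included[hit] <- FALSE
    table$exclusion_reason[hit] <- "threshold_unattainable"
  }
  fix <- table$observer_id %in% exclude_observers
  table$included[fix] <- FALSE
  table$exclusion_reason[fix] <- "poor_fixation"
  table
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values numeric p-values in [0, 1]
#' @param alpha familywise level
#' @return tibble with `p`, `p_adjusted` and `reject`
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(tibble::tibble(p = numeric(), p_adjusted = numeric(),
                          reject = logical()))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_invalid("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "holm")
  tibble::tibble(p = p_values, p_adjusted = adj, reject = adj <= alpha)
}

#' Within-observer paired sign-flip permutation test
#'
#' Self-contained alternative to a mixed-model contrast for paired
#' threshold comparisons: the statistic is the mean within-observer
#' difference, and the null randomly flips each observer's difference sign.
#'
#' @param x,y paired measurements (same observers, same order)
#' @param n_perm number of sign flips
#' @param seed integer seed
#' @return list with `observed` mean difference, `p` (two-tailed) and
#'   `n_pairs`
#' @export
paired_permutation_test <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2) stop_invalid("need at least 2 complete pairs")
  obs <- mean(d)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(d * sample(c(-1, 1), n, replace = TRUE)), numeric(1)))
  list(observed = obs, p = perm_p(null, obs, "two_tailed"), n_pairs = n)
}
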