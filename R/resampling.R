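# Stratified permutation inference on d' time courses: per-TPO dip tests
# within a condition (pointwise and min-statistic omnibus) and between-band
# masking-strength comparisons. The permutation engine works on per-observer
# count matrices so thousands of full pipeline re-runs stay cheap.

# ---- internal engine -------------------------------------------------------

# trailing moving-average operator as a (K-w+1) x K matrix
ma_matrix <- function(K, w) {
  nb <- K - w + 1
  A <- matrix(0, nb, K)
  for (i in seq_len(nb)) A[i, i:(i + w - 1)] <- 1 / w
  A
}

col_mins <- function(M) as.numeric(do.call(pmin, asplit(M, 1)))
col_maxs <- function(M) as.numeric(do.call(pmax, asplit(M, 1)))

center_cols <- function(M) M - rep(colMeans(M), each = nrow(M))

# condition filter + shared frame grid (pooled undersampling rule)
condition_trials <- function(trials, noise_band, character_set, design,
                             min_trials_per_frame) {
  x <- trials[trials$fixation_ok & trials$noise_band %in% noise_band, ,
              drop = FALSE]
  if (!is.null(character_set))
    x <- x[x$character_set %in% character_set, , drop = FALSE]
  x <- x[x$soa_frame %in% design$soa_frames, , drop = FALSE]
  if (nrow(x) == 0) stop_invalid("no trials in the requested condition")
  pooled <- table(x$soa_frame)
  thr <- if (is.null(min_trials_per_frame)) 0.5 * median(pooled)
         else min_trials_per_frame
  frames <- sort(as.integer(names(pooled)[pooled >= thr]))
  if (length(frames) < 2) stop_invalid("fewer than 2 SOA frames after filtering")
  x[x$soa_frame %in% frames, , drop = FALSE]
}

# per-observer cell counts: one row per SOA frame, columns counting the
# four truth x response combinations (dd = hit, ds = miss, sd = false
# alarm, ss = correct rejection). Trials within a (frame, truth, response)
# cell are exchangeable, so stratified permutations only need these counts.
prep_observer <- function(d, frames) {
  fidx <- factor(match(d$soa_frame, frames), levels = seq_along(frames))
  t_diff <- d$truth == "different"
  y <- d$response == "different"
  type <- factor(ifelse(t_diff, ifelse(y, 1L, 2L), ifelse(y, 3L, 4L)),
                 levels = 1:4)
  M <- matrix(as.integer(table(fidx, type)), length(frames), 4)
  colnames(M) <- c("dd", "ds", "sd", "ss")
  M
}

hautus_mat <- function(hits, n_diff, fa, n_same) {
  qnorm((hits + 0.5) / (n_diff + 1)) - qnorm((fa + 0.5) / (n_same + 1))
}

# Draw, for B independent uniform allocations of `n_ones` marked items
# into cells of the given sizes, the number of marked items per cell.
# Sequential conditioning: cell j receives Hypergeometric(ones left,
# others left, cell size) marked items; exact and vectorized across B.
alloc_hypergeom <- function(cell_sizes, n_ones, B) {
  J <- length(cell_sizes)
  out <- matrix(0L, J, B)
  ones_left <- rep.int(n_ones, B)
  tot_left <- sum(cell_sizes)
  for (j in seq_len(J)) {
    m <- cell_sizes[j]
    x <- stats::rhyper(B, ones_left, tot_left - ones_left, m)
    out[j, ] <- x
    ones_left <- ones_left - x
    tot_left <- tot_left - m
  }
  out
}

# K x B matrix of per-frame d' under B stratified permutations of one
# observer's trials.
# "shuffle_responses": the observer's responses are reallocated uniformly
#   across trials (truth and frame labels fixed).
# "shuffle_soa_labels": the (truth, response) pairs are reallocated across
#   SOA frames (frame sizes fixed).
observer_d_perm <- function(M, B, perm_mode) {
  K <- nrow(M)
  n_diff <- M[, 1] + M[, 2]
  n_same <- M[, 3] + M[, 4]
  if (perm_mode == "shuffle_responses") {
    # responses are reshuffled within their truth class, preserving the
    # observer's overall hit and false-alarm rates; without the truth
    # stratification the shuffle would destroy the truth-response coupling
    # and inflate the null variance of the per-frame d'
    hits <- alloc_hypergeom(n_diff, sum(M[, 1]), B)
    fa <- alloc_hypergeom(n_same, sum(M[, 3]), B)
    hautus_mat(hits, n_diff, fa, n_same)
  } else {
    sizes <- n_diff + n_same
    a_left <- rep.int(sum(M[, 1]), B); b_left <- rep.int(sum(M[, 2]), B)
    c_left <- rep.int(sum(M[, 3]), B)
    tot_left <- sum(sizes); d_tot <- sum(M[, 4])
    hits <- matrix(0L, K, B); miss <- matrix(0L, K, B); fa <- matrix(0L, K, B)
    for (f in seq_len(K)) {
      m <- sizes[f]
      xa <- stats::rhyper(B, a_left, tot_left - a_left, m)
      xb <- stats::rhyper(B, b_left, tot_left - a_left - b_left, m - xa)
      xc <- stats::rhyper(B, c_left, tot_left - a_left - b_left - c_left,
                          m - xa - xb)
      hits[f, ] <- xa; miss[f, ] <- xb; fa[f, ] <- xc
      a_left <- a_left - xa; b_left <- b_left - xb; c_left <- c_left - xc
      tot_left <- tot_left - m
    }
    hautus_mat(hits, hits + miss, fa, sizes - (hits + miss))
  }
}

observer_d_observed <- function(M) {
  hautus_mat(M[, 1], M[, 1] + M[, 2], M[, 3], M[, 3] + M[, 4])
}

# group centered MA curves for B permutations of one condition (B = 0
# returns the observed curve only). The moving average and the centering
# are linear, so they are applied once to the observer-mean d' series.
engine_group_curves <- function(obs_list, A_ma, B, perm_mode) {
  observed_d <- Reduce(`+`, lapply(obs_list, observer_d_observed)) /
    length(obs_list)
  observed <- drop(center_cols(A_ma %*% observed_d))
  if (B == 0) return(list(observed = observed, curves = NULL))
  Dsum <- Reduce(`+`, lapply(obs_list, observer_d_perm, B = B,
                             perm_mode = perm_mode))
  curves <- center_cols(A_ma %*% (Dsum / length(obs_list)))
  list(observed = observed, curves = curves)
}

# shared preparation for condition-level permutation analyses
perm_condition_curves <- function(trials, noise_band, character_set, design,
                                  n_perm, seed, perm_mode, window_frames,
                                  min_trials_per_frame) {
  x <- condition_trials(trials, noise_band, character_set, design,
                        min_trials_per_frame)
  frames <- sort(unique(x$soa_frame))
  if (length(frames) < window_frames)
    stop_invalid("fewer SOA frames than the moving-average window")
  obs_list <- lapply(split(x, x$observer_id), prep_observer, frames = frames)
  A_ma <- ma_matrix(length(frames), window_frames)
  res <- with_seed(seed,
                   engine_group_curves(obs_list, A_ma, n_perm, perm_mode))
  tpo_frame <- frames[seq_len(nrow(A_ma))]
  list(observed = res$observed, curves = res$curves, tpo_frame = tpo_frame,
       tpo_ms = tpo_frame * design$frame_ms, n_observers = length(obs_list))
}

# band-pair engine: permutes band labels within observer (uniform
# reallocation of the band-a label over the pooled trials of both bands,
# stratified by observer; counts per band preserved), returns per-band
# group centered curves for the observed data and B permutations. Because
# trials within a (frame, truth, response) cell are exchangeable, the
# reallocation reduces to a hypergeometric split of each cell's count.
perm_band_pair_curves <- function(trials, band_a, band_b, character_set,
                                  design, n_perm, seed, window_frames,
                                  min_trials_per_frame) {
  x <- condition_trials(trials, c(band_a, band_b), character_set, design,
                        min_trials_per_frame)
  frames <- sort(unique(x$soa_frame))
  if (length(frames) < window_frames)
    stop_invalid("fewer SOA frames than the moving-average window")
  K <- length(frames)
  A_ma <- ma_matrix(K, window_frames)
  obs_list <- lapply(split(x, x$observer_id), function(d) {
    list(Ma = prep_observer(d[d$noise_band == band_a, ], frames),
         Mb = prep_observer(d[d$noise_band == band_b, ], frames))
  })
  n_obs <- length(obs_list)

  observed_a <- drop(center_cols(A_ma %*% (
    Reduce(`+`, lapply(obs_list, function(o) observer_d_observed(o$Ma))) / n_obs)))
  observed_b <- drop(center_cols(A_ma %*% (
    Reduce(`+`, lapply(obs_list, function(o) observer_d_observed(o$Mb))) / n_obs)))

  res <- with_seed(seed, {
    Da <- matrix(0, K, n_perm); Db <- matrix(0, K, n_perm)
    for (o in obs_list) {
      Mtot <- o$Ma + o$Mb
      n_a <- sum(o$Ma)
      # split every (frame x truth x response) cell between the two bands
      H <- alloc_hypergeom(as.vector(Mtot), n_a, n_perm)
      cell <- function(j) H[(j - 1) * K + seq_len(K), , drop = FALSE]
      hits_a <- cell(1); miss_a <- cell(2); fa_a <- cell(3); cr_a <- cell(4)
      Da <- Da + hautus_mat(hits_a, hits_a + miss_a, fa_a, fa_a + cr_a)
      hits_b <- Mtot[, 1] - hits_a; miss_b <- Mtot[, 2] - miss_a
      fa_b <- Mtot[, 3] - fa_a; cr_b <- Mtot[, 4] - cr_a
      Db <- Db + hautus_mat(hits_b, hits_b + miss_b, fa_b, fa_b + cr_b)
    }
    list(a = center_cols(A_ma %*% (Da / n_obs)),
         b = center_cols(A_ma %*% (Db / n_obs)))
  })
  tpo_frame <- frames[seq_len(nrow(A_ma))]
  list(observed_a = observed_a, observed_b = observed_b,
       curves_a = res$a, curves_b = res$b,
       tpo_frame = tpo_frame, tpo_ms = tpo_frame * design$frame_ms,
       n_observers = n_obs)
}

perm_p <- function(null_values, observed, side) {
  B <- length(null_values)
  switch(side,
    lower = (1 + sum(null_values <= observed)) / (B + 1),
    upper = (1 + sum(null_values >= observed)) / (B + 1),
    two_tailed = min(1, 2 * min(
      (1 + sum(null_values <= observed)) / (B + 1),
      (1 + sum(null_values >= observed)) / (B + 1)))
  )
}

# ---- public operations -----------------------------------------------------

#' Lazy stream of stratified within-observer permutations
#'
#' Produces permuted copies of a trial table on demand. Labels are shuffled
#' only within observer x character x band strata, preserving all stratum
#' counts. `"shuffle_responses"` permutes the response column within each
#' stratum's truth class (preserving the observer's hit and false-alarm
#' rates); `"shuffle_soa_labels"` permutes the SOA frames against the
#' (truth, response) pairs. Both break any SOA dependence while keeping the
#' SDT structure intact. Each permutation index has its own seed derived
#' from the master seed, so `get(i)` is reproducible in any order.
#'
#' @param trials tibble of trial records
#' @param mode "shuffle_responses" or "shuffle_soa_labels"
#' @param n_perm number of permutations (>= 1)
#' @param seed master seed
#' @return object of class `perm_stream` with fields `n_perm`, `mode`, and
#'   `get(i)` returning the i-th permuted trial table
#' @export
permute_within_observer <- function(trials, mode = c("shuffle_responses",
                                                     "shuffle_soa_labels"),
                                    n_perm = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_invalid("n_perm must be at least 1")
  strata <- if (mode == "shuffle_responses") {
    interaction(trials$observer_id, trials$character_set, trials$noise_band,
                trials$truth, drop = TRUE)
  } else {
    interaction(trials$observer_id, trials$character_set, trials$noise_band,
                drop = TRUE)
  }
  get <- function(i) {
    if (i < 1 || i > n_perm) stop_invalid("permutation index out of range")
    with_seed(derive_seed(seed, i), {
      out <- trials
      for (s in levels(strata)) {
        idx <- which(strata == s)
        p <- idx[sample.int(length(idx))]
        if (mode == "shuffle_responses") {
          out$response[idx] <- trials$response[p]
        } else {
          out$soa_frame[idx] <- trials$soa_frame[p]
        }
      }
      out
    })
  }
  structure(list(n_perm = n_perm, mode = mode, seed = seed, get = get),
            class = "perm_stream")
}

#' Permutation test for performance dips across TPO
#'
#' Re-runs the full time-course pipeline (per-frame Hautus d', trailing
#' moving average, per-observer centering, group average) on the observed
#' data and on `n_perm` stratified permutations. In `"pointwise"` mode each
#' TPO bin gets the lower-tail alpha-quantile of its permuted centered d'
#' as critical value (performance reductions are negative, so this is the
#' one-sided test at the 95th percentile of reduction magnitude); in
#' `"omnibus_min"` mode the min-over-bins statistic gives a familywise
#' critical value and a single p-value.
#'
#' @param trials tibble of trial records
#' @param noise_band band defining the condition ("lsf", "msf" or "hsf")
#' @param character_set optional character condition filter
#' @param design a [design_spec()]
#' @param n_perm number of permutations
#' @param alpha test level (one-tailed)
#' @param mode "pointwise" or "omnibus_min"
#' @param perm_mode see [permute_within_observer()]
#' @param window_frames moving-average window
#' @param min_trials_per_frame see [bin_by_soa()]
#' @param seed integer seed
#' @return a `permutation_result` list: `tpo_ms`, `observed` (group centered
#'   d'), per-bin `crit` and `p` (pointwise), `p_omnibus` and `crit_omnibus`
#'   (omnibus_min), `significant` bins, `n_perm`, `side`, `seed`
#' @export
dip_test <- function(trials, noise_band, character_set = NULL,
                     design = design_spec(), n_perm = 10000, alpha = 0.05,
                     mode = c("pointwise", "omnibus_min"),
                     perm_mode = c("shuffle_responses", "shuffle_soa_labels"),
                     window_frames = design$noise_dur_frames,
                     min_trials_per_frame = NULL, seed = 1) {
  mode <- match.arg(mode); perm_mode <- match.arg(perm_mode)
  if (n_perm < 1) stop_invalid("n_perm must be at least 1")
  pc <- perm_condition_curves(trials, noise_band, character_set, design,
                              n_perm, seed, perm_mode, window_frames,
                              min_trials_per_frame)
  obs <- pc$observed
  res <- list(statistic = "group centered d' per TPO bin",
              noise_band = noise_band, character_set = character_set,
              tpo_frame = pc$tpo_frame, tpo_ms = pc$tpo_ms, observed = obs,
              n_perm = n_perm, alpha = alpha, mode = mode,
              side = "one_tailed_lower", perm_mode = perm_mode, seed = seed,
              n_observers = pc$n_observers)
  if (mode == "pointwise") {
    res$crit <- apply(pc$curves, 1, quantile, probs = alpha, names = FALSE)
    res$p <- vapply(seq_along(obs), function(b)
      perm_p(pc$curves[b, ], obs[b], "lower"), numeric(1))
    res$significant <- obs < res$crit
  } else {
    mins <- col_mins(pc$curves)
    res$crit_omnibus <- quantile(mins, alpha, names = FALSE)
    res$p_omnibus <- perm_p(mins, min(obs), "lower")
    res$significant <- obs < res$crit_omnibus
    res$null_min <- mins
  }
  class(res) <- "permutation_result"
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test:", x$statistic, "\n")
  cat("  n_perm =", x$n_perm, " side =", x$side, " mode =", x$mode %||% "", "\n")
  if (!is.null(x$p_omnibus)) cat("  omnibus p =", format.pval(x$p_omnibus), "\n")
  if (!is.null(x$p) && length(x$p) > 1)
    cat("  significant bins:", sum(x$significant), "of", length(x$p), "\n")
  if (!is.null(x$p_scalar)) cat("  p =", format.pval(x$p_scalar), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare masking strength between two noise bands
#'
#' Statistic: the strongest impairment (minimum over TPO of the group
#' centered d') under band A minus that under band B, evaluated at each
#' band's own worst TPO so that bands masking at different times are
#' compared fairly. The null is built by shuffling band labels within
#' observer (trial counts per band preserved) and recomputing both minima;
#' the decision uses the central (1 - alpha) interval (two-tailed).
#'
#' @param trials tibble of trial records
#' @param band_a,band_b distinct noise bands
#' @inheritParams dip_test
#' @return a `permutation_result` with scalar `observed_diff`, `p_scalar`,
#'   `crit` (two-sided interval), and the per-band observed minima
#' @export
compare_noise_strength <- function(trials, band_a, band_b,
                                   character_set = NULL,
                                   design = design_spec(), n_perm = 10000,
                                   alpha = 0.05,
                                   window_frames = design$noise_dur_frames,
                                   min_trials_per_frame = NULL, seed = 1) {
  if (identical(band_a, band_b)) stop_invalid("band_a and band_b must differ")
  # canonical internal order: the result is exactly antisymmetric in the
  # band arguments (same permutation stream, sign-flipped statistic)
  flip <- band_a > band_b
  bands <- if (flip) c(band_b, band_a) else c(band_a, band_b)
  pc <- perm_band_pair_curves(trials, bands[1], bands[2], character_set,
                              design, n_perm, seed, window_frames,
                              min_trials_per_frame)
  if (flip) {
    pc[c("observed_a", "observed_b")] <- pc[c("observed_b", "observed_a")]
    pc[c("curves_a", "curves_b")] <- pc[c("curves_b", "curves_a")]
  }
  stat_obs <- min(pc$observed_a) - min(pc$observed_b)
  null_diff <- col_mins(pc$curves_a) - col_mins(pc$curves_b)
  structure(list(
    statistic = "min-over-TPO centered d' difference (band_a - band_b)",
    band_a = band_a, band_b = band_b, character_set = character_set,
    observed_diff = stat_obs,
    observed_min_a = min(pc$observed_a), observed_min_b = min(pc$observed_b),
    crit = quantile(null_diff, c(alpha / 2, 1 - alpha / 2), names = FALSE),
    p_scalar = perm_p(null_diff, stat_obs, "two_tailed"),
    null_diff = null_diff, n_perm = n_perm, alpha = alpha,
    side = "two_tailed", seed = seed, n_observers = pc$n_observers
  ), class = "permutation_result")
}
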