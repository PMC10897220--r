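# Psychometric fitting, threshold extraction, exclusion rules, and the
# multiple-comparison helpers of the threshold-experiment analysis.

sim_psych_data <- function(obs, n, seed, lo = -2.2, hi = 0) {
  withr::with_seed(seed, {
    cc <- 10^runif(n, lo, hi)
    list(contrast = cc, correct = runif(n) < observer_accuracy(obs, cc))
  })
}

test_that("maximum-likelihood fit recovers a known observer", {
  obs <- psych_observer(threshold = 0.1, target_p = 0.707, slope = 3,
                        lapse = 0.02, family = "cumulative_gaussian")
  d <- sim_psych_data(obs, 2000, seed = 1)
  fit <- fit_psychometric(d$contrast, d$correct, "cumulative_gaussian")
  expect_true(fit$converged)
  expect_equal(threshold_at(fit, 0.707), 0.1, tolerance = 0.1)
  # deterministic: identical data, identical fit
  fit2 <- fit_psychometric(d$contrast, d$correct, "cumulative_gaussian")
  expect_identical(fit, fit2)
  # Weibull family works on the same data
  fitw <- fit_psychometric(d$contrast, d$correct, "weibull")
  expect_true(fitw$converged)
  expect_equal(threshold_at(fitw, 0.707), 0.1, tolerance = 0.15)
})

test_that("inverse and forward accuracy close to machine precision", {
  obs <- psych_observer(threshold = 0.05, target_p = 0.75, slope = 4)
  d <- sim_psych_data(obs, 600, seed = 2)
  fit <- fit_psychometric(d$contrast, d$correct, "weibull")
  for (p in c(0.6, 0.707, 0.85)) {
    expect_equal(predict_accuracy(fit, threshold_at(fit, p)), p,
                 tolerance = 1e-6)
  }
})

test_that("degenerate and unattainable cases are flagged, not fatal", {
  cc <- rep(c(0.01, 0.1, 0.5), each = 10)
  fit <- fit_psychometric(cc, rep(TRUE, 30))
  expect_false(fit$converged)
  expect_error(threshold_at(fit, 0.707),
               class = "fovealmask_unattainable_accuracy")
  # a heavy lapse puts 70.7% out of reach
  lapsy <- structure(list(family = "weibull", threshold_param = -1,
                          slope_param = 3, lapse = 0.35, guess_rate = 0.5,
                          converged = TRUE), class = "psychometric_fit")
  expect_error(threshold_at(lapsy, 0.707),
               class = "fovealmask_unattainable_accuracy")
  expect_error(fit_psychometric(cc[1:10], rep(TRUE, 10)),
               class = "fovealmask_invalid_argument")
})

test_that("staircase convergence and psychometric threshold agree", {
  obs <- psych_observer(threshold = 0.08, target_p = 0.707, slope = 3.5,
                        lapse = 0.02)
  sc <- simulate_staircase_pair(obs, start_low = 0.01, start_high = 0.6,
                                n_trials = 2000, seed = 3)
  fit <- fit_psychometric(sc$contrast, sc$correct, "weibull")
  th <- threshold_at(fit, 0.707)
  expect_equal(th, 0.08, tolerance = 0.15)
})

test_that("exclusions are scoped to the failing character condition", {
  tbl <- tidyr::expand_grid(observer_id = c("o1", "o2"),
                            character_set = c("latin", "korean"),
                            eccentricity = c(0, 10),
                            noise_band = c("lsf", "msf"))
  tbl$threshold_contrast <- 0.1
  tbl$threshold_contrast[tbl$observer_id == "o1" &
                           tbl$character_set == "korean" &
                           tbl$eccentricity == 10 &
                           tbl$noise_band == "lsf"] <- NA_real_
  out <- apply_exclusions(tbl)
  excl <- out[!out$included, ]
  expect_true(all(excl$observer_id == "o1" & excl$character_set == "korean"))
  expect_equal(nrow(excl), 4)  # all korean cells of o1, latin kept
  expect_true(all(out$included[out$character_set == "latin"]))
  expect_equal(unique(excl$exclusion_reason), "threshold_unattainable")
  # global exclusion hook (e.g. poor fixation)
  out2 <- apply_exclusions(tbl, exclude_observers = "o2")
  expect_true(all(!out2$included[out2$observer_id == "o2"]))
  expect_equal(nrow(apply_exclusions(tbl[0, ])), 0)
})

test_that("Holm-Bonferroni step-down matches the hand-computed ladder", {
  r <- holm_bonferroni(c(0.01, 0.04), alpha = 0.05)
  expect_equal(r$p_adjusted, c(0.02, 0.04))
  expect_true(all(r$reject))
  expect_false(holm_bonferroni(0.6)$reject)
  expect_equal(nrow(holm_bonferroni(numeric(0))), 0)
  expect_error(holm_bonferroni(c(0.2, 1.4)),
               class = "fovealmask_invalid_argument")
})

test_that("paired sign-flip test separates shifted from exchangeable pairs", {
  withr::with_seed(8, {
    y <- rnorm(12)
    shifted <- paired_permutation_test(y + 1, y, n_perm = 2000, seed = 5)
    expect_lt(shifted$p, 0.01)
    null <- paired_permutation_test(y + rnorm(12, 0, 0.5), y,
                                    n_perm = 2000, seed = 6)
    expect_gt(null$p, 0.05)
  })
  expect_error(paired_permutation_test(1:3, 1:2),
               class = "fovealmask_invalid_argument")
})
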