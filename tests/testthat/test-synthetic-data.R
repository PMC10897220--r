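# Generative observers and trial-level simulators: masking kernel, effective
# d', session design fidelity, SDT closure, staircases and QUEST.

test_that("masking kernel combines the Gaussian dip and the cosine term", {
  p <- observer_params(dip_depth = c(lsf = 0.7, msf = 0, hsf = 0),
                       dip_center_ms = c(lsf = 220, msf = 185, hsf = 190),
                       dip_sd_ms = c(lsf = 30, msf = 25, hsf = 25),
                       osc_amp = 0)
  expect_equal(masking_kernel(p, "lsf", 220), 0.7)
  expect_equal(masking_kernel(p, "lsf", c(190, 250)),
               rep(0.7 * exp(-1 / 2), 2), tolerance = 1e-12)
  p2 <- observer_params(dip_depth = 0, osc_amp = c(lsf = 0.4, msf = 0, hsf = 0),
                        osc_phase_rad = 0)
  expect_equal(masking_kernel(p2, "lsf", 0), 0.4)  # cosine peak at phase 0
  expect_true(all(masking_kernel(p2, "lsf", seq(0, 400, 1)) >= 0))
})

test_that("effective d' reduces baseline by the windowed kernel and overlap", {
  d <- design_spec()
  expect_equal(trial_dprime(null_observer(d_base = 2), "none", c(0L, 12L), d),
               c(2, 2))
  none <- observer_params(d_base = 2, dip_depth = 0, osc_amp = 0,
                          simultaneity_cost = 0)
  expect_equal(trial_dprime(none, "lsf", 24L, d), 2)  # 200 ms, no masking
  # flat kernel of height k: zero-frequency cosine at phase 0
  flat <- observer_params(d_base = 2, dip_depth = 0, osc_freq_hz = 0,
                          osc_amp = c(lsf = 0.5, msf = 0.5, hsf = 0.5),
                          simultaneity_cost = 0)
  expect_equal(trial_dprime(flat, "lsf", 24L, d), 2 - 0.5)
  # simultaneity cost scales with the overlap fraction
  sim <- observer_params(d_base = 2, dip_depth = 0, osc_amp = 0,
                         simultaneity_cost = 0.7)
  expect_equal(trial_dprime(sim, "msf", 0L, d), 2 - 0.7)   # full overlap
  expect_equal(trial_dprime(sim, "msf", 36L, d), 2)        # none
  # never below zero
  deep <- observer_params(d_base = 0.1, dip_depth = 0, osc_freq_hz = 0,
                          osc_amp = 5, simultaneity_cost = 0)
  expect_equal(trial_dprime(deep, "hsf", 24L, d), 0)
})

test_that("session simulation matches the experimental design", {
  d <- design_spec()
  expect_equal(length(d$soa_frames), 40L)
  expect_equal(range(d$soa_frames) * d$frame_ms, c(-25, 300))
  d1 <- design_spec(n_sessions = 1)
  tr <- simulate_sessions(d1, null_observer(), n_observers = 2, seed = 1)
  expect_equal(nrow(tr), 2 * 620)
  counts <- table(tr$noise_band) / 2
  expect_equal(as.integer(counts[c("none", "lsf", "msf", "hsf")]),
               c(20L, 200L, 200L, 200L))
  expect_true(all(is.na(tr$soa_frame[tr$noise_band == "none"])))
  expect_true(all(tr$soa_frame[tr$noise_band != "none"] %in% d1$soa_frames))
  # SOAs repeated equally: 5 trials per frame per band per session
  one <- tr[tr$observer_id == "obs01" & tr$noise_band == "lsf", ]
  expect_true(all(table(one$soa_frame) == 5))
  # balanced truth within band
  expect_equal(sum(one$truth == "different"), 100)
  # seeded determinism
  expect_tibble_equal(tr, simulate_sessions(d1, null_observer(), 2, seed = 1))
})

test_that("simulated responses close the SDT loop", {
  d <- tiny_design(n_per_noise = 50000)
  p <- observer_params(d_base = 2, criterion = 1, lapse = 0, dip_depth = 0,
                       osc_amp = 0, simultaneity_cost = 0)
  tr <- simulate_sessions(d, p, 1, seed = 2)
  hit <- mean(tr$response[tr$truth == "different"] == "different")
  fa <- mean(tr$response[tr$truth == "same"] == "different")
  expect_lt(abs(hit - pnorm(2 - 1)), 0.01)
  expect_lt(abs(fa - pnorm(-1)), 0.01)
  # no sensitivity, neutral criterion: both response rates are 1/2
  p0 <- observer_params(d_base = 0, criterion = 0, lapse = 0, dip_depth = 0,
                        osc_amp = 0, simultaneity_cost = 0)
  tr0 <- simulate_sessions(d, p0, 1, seed = 3)
  expect_lt(abs(mean(tr0$response[tr0$truth == "different"] == "different") -
                  0.5), 0.01)
  expect_lt(abs(mean(tr0$response[tr0$truth == "same"] == "different") -
                  0.5), 0.01)
})

test_that("staircase moves monotonically for degenerate observers", {
  # observer that is essentially always correct in the tested range
  # floor kept far above the threshold, so accuracy ~1 everywhere tested
  easy <- psych_observer(threshold = 1e-4, slope = 8, lapse = 0)
  sc <- simulate_staircase(easy, start_contrast = 0.5, n_trials = 60,
                           bounds = c(0.01, 1), seed = 1)
  expect_true(all(diff(sc$contrast) <= 0))
  expect_equal(min(sc$contrast), 0.01)
  # observer that is essentially always wrong (at chance, coin responses)
  hard <- psych_observer(threshold = 0.999, slope = 60, lapse = 0)
  set.seed(2)
  sc2 <- simulate_staircase(hard, start_contrast = 0.01, n_trials = 200,
                            bounds = c(1e-4, 0.5), seed = 2)
  # never two consecutive correct at chance-half rate pushes it upward
  expect_gt(mean(tail(sc2$contrast, 50)), 0.2)
  expect_error(simulate_staircase(easy, start_contrast = 2),
               class = "fovealmask_invalid_argument")
})

test_that("2-up-1-down staircase converges near the 70.7% level", {
  obs <- psych_observer(threshold = 0.05, target_p = 0.75, slope = 3.5,
                        lapse = 0)
  sc <- simulate_staircase(obs, start_contrast = 0.1, n_trials = 4000,
                           seed = 11)
  lev <- staircase_converged_level(sc)
  expect_lt(abs(observer_accuracy(obs, lev) - sqrt(0.5)), 0.03)
})

test_that("QUEST is deterministic and lands near the observer's 75% point", {
  obs <- psych_observer(threshold = 0.05, target_p = 0.75, slope = 3.5,
                        lapse = 0)
  q1 <- simulate_quest(obs, n_trials = 80, lapse = 0, seed = 5)
  q2 <- simulate_quest(obs, n_trials = 80, lapse = 0, seed = 5)
  expect_identical(q1$threshold, q2$threshold)
  expect_error(simulate_quest(obs, target_p = 0.4),
               class = "fovealmask_invalid_argument")
  # a near-step observer pins the estimate to the step location
  steep <- psych_observer(threshold = 0.1, target_p = 0.75, slope = 30,
                          lapse = 0, family = "cumulative_gaussian")
  qs <- simulate_quest(steep, n_trials = 80, lapse = 0, seed = 6)
  expect_equal(qs$threshold, 0.1, tolerance = 0.15)
  # averaged over replicates, accuracy at the pair estimate is ~75%
  acc <- vapply(1:60, function(i)
    observer_accuracy(obs, quest_pair(obs, seed = i, lapse = 0)), numeric(1))
  expect_lt(abs(mean(acc) - 0.75), 0.03)
})

test_that("threshold-experiment simulator carries the designed structure", {
  tr <- simulate_exp2(n_observers = 2, seed = 9)
  expect_equal(nrow(tr), 2 * 640)
  expect_equal(sort(unique(tr$eccentricity)), c(0, 10))
  expect_equal(sort(unique(tr$noise_band)), c("lsf", "msf"))
  tt <- attr(tr, "true_thresholds")
  expect_equal(nrow(tt), 2 * 8)
  # generative ordering: MSF > LSF at fixation, LSF > MSF at 10 deg
  g <- exp2_true_thresholds()
  expect_gt(g$threshold[g$eccentricity == 0 & g$noise_band == "msf"],
            g$threshold[g$eccentricity == 0 & g$noise_band == "lsf"])
  expect_gt(g$threshold[g$eccentricity == 10 & g$noise_band == "lsf"],
            g$threshold[g$eccentricity == 10 & g$noise_band == "msf"])
})
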