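test_that("a constant heart period produces beats at exact multiples", {
  ev <- generate_trial_sequence(tiny_design(trials = 1, lead_in = 5,
                                            lead_out = 5), "recall", 1)
  beats <- simulate_heart_beats(ev, rf_registry("hprf_rew"), c(0, 0), 1.0,
                                list(spectrum = "white", sd = 0), t_end = 30)
  expect_equal(beats, 0:30, tolerance = 1e-9)
})

test_that("a single trial adds the kernel's area to the heart period", {
  spec <- tiny_design(trials = 1, lead_in = 60, lead_out = 120)
  ev <- generate_trial_sequence(spec, "recall", seed = 2)
  ev <- ev[1, ]
  t_end <- ev$cs_onset + 150
  hprf <- rf_registry("hprf_rew")
  beats <- simulate_heart_beats(ev, hprf, 50, 1.0,
                                list(spectrum = "white", sd = 0), t_end)
  ibi <- beats_to_ibi(beats)
  # brute-force integral of (h - baseline) over the session, in ms*s
  excess <- sum((ibi$ibi - 1.0) * 1000 * ibi$ibi)
  kt <- seq(hprf$support[1], hprf$support[2], by = 0.01)
  kernel_area <- sum(rf_evaluate(hprf, kt, normalise = TRUE)) * 0.01
  expect_equal(excess, 50 * kernel_area, tolerance = 0.01 * abs(50 * kernel_area))
})

test_that("an unphysiological period specification errors", {
  ev <- generate_trial_sequence(tiny_design(trials = 1, lead_in = 5,
                                            lead_out = 5), "recall", 1)
  expect_error(
    simulate_heart_beats(ev, rf_registry("hprf_rew"), c(-300, -300), 0.21,
                         list(spectrum = "white", sd = 0), t_end = 30),
    "unphysiological")
})

test_that("same seed reproduces identical recordings", {
  design <- tiny_design(trials = 2, lead_in = 30, lead_out = 30)
  a <- simulate_cohort(design, noiseless_cohort(n = 2, seed = 5))
  b <- simulate_cohort(design, noiseless_cohort(n = 2, seed = 5))
  expect_identical(a, b)
  c <- simulate_cohort(design, noiseless_cohort(n = 2, seed = 6))
  expect_false(identical(a[[1]]$beats, c[[1]]$beats))
})

test_that("a null effect with all noise off yields identical trial truths", {
  design <- tiny_design(trials = 3, lead_in = 30, lead_out = 30)
  coh <- simulate_cohort(design, noiseless_cohort(n = 2, delta = 0))
  truth <- coh[[1]]$truth
  for (ch in c("heart", "scr", "pupil", "resp")) {
    expect_equal(length(unique(truth[[ch]][truth$condition == "CS+"])), 1L)
    expect_equal(unique(truth[[ch]][truth$condition == "CS+"]),
                 unique(truth[[ch]][truth$condition == "CS-"]))
  }
})

test_that("pink noise is scaled and autocorrelated", {
  x <- pavcal:::with_seed(3, pavcal:::pink_noise(20000, sd = 2))
  expect_equal(sd(x), 2, tolerance = 1e-6)
  ac <- acf(x, lag.max = 5, plot = FALSE)$acf
  expect_gt(ac[2], 0.3)   # white noise would be ~0
})

test_that("blinks produce missing spans in the pupil channel", {
  ev <- generate_trial_sequence(tiny_design(trials = 2, lead_in = 10,
                                            lead_out = 10), "recall", 3)
  rec <- pavcal:::with_seed(8,
    simulate_pupil(ev, rf_registry("psr_rf3"), rep(0.1, nrow(ev)), 4,
                   list(spectrum = "white", sd = 0), t_end = 80,
                   blink_rate_per_min = 20))
  expect_gt(sum(!rec$pupil$valid), 0)
  expect_true(all(is.na(rec$pupil$values[!rec$pupil$valid])))
})

test_that("amplitude-layer cohort matches its closed-form effect size", {
  eff <- true_paired_effect(delta = 0.5590170, between_sd = 1, trial_sd = 2,
                            n_csp = 24, n_csm = 48)
  expect_equal(eff, 0.5, tolerance = 1e-6)
  d <- pavcal:::with_seed(10, {
    reps <- replicate(4000, {
      z <- simulate_amplitude_cohort(8, delta = 0.559017)
      mean(z$csp - z$csm) / sd(z$csp - z$csm)
    })
    mean(reps)
  })
  # mean observed Cohen's d approximates the true effect / J correction
  expect_equal(d * hedges_correction(7), 0.5, tolerance = 0.03)
})

test_that("the statistical truth propagates into the full generator", {
  design <- tiny_design(trials = 3, lead_in = 30, lead_out = 30)
  spec <- noiseless_cohort(n = 3, delta = 0.8)
  coh <- simulate_cohort(design, spec)
  for (rec in coh) {
    tr <- rec$truth
    expect_equal(mean(tr$heart[tr$condition == "CS+"]) -
                 mean(tr$heart[tr$condition == "CS-"]),
                 0.8 * 15, tolerance = 1e-9)
  }
})
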