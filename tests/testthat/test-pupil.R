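make_pupil_rec <- function(ev, rf, amps, t_end, noise_sd = 0) {
  pavcal:::with_seed(5,
    simulate_pupil(ev, rf, amps, 4, list(spectrum = "white", sd = noise_sd),
                   t_end, blink_rate_per_min = 0,
                   gaze_excursion_per_min = 0))
}

test_that("gaze excursions beyond 5 degrees are marked missing", {
  n <- 100 * 60
  ts <- pav_ts(rep(4, n), rate = 100, units = "mm")
  gx <- rep(0, n); gy <- rep(0, n)
  gx[2000:2100] <- 6
  ev <- generate_trial_sequence(tiny_design(trials = 1, lead_in = 5,
                                            lead_out = 5), "recall", 1)
  out <- suppressWarnings(pupil_preprocess(ts, gx, gy, ev, zscore = FALSE))
  expect_true(all(!out$valid[2005:2095]))
  expect_true(all(out$valid[3000:4000]))
})

test_that("block z-scoring gives per-block mean 0 and SD 1", {
  spec <- tiny_design(trials = 4, blocks = 2, lead_in = 10, lead_out = 10)
  ev <- generate_trial_sequence(spec, "recall", seed = 7)
  t_end <- pavcal:::session_end(ev, spec)
  rf <- rf_registry("psr_rf3")
  rec <- make_pupil_rec(ev, rf, flat_amps(ev, 0.2, 0.1), t_end,
                        noise_sd = 0.02)
  out <- pupil_preprocess(rec$pupil, rec$gaze_x, rec$gaze_y, ev,
                          zscore = TRUE)
  tg <- ts_time(out)
  b2start <- min(ev$cs_onset[ev$block == 2])
  for (idx in list(tg < b2start, tg >= b2start)) {
    expect_equal(mean(out$values[idx]), 0, tolerance = 1e-8)
    expect_equal(sd(out$values[idx]), 1, tolerance = 1e-6)
  }
})

test_that("downstream estimates are invariant to a constant block shift", {
  spec <- tiny_design(trials = 3, lead_in = 10, lead_out = 10)
  ev <- generate_trial_sequence(spec, "recall", seed = 8)
  t_end <- pavcal:::session_end(ev, spec)
  rf <- rf_registry("psr_rf3")
  rec <- make_pupil_rec(ev, rf, flat_amps(ev, 0.2, 0.1), t_end,
                        noise_sd = 0.02)
  # centred gaze isolates the z-score property from the (gaze-dependent)
  # foreshortening correction
  zero <- rep(0, length(rec$pupil$values))
  p1 <- pupil_preprocess(rec$pupil, zero, zero, ev)
  shifted <- rec$pupil
  shifted$values <- shifted$values + 0.5
  p2 <- pupil_preprocess(shifted, zero, zero, ev)
  a1 <- psr_amplitudes(extract_pupil_segments(p1, ev, rf), rf)
  a2 <- psr_amplitudes(extract_pupil_segments(p2, ev, rf), rf)
  expect_equal(a1$amplitude, a2$amplitude, tolerance = 1e-4)
})

test_that("segment retention follows the kernel rules", {
  spec <- design_spec()
  ev <- generate_trial_sequence(spec, "learning", seed = 9)
  ts <- pav_ts(rep(0, 100 * 2200), rate = 100)
  s1 <- extract_pupil_segments(ts, ev, "psr_rf1")
  expect_identical(sum(s1$trials$condition == "CS+"), 24L)  # nonreinforced
  expect_identical(sum(s1$trials$condition == "CS-"), 48L)
  s5 <- extract_pupil_segments(ts, ev, "psr_rf5")
  expect_identical(nrow(s5$trials), 96L)
  expect_equal(max(s5$rel_time), 3)
})

test_that("trial-wise amplitudes recover injected values for each family", {
  spec <- tiny_design(trials = 6)
  ev <- generate_trial_sequence(spec, "learning", seed = 10)
  t_end <- pavcal:::session_end(ev, spec)
  amps <- flat_amps(ev, 0.16, 0.1)
  for (nm in c("psr_rf2", "psr_rf3", "psr_rf5")) {
    rf <- rf_registry(nm)
    rec <- make_pupil_rec(ev, rf, amps, t_end)
    pts <- pupil_preprocess(rec$pupil, rec$gaze_x, rec$gaze_y, ev,
                            zscore = FALSE)
    est <- psr_amplitudes(extract_pupil_segments(pts, ev, rf), rf)
    expect_lt(max(abs(est$amplitude - amps) / amps), 0.02)
  }
  # RF1 via the session-wide joint GLM
  rf1 <- rf_registry("psr_rf1")
  rec <- make_pupil_rec(ev, rf1, amps, t_end)
  pts <- pupil_preprocess(rec$pupil, rec$gaze_x, rec$gaze_y, ev,
                          zscore = FALSE)
  est <- psr_amplitudes_joint(pts, ev, rf1)
  truth <- amps[match(est$trial_index, ev$trial_index)]
  expect_lt(max(abs(est$amplitude - truth) / truth), 0.02)
})

test_that("peak scoring follows the two window conventions exactly", {
  # one trial: flat 3.0 mm, then linear rise to 3.4 mm at 5 s post-onset
  rate <- 100
  onset <- 30
  t <- seq(0, 60, by = 1 / rate)
  x <- rep(3, length(t))
  rise <- t >= onset & t <= onset + 5
  x[rise] <- 3 + 0.4 * (t[rise] - onset) / 5
  x[t > onset + 5] <- 3.4
  ts <- pav_ts(x, rate = rate, units = "mm")
  ev <- data.frame(trial_index = 1L, block = 1L, condition = "CS+",
                   reinforced = FALSE, cs_onset = onset, us_onset = NA,
                   iti_duration = 10L, swallow_onset = onset + 8)
  segs <- extract_pupil_segments(ts, ev, rf = NULL, window = 5)
  m1 <- peak_score(segs, "finke")
  m2 <- peak_score(segs, "pietrock")
  expect_equal(m1$amplitude, 0.4, tolerance = 1e-6)
  expect_equal(m2$amplitude, 0.4, tolerance = 1e-6)
  # flat trial scores zero
  segs0 <- extract_pupil_segments(pav_ts(rep(3, length(t)), rate = rate),
                                  ev, rf = NULL, window = 5)
  expect_equal(peak_score(segs0, "finke")$amplitude, 0)
})

test_that("an all-missing baseline marks the trial missing", {
  rate <- 100
  t <- seq(0, 60, by = 1 / rate)
  x <- rep(3, length(t))
  valid <- rep(TRUE, length(t))
  valid[t >= 28.9 & t <= 30.1] <- FALSE   # covers the 1-s pre-CS baseline
  ts <- pav_ts(x, rate = rate, valid = valid)
  ev <- data.frame(trial_index = 1L, block = 1L, condition = "CS+",
                   reinforced = FALSE, cs_onset = 30, us_onset = NA,
                   iti_duration = 10L, swallow_onset = 38)
  segs <- extract_segments(ts, ev, window = 5, baseline_window = 1,
                           retain = "all")
  expect_true(is.na(peak_score(segs, "finke")$amplitude))
})

test_that("exclusion rules drop implausible trials and flag participants", {
  est <- data.frame(trial_index = 1:96,
                    condition = rep(c("CS+", "CS-"), 48),
                    reinforced = FALSE,
                    amplitude = rep(0.2, 96),
                    missing_fraction = 0)
  est$amplitude[1] <- -6.5
  out <- apply_pupil_exclusions(est)
  expect_identical(out$n_excluded, 1L)
  expect_false(out$participant_excluded)
  # 49 of 96 trials bad -> participant excluded
  est$missing_fraction[1:49] <- 0.8
  out <- apply_pupil_exclusions(est)
  expect_identical(out$n_excluded, 49L)
  expect_true(out$participant_excluded)
})

test_that("a blink covering trial and baseline flags that trial missing", {
  spec <- tiny_design(trials = 2, lead_in = 20, lead_out = 20)
  ev <- generate_trial_sequence(spec, "recall", seed = 12)
  t_end <- pavcal:::session_end(ev, spec)
  rf <- rf_registry("psr_rf3")
  rec <- make_pupil_rec(ev, rf, rep(0.1, nrow(ev)), t_end)
  # blank out trial 2 entirely, including its baseline
  tg <- ts_time(rec$pupil)
  span <- tg >= ev$cs_onset[2] - 2.2 & tg <= ev$cs_onset[2] + 5.5
  rec$pupil$valid[span] <- FALSE
  rec$pupil$values[span] <- NA
  pts <- pupil_preprocess(rec$pupil, rec$gaze_x, rec$gaze_y, ev,
                          zscore = FALSE)
  segs <- extract_pupil_segments(pts, ev, rf = NULL, window = 5)
  sc <- peak_score(segs, "finke")
  expect_true(is.na(sc$amplitude[2]))
  expect_false(is.na(sc$amplitude[1]))
})
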