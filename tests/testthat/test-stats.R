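test_that("the g conversion reproduces the reference contrast table", {
  ref <- read.delim(system.file("extdata", "reference_contrasts.tsv",
                                package = "pavcal"))
  g <- hedges_g(ref$t, ref$n)
  expect_equal(round(g, 2), ref$g_printed)
})

test_that("hedges_g basic properties hold", {
  expect_equal(hedges_g(0, 20), 0)
  expect_error(hedges_g(1, 1), "n >= 2")
  t_seq <- seq(-3, 3, by = 0.5)
  g_seq <- hedges_g(t_seq, 15)
  expect_true(all(diff(g_seq) > 0))               # monotone in t
  expect_true(all(abs(g_seq) < abs(t_seq / sqrt(15)) + 1e-12))
  expect_true(all(hedges_correction(c(5, 10, 50, 200)) < 1))
})

test_that("the correction factor matches a Monte-Carlo bias estimate", {
  # at df = 10, E[d_hat] = delta / J(df); so mean(d_hat) * J ~ delta
  sim <- pavcal:::with_seed(21, replicate(40000, {
    x <- rnorm(11, mean = 1)
    mean(x) / sd(x)
  }))
  expect_equal(mean(sim) * hedges_correction(10), 1, tolerance = 0.02)
})

test_that("paired_ttest matches the textbook formula", {
  set.seed(14)
  csp <- rnorm(10, 1)
  csm <- rnorm(10)
  res <- paired_ttest(csp, csm)
  d <- csp - csm
  t_ref <- mean(d) / (sd(d) / sqrt(10))
  p_ref <- 2 * pt(-abs(t_ref), 9)
  expect_equal(res$t, t_ref)
  expect_equal(res$p, p_ref)
  expect_equal(res$df, 9)
  expect_equal(res$g, hedges_g(t_ref, 10))
  one <- paired_ttest(csp, csm, sides = "one")
  expect_equal(one$p, pt(t_ref, 9, lower.tail = FALSE))
})

test_that("degenerate paired inputs behave as specified", {
  x <- c(1, 2, 3, 4)
  res <- paired_ttest(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$g, 0)
  expect_error(paired_ttest(x + 1, x), "zero variance")
  jit <- x + 1 + c(1e-6, -1e-6, 1e-6, -1e-6)
  res2 <- paired_ttest(jit, x)
  expect_gt(res2$t, 100)
  expect_gt(res2$g, 0)
})

test_that("3-SD exclusion masks gross outliers and nothing else", {
  set.seed(15)
  csp <- rnorm(30)
  csm <- rnorm(30)
  csp[7] <- 10
  keep <- exclude_outliers_3sd(csp, csm)
  expect_false(keep[7])
  expect_true(all(keep[-7]))
  expect_true(all(exclude_outliers_3sd(rep(1, 5), rep(2, 5))))
  # order invariance
  ord <- sample(30)
  expect_identical(exclude_outliers_3sd(csp[ord], csm[ord]), keep[ord])
})

test_that("a constant condition difference gives a flat g(n) curve", {
  est <- do.call(rbind, lapply(1:6, function(p)
    data.frame(participant = p, trial_index = 1:20,
               condition = rep(c("CS+", "CS-"), 10), reinforced = FALSE,
               amplitude = rep(c(1 + 0.2 * p, 1), 10))))
  scan <- trial_subset_scan(est)
  expect_true(all(abs(diff(scan$g)) < 1e-9))
  expect_identical(nrow(scan), 10L)
})

test_that("an early-trials-only effect peaks the g(n) curve at small n", {
  set.seed(16)
  est <- do.call(rbind, lapply(1:20, function(p) {
    csp_amp <- c(rep(1.5, 5), rep(0, 15)) + rnorm(20, sd = 0.8)
    csm_amp <- rnorm(20, sd = 0.8)
    rbind(data.frame(participant = p, trial_index = seq(1, 40, 2),
                     condition = "CS+", reinforced = FALSE,
                     amplitude = csp_amp),
          data.frame(participant = p, trial_index = seq(2, 40, 2),
                     condition = "CS-", reinforced = FALSE,
                     amplitude = csm_amp))
  }))
  scan <- trial_subset_scan(est)
  expect_lte(which.max(scan$g), 7)
  expect_gt(max(scan$g), scan$g[nrow(scan)])
})

test_that("the nonreinforced scheme pairs n CS+ with 2n CS-", {
  set.seed(44)
  est <- do.call(rbind, lapply(1:4, function(p) {
    df <- data.frame(participant = p, trial_index = 1:12,
                     condition = rep(c("CS+", "CS-", "CS-"), 4),
                     reinforced = FALSE, amplitude = 1:12 + rnorm(12))
    df$reinforced[df$trial_index == 1] <- TRUE  # first CS+ reinforced
    df
  }))
  scan <- trial_subset_scan(est, scheme = "nonreinforced_pairing")
  # 3 nonreinforced CS+, 8 CS- -> n ranges 1..3
  expect_identical(nrow(scan), 3L)
})

test_that("halves analysis separates an effect confined to the first half", {
  set.seed(17)
  est <- do.call(rbind, lapply(1:15, function(p) {
    df <- data.frame(participant = p, trial_index = 1:24,
                     condition = rep(c("CS+", "CS-"), 12),
                     reinforced = FALSE, amplitude = rnorm(24, sd = 0.3))
    early_csp <- df$condition == "CS+" & df$trial_index <= 12
    df$amplitude[early_csp] <- df$amplitude[early_csp] + 2
    df
  }))
  res <- halves_analysis(est)
  expect_gt(res$first$g, 1)
  expect_lt(abs(res$second$g), 0.8)
  expect_gt(res$first$g, res$second$g)
})

test_that("halves partition the trials exactly", {
  est <- data.frame(participant = 1, trial_index = 1:8,
                    condition = rep(c("CS+", "CS-"), 4), reinforced = FALSE,
                    amplitude = c(rep(1, 4), rep(3, 4)))
  parts <- split(est, est$trial_index <= median(est$trial_index))
  expect_identical(sum(vapply(parts, nrow, 0L)), nrow(est))
})

test_that("Holm correction matches its step-down definition", {
  res <- holm_bonferroni(c(0.01, 0.04))
  expect_true(all(res$reject))
  expect_equal(holm_bonferroni(0.03)$adjusted, 0.03)
  # brute-force enumeration oracle for 5 p-values
  set.seed(18)
  p <- round(runif(5, 0, 0.2), 3)
  ord <- order(p)
  adj_ref <- numeric(5)
  running <- 0
  for (k in seq_along(ord)) {
    running <- max(running, (5 - k + 1) * p[ord[k]])
    adj_ref[ord[k]] <- min(1, running)
  }
  expect_equal(holm_bonferroni(p)$adjusted, adj_ref)
})

test_that("type-I error of the paired test is calibrated at alpha = 0.05", {
  rej <- pavcal:::with_seed(19, replicate(1500, {
    z <- simulate_amplitude_cohort(34, delta = 0)
    paired_ttest(z$csp, z$csm)$p < 0.05
  }))
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("the calibration report flags exactly the injected channels", {
  set.seed(20)
  big <- data.frame(participant = 1:40, csp = rnorm(40, 1.2),
                    csm = rnorm(40))
  null <- data.frame(participant = 1:40, csp = rnorm(40), csm = rnorm(40))
  rep <- calibration_report(list(hpr = big, scr = null))
  expect_true(rep$retained[rep$measure == "hpr"])
  expect_false(rep$retained[rep$measure == "scr"])
  expect_named(rep, c("measure", "n", "n_excluded", "csp_mean", "csp_sd",
                      "csm_mean", "csm_sd", "t", "df", "p", "g", "retained"))
  # deterministic given inputs
  expect_identical(rep, calibration_report(list(hpr = big, scr = null)))
})
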