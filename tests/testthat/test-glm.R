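test_that("span membership gives exact betas", {
  spec <- tiny_design()
  ev <- generate_trial_sequence(spec, "recall", seed = 1)
  rf <- rf_registry("psr_rf5")
  n <- 100 * 300
  des <- build_design(ev, rf, rate = 100, n_samples = n, mode = "condition")
  y <- 3.0 * des$X[, "CS+"] + 0.0 * des$X[, "CS-"]
  fit <- glm_invert(y, des)
  expect_equal(unname(fit$betas["CS+"]), 3.0, tolerance = 1e-12)
  expect_equal(unname(fit$betas["CS-"]), 0.0, tolerance = 1e-12)
  expect_equal(fit$dof, n - 3L)
})

test_that("an impulse at t = 0 convolved with a kernel reproduces it", {
  rf <- rf_registry("psr_rf2")
  ev <- data.frame(trial_index = 1L, block = 1L, condition = "CS+",
                   reinforced = FALSE, cs_onset = 0, us_onset = NA,
                   iti_duration = 10L, swallow_onset = 8)
  des <- build_design(ev, rf, rate = 100, n_samples = 500,
                      mode = "trial", intercept = FALSE)
  g <- (0:499) / 100
  inside <- g <= rf$support[2]
  expect_equal(unname(des$X[inside, 1]),
               rf_evaluate(rf, g[inside], normalise = TRUE),
               tolerance = 1e-12)
  expect_true(all(des$X[!inside, 1] == 0))  # kernel truncated at support
})

test_that("trial regressors are orthogonal when the kernel fits the gap", {
  spec <- tiny_design()
  ev <- generate_trial_sequence(spec, "recall", seed = 2)
  rf <- rf_registry("psr_rf3")   # 3-s support << 15-s spacing
  n <- 100 * 300
  des <- build_design(ev, rf, rate = 100, n_samples = n, mode = "trial",
                      intercept = FALSE)
  G <- crossprod(des$X)
  offdiag <- G[upper.tri(G)]
  expect_true(all(abs(offdiag) < 1e-10 * max(diag(G))))
})

test_that("invert matches an independent normal-equations solver", {
  set.seed(31)
  X <- cbind(1, matrix(rnorm(200 * 4), 200, 4))
  colnames(X) <- c("(intercept)", paste0("b", 1:4))
  y <- rnorm(200)
  fit <- glm_invert(y, X)
  # brute-force normal equations, no shared code path
  ref <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(fit$betas), unname(drop(ref)), tolerance = 1e-10)
})

test_that("pure noise on an orthogonal design gives near-zero betas", {
  set.seed(5)
  X <- qr.Q(qr(matrix(rnorm(500 * 3), 500, 3))) * 10
  colnames(X) <- paste0("r", 1:3)
  y <- rnorm(500, sd = 0.1)
  fit <- glm_invert(y, X)
  expect_true(all(abs(fit$betas) < 0.1))
  expect_lt(fit$r_squared, 0.05)
})

test_that("rank deficiency is a loud error, never a silent pseudo-inverse", {
  X <- cbind(a = rnorm(50), b = rnorm(50))
  X <- cbind(X, c = X[, 1] + X[, 2])
  expect_error(glm_invert(rnorm(50), X), "rank-deficient")
})

test_that("inversion is linear in the data", {
  set.seed(8)
  X <- cbind(1, rnorm(120), rnorm(120))
  colnames(X) <- c("i", "a", "b")
  y1 <- rnorm(120)
  y2 <- rnorm(120)
  b1 <- glm_invert(y1, X)$betas
  b2 <- glm_invert(y2, X)$betas
  b12 <- glm_invert(2 * y1 - 0.5 * y2, X)$betas
  expect_equal(b12, 2 * b1 - 0.5 * b2, tolerance = 1e-10)
})

test_that("beta estimates are unbiased under Gaussian noise", {
  set.seed(13)
  spec <- tiny_design(trials = 4)
  ev <- generate_trial_sequence(spec, "recall", seed = 4)
  rf <- rf_registry("psr_rf3")
  n <- 100 * 250
  des <- build_design(ev, rf, rate = 100, n_samples = n, mode = "condition")
  truth <- c(2, 1, 0)
  signal <- des$X %*% truth
  errs <- replicate(400, {
    fit <- glm_invert(drop(signal) + rnorm(n, sd = 1), des)
    fit$betas["CS+"] - 2
  })
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * se + 1e-12)
})

test_that("segment projection matches a one-trial design inversion", {
  rf <- rf_registry("psr_rf3")
  g <- seq(0, 3, by = 0.01)
  k <- rf_evaluate(rf, g, normalise = TRUE)
  seg <- 2.5 * k
  expect_equal(trialwise_amplitude(seg, k), 2.5, tolerance = 1e-12)
  # orthogonal segment
  ortho <- sin(2 * pi * 5 * g)
  ortho <- ortho - k * sum(ortho * k) / sum(k * k)
  expect_equal(trialwise_amplitude(ortho, k), 0, tolerance = 1e-10)
  # internal consistency with full inversion
  X <- matrix(k, ncol = 1, dimnames = list(NULL, "trial_1"))
  seg2 <- 1.7 * k + 0.01 * ortho
  expect_equal(trialwise_amplitude(seg2, k),
               unname(glm_invert(seg2, X)$betas["trial_1"]),
               tolerance = 1e-12)
})

test_that("all-missing segments yield a missing amplitude", {
  k <- rf_evaluate(rf_registry("psr_rf3"), seq(0, 3, 0.01), normalise = TRUE)
  expect_true(is.na(trialwise_amplitude(rep(NA_real_, length(k)), k)))
})
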