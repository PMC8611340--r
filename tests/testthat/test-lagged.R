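test_that("the lag design maps temporal positions to lags correctly", {
  sched <- toy_schedule(as.numeric(1:8))
  r <- toy_ratings(sched, c(0.1, 0.2))
  d <- build_lag_design(sched, r, "valence")
  expect_equal(nrow(d), 2)
  # lag1 is the image immediately before the rating (position 4)
  expect_equal(d$S_lag1, c(4, 8))
  expect_equal(d$S_lag4, c(1, 5))
  expect_equal(d$rating, c(0.1, 0.2))
  # control blocks: 19 rows x 4 lag columns per participant
  ctrl <- shared_schedule[shared_schedule$block_type == "control", ]
  pars <- list(valence = wi_params(0, beta = 0.3), arousal = wi_params(0, beta = 0.2))
  rc <- simulate_ratings(ctrl, "WI", pars, noise_sd = 0.5, seed = 1)
  dc <- build_lag_design(ctrl, rc, "valence")
  expect_equal(nrow(dc), 19 * 2)
  expect_false("rel_lag1" %in% names(dc))
})

test_that("relevance indicators join the design only for task blocks", {
  pars <- list(valence = wi_params(0, beta = 0.3, beta_rel = 0.4, beta_irr = 0.2),
               arousal = wi_params(0, beta = 0.2, beta_rel = 0.2, beta_irr = 0.2))
  r <- simulate_ratings(shared_schedule, "WI", pars, noise_sd = 0.5, seed = 2)
  d <- build_lag_design(shared_schedule, r, "valence", include_relevance = TRUE)
  expect_equal(nrow(d), 76 * 2) # task ratings only
  expect_true(all(paste0("rel_lag", 1:4) %in% names(d)))
  expect_true(all(d[paste0("rel_lag", 1:4)] == 0 | d[paste0("rel_lag", 1:4)] == 1))
  # indicator balance mirrors the schedule: 38 relevant per position & participant
  expect_equal(sum(d$rel_lag1), 38 * 2)
})

test_that("Wald comparisons match hand calculation and its symmetries", {
  f <- list(coef = c(a = 0.3, b = 0.1),
            cov = matrix(c(0.01, 0, 0, 0.01), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))
  w <- wald_compare(f, "a", "b")
  expect_equal(w$z, sqrt(2), tolerance = 1e-6)
  expect_equal(w$p, 0.1573, tolerance = 1e-3)
  # equal coefficients
  f2 <- f; f2$coef <- c(a = 0.2, b = 0.2)
  expect_equal(wald_compare(f2, "a", "b")$z, 0)
  expect_equal(wald_compare(f2, "a", "b")$p, 1)
  # antisymmetry and shift invariance
  expect_equal(wald_compare(f, "b", "a")$z, -w$z)
  expect_equal(wald_compare(f, "b", "a")$p, w$p)
  f3 <- f; f3$coef <- f$coef + 5
  expect_equal(wald_compare(f3, "a", "b")$z, w$z)
})

test_that("Holm step-down correction matches hand computation and dominates Bonferroni", {
  h <- holm_bonferroni(c(x = 0.01, y = 0.03, z = 0.04))
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06))
  expect_equal(h$reject, c(TRUE, FALSE, FALSE))
  expect_true(all(!holm_bonferroni(rep(1, 4))$reject))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(6)^2
    holm_rej <- holm_bonferroni(p)$reject
    bonf_rej <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(holm_rej[bonf_rej])) # Holm rejects a superset
  }
})

test_that("paired t-test sample size reproduces the a-priori power analysis", {
  expect_equal(paired_ttest_sample_size(0.5, power = 0.95, alpha = 0.05), 54)
  expect_lt(paired_ttest_sample_size(1, power = 0.95, alpha = 0.05), 54)
  # definition check: power crosses the target exactly at the returned n
  pow <- function(n, dz = 0.5) {
    crit <- qt(0.975, n - 1)
    1 - pt(crit, n - 1, dz * sqrt(n)) + pt(-crit, n - 1, dz * sqrt(n))
  }
  expect_gte(pow(54), 0.95)
  expect_lt(pow(53), 0.95)
})

test_that("regression on WI-simulated data recovers recency and relevance effects", {
  sch <- build_schedule(12, shared_catalog, seed = 99)
  task <- sch[sch$block_type == "task", ]
  pars <- list(valence = wi_params(0, beta_rel = 0.4, beta_irr = 0.2),
               arousal = wi_params(0, beta_rel = 0.15, beta_irr = 0.12))
  r <- simulate_ratings(task, "WI", pars, noise_sd = 0.5, seed = 99)
  d <- build_lag_design(task, r, "valence", include_relevance = TRUE)
  fit <- fit_lagged_model(d, method = "two_stage")
  # recency: the most recent image contributes most
  expect_gt(fit$coef[["S_lag1"]], fit$coef[["S_lag4"]])
  expect_gt(fit$coef[["S_lag1"]], 0)
  # beta_rel > beta_irr shows up as positive recent-lag interactions
  expect_gt(fit$coef[["S_lag1:rel_lag1"]], 0)
  expect_gt(fit$coef[["S_lag2:rel_lag2"]], 0)
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$cov))), tolerance = 1e-12)
})

test_that("the mixed-model route runs and agrees with the two-stage summary", {
  sch <- build_schedule(8, shared_catalog, seed = 55)
  task <- sch[sch$block_type == "task", ]
  pars <- list(valence = wi_params(0, beta_rel = 0.35, beta_irr = 0.25),
               arousal = wi_params(0, beta_rel = 0.15, beta_irr = 0.12))
  r <- simulate_ratings(task, "WI", pars, noise_sd = 0.5, seed = 56)
  d <- build_lag_design(task, r, "valence", include_relevance = TRUE)
  f_lmm <- fit_lagged_model(d, method = "lmm")
  f_ts <- fit_lagged_model(d, method = "two_stage")
  expect_s3_class(f_lmm, "lagged_fit")
  expect_true(all(is.finite(f_lmm$se)))
  # in this balanced design the estimators agree closely
  expect_lt(max(abs(f_lmm$coef - f_ts$coef)), 0.05)
  expect_gt(f_lmm$coef[["S_lag1"]], f_lmm$coef[["S_lag4"]])
})

test_that("under the null, per-coefficient estimates are calibrated", {
  sch <- build_schedule(20, shared_catalog, seed = 77)
  ctrl <- sch[sch$block_type == "control", ]
  set.seed(123)
  n_runs <- 20
  covered <- 0L
  total <- 0L
  for (run in seq_len(n_runs)) {
    idx <- which(ctrl$is_rating_trial)
    r <- data.frame(
      participant_id = ctrl$participant_id[idx],
      block_index = ctrl$block_index[idx],
      block_type = "control",
      rating_index = ctrl$window[idx],
      trial_index = ctrl$trial_index[idx],
      valence_std = rnorm(length(idx)), arousal_std = rnorm(length(idx)),
      stringsAsFactors = FALSE)
    d <- build_lag_design(ctrl, r, "valence")
    fit <- fit_lagged_model(d, method = "two_stage")
    covered <- covered + sum(abs(fit$coef) < 2 * fit$se)
    total <- total + length(fit$coef)
  }
  expect_gte(covered / total, 0.9)
})
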