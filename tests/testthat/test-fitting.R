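test_that("the Gaussian negative log-likelihood matches hand values", {
  sched <- toy_schedule(c(1, 2, -1, 0.5, 0, 1, -0.5, 2))
  p <- wi_params(0, beta = 0.5)
  traj <- wi_trajectory_recursive(p, sched$s_valence)
  on_traj <- toy_ratings(sched, traj[sched$is_rating_trial])
  # two residual-free ratings at sigma = 1: NLL = log(2*pi)
  expect_equal(negative_log_likelihood("WI", p, 1, on_traj, sched, "valence"),
               log(2 * pi), tolerance = 1e-12)
  off <- toy_ratings(sched, traj[sched$is_rating_trial] + c(1, -1))
  expect_equal(negative_log_likelihood("WI", p, 1, off, sched, "valence"),
               log(2 * pi) + 1, tolerance = 1e-12)
})

test_that("NLL equals a brute-force per-point density product", {
  set.seed(14)
  for (i in 1:10) {
    n <- 16
    sv <- rnorm(n)
    rel <- sample(c("relevant", "irrelevant"), n, replace = TRUE)
    sched <- toy_schedule(sv, relevance = rel)
    p <- ed_params(runif(1, -0.5, 0.5), wS_rel = runif(1), wS_irr = runif(1),
                   gamma_rel = runif(1), gamma_irr = runif(1))
    obs <- rnorm(n / 4)
    sig <- runif(1, 0.2, 2)
    r <- toy_ratings(sched, obs)
    grp <- ifelse(rel == "relevant", 1L, 2L)
    traj <- ref_ed(p$w0, c(p$wS_rel, p$wS_irr), c(p$gamma_rel, p$gamma_irr),
                   sv, grp)
    oracle <- -sum(log(dnorm(obs, traj[sched$is_rating_trial], sig)))
    expect_equal(negative_log_likelihood("ED", p, sig, r, sched, "valence"),
                 oracle, tolerance = 1e-10)
  }
})

test_that("aic follows 2k - 2 logL for plain values and fits", {
  expect_equal(aic(-10, k = 3), 26)
  expect_equal(aic(0, k = 4), 8)
  # a larger model with identical loglik pays exactly 2 per extra parameter
  expect_equal(aic(-5, k = 6) - aic(-5, k = 4), 4)
})

test_that("MLE recovers WI parameters from clean simulated data", {
  task <- shared_schedule[shared_schedule$block_type == "task" &
                            shared_schedule$participant_id == "P001", ]
  true_p <- list(valence = wi_params(0, beta_rel = 0.6, beta_irr = 0.6),
                 arousal = wi_params(0, beta_rel = 0.6, beta_irr = 0.6))
  r <- simulate_ratings(task, "WI", true_p, noise_sd = 0.05, seed = 5)
  fit <- fit_mle("WI", r, task, "valence", design = "task", seed = 6)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$beta_rel - 0.6), 0.05)
  expect_lt(abs(fit$params$beta_irr - 0.6), 0.05)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-9)
  # in-sample MLE dominates the generating parameters
  nll_true <- negative_log_likelihood("WI", true_p$valence, 0.05, r, task,
                                      "valence")
  expect_gte(fit$loglik, -nll_true - 1e-6)
})

test_that("beta = 0 data yield a constant fitted trajectory that beats truth in-sample", {
  ctrl <- shared_schedule[shared_schedule$block_type == "control" &
                            shared_schedule$participant_id == "P001", ]
  p0 <- list(valence = wi_params(0.4, beta = 0), arousal = wi_params(0.4, beta = 0))
  r <- simulate_ratings(ctrl, "WI", p0, noise_sd = 0.3, seed = 8)
  fit <- fit_mle("WI", r, ctrl, "valence", design = "control", seed = 2)
  expect_lt(fit$params$beta, 0.15)
  nll_true <- negative_log_likelihood("WI", p0$valence, 0.3, r, ctrl, "valence")
  expect_gte(fit$loglik, -nll_true - 1e-6)
})

test_that("parameter counts match the design: control 3/4, task 4/6", {
  pid <- "P001"
  s <- shared_schedule[shared_schedule$participant_id == pid, ]
  pars <- list(valence = wi_params(0, beta = 0.3, beta_rel = 0.35, beta_irr = 0.2),
               arousal = wi_params(0, beta = 0.3, beta_rel = 0.35, beta_irr = 0.2))
  r <- simulate_ratings(s, "WI", pars, noise_sd = 0.5, seed = 4)
  ctrl <- s[s$block_type == "control", ]
  task <- s[s$block_type == "task", ]
  expect_equal(fit_mle("WI", r, ctrl, design = "control", n_restarts = 2)$n_params, 3)
  expect_equal(fit_mle("ED", r, ctrl, design = "control", n_restarts = 2)$n_params, 4)
  expect_equal(fit_mle("WI", r, task, design = "task", n_restarts = 2)$n_params, 4)
  expect_equal(fit_mle("ED", r, task, design = "task", n_restarts = 2)$n_params, 6)
})

test_that("fits are reproducible and more restarts never hurt the likelihood", {
  ctrl <- shared_schedule[shared_schedule$block_type == "control" &
                            shared_schedule$participant_id == "P002", ]
  pars <- list(valence = wi_params(0.2, beta = 0.45),
               arousal = wi_params(0, beta = 0.2))
  r <- simulate_ratings(ctrl, "WI", pars, noise_sd = 0.4, seed = 11)
  f_a <- fit_mle("ED", r, ctrl, "valence", design = "control", seed = 31)
  f_b <- fit_mle("ED", r, ctrl, "valence", design = "control", seed = 31)
  expect_identical(f_a$theta, f_b$theta)
  f5 <- fit_mle("ED", r, ctrl, "valence", design = "control",
                n_restarts = 5, seed = 31)
  f10 <- fit_mle("ED", r, ctrl, "valence", design = "control",
                 n_restarts = 10, seed = 31)
  expect_gte(f10$loglik, f5$loglik - 1e-9)
})

test_that("misaligned ratings and short datasets are rejected", {
  sched <- toy_schedule(rnorm(16))
  r <- toy_ratings(sched, rnorm(4))
  expect_error(fit_mle("WI", r[-1, ], sched, design = "control"),
               "misaligned")
  expect_error(fit_mle("WI", r, sched, design = "control"), "at least 8")
})
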