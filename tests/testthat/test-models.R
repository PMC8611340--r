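test_that("ED trajectory reproduces hand-computed integration examples", {
  # even weighting (gamma = 1): cumulative sum of stimulus values
  expect_equal(ed_trajectory(ed_params(0, wS = 1, gamma = 1), c(0.2, 0.3, 0.5)),
               c(0.2, 0.5, 1.0))
  # gamma = 0: only the most recent stimulus counts (0^0 == 1)
  expect_equal(ed_trajectory(ed_params(0.1, wS = 2, gamma = 0), c(1, -1)),
               c(2.1, -1.9))
  expect_equal(ed_trajectory(ed_params(0, wS = 1, gamma = 0.5), c(1, 2)),
               c(1, 2.5))
})

test_that("ED trajectory matches a direct double-loop reference, split and not", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    s <- rnorm(n)
    w0 <- runif(1, -1, 1)
    wS <- runif(2, -2, 2)
    gam <- runif(2)
    expect_equal(ed_trajectory(ed_params(w0, wS = wS[1], gamma = gam[1]), s),
                 ref_ed(w0, wS[1], gam[1], s), tolerance = 1e-12)
    rel <- sample(c("relevant", "irrelevant"), n, replace = TRUE)
    grp <- ifelse(rel == "relevant", 1L, 2L)
    expect_equal(
      ed_trajectory(ed_params(w0, wS_rel = wS[1], wS_irr = wS[2],
                              gamma_rel = gam[1], gamma_irr = gam[2]), s, rel),
      ref_ed(w0, wS, gam, s, grp), tolerance = 1e-12)
  }
})

test_that("ED with gamma = 1 equals the cumulative-sum closed form", {
  set.seed(3)
  s <- rnorm(60)
  expect_equal(ed_trajectory(ed_params(0.4, wS = 0.7, gamma = 1), s),
               0.4 + 0.7 * cumsum(s), tolerance = 1e-12)
})

test_that("WI recursion reproduces its limiting behaviours", {
  expect_equal(wi_trajectory_recursive(wi_params(0, beta = 0.5), c(1, 1)),
               c(0.5, 0.75))
  # beta = 0: stimuli have no impact, affect frozen at the initial state
  expect_equal(wi_trajectory_recursive(wi_params(0.3, beta = 0), rnorm(10)),
               rep(0.3, 10))
  # beta = 1: affect depends only on the most recent stimulus
  s <- rnorm(10)
  expect_equal(wi_trajectory_recursive(wi_params(-2, beta = 1), s), s)
})

test_that("WI closed form: hand examples and equivalence with the recursion", {
  expect_equal(wi_trajectory_closed(wi_params(5, beta = 1), 0.3), 0.3)
  expect_equal(wi_trajectory_closed(wi_params(1, beta = 0.5), c(0, 0)),
               c(0.5, 0.25))
  set.seed(21)
  worst <- 0
  for (i in 1:300) {
    n <- sample(1:76, 1)
    p <- wi_params(runif(1, -2, 2), beta = runif(1))
    s <- rnorm(n)
    worst <- max(worst, max(abs(wi_trajectory_closed(p, s) -
                                  wi_trajectory_recursive(p, s))))
  }
  expect_lt(worst, 1e-10)
})

test_that("WI trajectories stay inside the convex hull of inputs", {
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, -3, 0); b <- runif(1, 0, 3)
    s <- runif(30, a, b)
    p <- wi_params(runif(1, a, b), beta = runif(1))
    tr <- wi_trajectory_recursive(p, s)
    expect_true(all(tr >= a - 1e-12 & tr <= b + 1e-12))
  }
})

test_that("relevance-split WI uses each stimulus' own update weight", {
  s <- c(1, 1, 1, 1)
  rel <- c("relevant", "irrelevant", "relevant", "irrelevant")
  p <- wi_params(0, beta_rel = 0.6, beta_irr = 0.1)
  expect_equal(wi_trajectory_recursive(p, s, rel),
               ref_wi(0, c(0.6, 0.1), s, c(1L, 2L, 1L, 2L)), tolerance = 1e-12)
  # equal split weights collapse to the single-parameter model
  p_eq <- wi_params(0.2, beta_rel = 0.4, beta_irr = 0.4)
  expect_equal(wi_trajectory_recursive(p_eq, s, rel),
               wi_trajectory_recursive(wi_params(0.2, beta = 0.4), s),
               tolerance = 1e-12)
})

test_that("parameter validation and argument mismatches are rejected", {
  expect_error(wi_params(0, beta = 1.2), "\\[0, 1\\]")
  expect_error(ed_params(0, wS = 1, gamma = -0.1), "\\[0, 1\\]")
  expect_error(ed_params(0, wS = 1), "gamma")
  p_split <- wi_params(0, beta_rel = 0.3, beta_irr = 0.2)
  expect_error(wi_trajectory_recursive(p_split, c(1, 2)), "relevance")
  expect_error(wi_trajectory_recursive(wi_params(0, beta = 0.3), c(1, 2),
                                       c("relevant", "irrelevant")), "split")
  expect_error(wi_trajectory_closed(p_split, c(1, 2)), "single update weight")
  expect_error(ed_trajectory(ed_params(0, wS_rel = 1, wS_irr = 1,
                                       gamma_rel = 0.5, gamma_irr = 0.5),
                             c(1, 2, 3), c("relevant", "irrelevant")),
               "length mismatch")
})
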