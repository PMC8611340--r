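wi_shared <- list(
  valence = wi_params(0, beta = 0.3, beta_rel = 0.32, beta_irr = 0.25),
  arousal = wi_params(0, beta = 0.14, beta_rel = 0.15, beta_irr = 0.12)
)

test_that("simulated ratings converge to the noiseless model trajectory", {
  r <- simulate_ratings(shared_schedule, "WI", wi_shared, noise_sd = 1e-9,
                        seed = 3)
  expect_equal(nrow(r), 2 * 95)
  # recompute the latent trajectory independently, block by block
  for (pid in unique(shared_schedule$participant_id)) {
    s <- shared_schedule[shared_schedule$participant_id == pid, ]
    for (b in unique(s$block_index)) {
      blk <- s[s$block_index == b, ]
      blk <- blk[order(blk$trial_index), ]
      expected <- if (blk$block_type[1] == "task")
        wi_trajectory_recursive(wi_shared$valence, blk$s_valence, blk$relevance)
      else
        wi_trajectory_recursive(wi_params(0, beta = 0.3), blk$s_valence)
      got <- r$valence_std[r$participant_id == pid & r$block_index == b]
      expect_equal(got, expected[blk$is_rating_trial], tolerance = 1e-6)
    }
  }
})

test_that("WI limiting cases propagate into the emitted ratings", {
  frozen <- list(valence = wi_params(0.3, beta = 0, beta_rel = 0, beta_irr = 0),
                 arousal = wi_params(0.3, beta = 0, beta_rel = 0, beta_irr = 0))
  r0 <- simulate_ratings(shared_schedule, "WI", frozen, noise_sd = 1e-9, seed = 1)
  expect_equal(r0$valence_std, rep(0.3, nrow(r0)), tolerance = 1e-6)
  track <- list(valence = wi_params(0, beta = 1, beta_rel = 1, beta_irr = 1),
                arousal = wi_params(0, beta = 1, beta_rel = 1, beta_irr = 1))
  r1 <- simulate_ratings(shared_schedule, "WI", track, noise_sd = 1e-9, seed = 1)
  # each rating equals the standardized valence of the image on the rating trial
  m <- match(paste(r1$participant_id, r1$block_index, r1$trial_index),
             paste(shared_schedule$participant_id, shared_schedule$block_index,
                   shared_schedule$trial_index))
  expect_equal(r1$valence_std, shared_schedule$s_valence[m], tolerance = 1e-6)
})

test_that("rating simulation is deterministic given the seed", {
  a <- simulate_ratings(shared_schedule, "WI", wi_shared, noise_sd = 0.5, seed = 9)
  b <- simulate_ratings(shared_schedule, "WI", wi_shared, noise_sd = 0.5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_ratings(shared_schedule, "WI", wi_shared, noise_sd = 0.5, seed = 10)))
})

test_that("standardize_ratings produces participant z-scores and flags zero variance", {
  sched <- toy_schedule(rep(0, 12))
  r <- toy_ratings(sched, c(1, 2, 3))
  r$valence_raw <- c(1, 2, 3); r$arousal_raw <- c(10, 10, 10)
  out <- standardize_ratings(r)
  expect_equal(out$valence_std, c(-1, 0, 1))
  expect_true(all(is.na(out$arousal_std)))
  fl <- attr(out, "flagged")
  expect_equal(fl$dimension, "arousal")
  # any valid output has mean 0 and unit variance per participant
  expect_lt(abs(mean(out$valence_std)), 1e-9)
  expect_lt(abs(var(out$valence_std) - 1), 1e-9)
})

test_that("slider-movement exclusions follow the 80% rule", {
  mk <- function(pid, v_raw, a_raw, block_type) data.frame(
    participant_id = pid, block_index = rep(1:5, each = 19),
    block_type = block_type, rating_index = rep(1:19, 5),
    trial_index = rep(seq(4, 76, 4), 5),
    valence_std = 0, arousal_std = 0,
    valence_raw = v_raw, arousal_raw = a_raw, stringsAsFactors = FALSE)
  bt <- rep(c("control", rep("task", 4)), each = 19)
  # A: 77 of 95 unmoved valence ratings -> excluded everywhere (77/95 > 0.8)
  a <- mk("A", c(rep(50, 77), 60 + 1:18), runif(95, 0, 100), bt)
  # B: slider always moved -> retained
  b <- mk("B", 40 + 1:95, 30 + 1:95, bt)
  # C: all 19 control-block arousal ratings unmoved, task arousal moved
  c_ <- mk("C", 40 + 1:95, c(rep(50, 19), 30 + 1:76), bt)
  res <- apply_exclusions(rbind(a, b, c_))
  rep_ <- res$report
  expect_true(rep_$excluded_global[rep_$participant_id == "A"])
  expect_false(rep_$excluded_global[rep_$participant_id == "B"])
  expect_false(rep_$excluded_global[rep_$participant_id == "C"])
  expect_true(rep_$excluded_control_arousal[rep_$participant_id == "C"])
  expect_false(rep_$excluded_control_arousal[rep_$participant_id == "B"])
  expect_setequal(unique(res$ratings$participant_id), c("B", "C"))
  # exactly at the threshold (76/95) is retained
  d <- mk("D", c(rep(50, 76), 60 + 1:19), 30 + 1:95, bt)
  expect_false(apply_exclusions(d)$report$excluded_global)
})
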