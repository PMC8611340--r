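# Reference implementations and tiny fixtures, independent of the package's
# computational paths (pure-R double loops vs the compiled recursions).

# direct double-loop ED trajectory; wS/gam are per-group vectors indexed by
# each stimulus' own relevance group
ref_ed <- function(w0, wS, gam, s, grp = rep(1L, length(s))) {
  n <- length(s)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- w0
    for (j in seq_len(t)) {
      g <- grp[j]
      acc <- acc + wS[g] * gam[g]^(t - j) * s[j]
    }
    out[t] <- acc
  }
  out
}

ref_wi <- function(x0, beta, s, grp = rep(1L, length(s))) {
  v <- x0
  out <- numeric(length(s))
  for (t in seq_along(s)) {
    v <- v + beta[grp[t]] * (s[t] - v)
    out[t] <- v
  }
  out
}

# hand-rolled one-participant, one-block schedule; length(S_v) must be a
# multiple of 4
toy_schedule <- function(S_v, S_a = S_v, relevance = NULL,
                         pid = "T01", block_index = 1L) {
  n <- length(S_v)
  stopifnot(n %% 4L == 0L)
  block_type <- if (is.null(relevance)) "control" else "task"
  if (is.null(relevance)) relevance <- rep("not_applicable", n)
  data.frame(
    participant_id = pid, block_index = block_index, block_type = block_type,
    trial_index = seq_len(n),
    window = (seq_len(n) - 1L) %/% 4L + 1L,
    position = (seq_len(n) - 1L) %% 4L + 1L,
    stimulus_id = sprintf("toy%03d", seq_len(n)),
    category = ifelse(S_v >= 0, "pleasant", "unpleasant"),
    relevance = relevance,
    target = "none",
    is_rating_trial = seq_len(n) %% 4L == 0L,
    s_valence = S_v, s_arousal = S_a,
    stringsAsFactors = FALSE
  )
}

toy_ratings <- function(sched, values_v, values_a = values_v) {
  idx <- which(sched$is_rating_trial)
  stopifnot(length(values_v) == length(idx))
  data.frame(
    participant_id = sched$participant_id[idx],
    block_index = sched$block_index[idx],
    block_type = sched$block_type[idx],
    rating_index = seq_along(idx),
    trial_index = sched$trial_index[idx],
    valence_std = values_v, arousal_std = values_a,
    valence_raw = pmin(100, pmax(0, 50 + 20 * values_v)),
    arousal_raw = pmin(100, pmax(0, 50 + 20 * values_a)),
    stringsAsFactors = FALSE
  )
}

# shared full-size fixtures, built once per test run
shared_catalog <- generate_catalog(seed = 42)
shared_schedule <- build_schedule(2, shared_catalog, seed = 42)
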