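# Design constants of the emulated experiment: 4 task blocks and 1 control
# block of 76 trials each; an affect rating is collected after every 4th
# image, i.e. 19 ratings per block and 4 temporal positions per rating
# window (position 4 = the image immediately before the rating).
.TRIALS_PER_BLOCK <- 76L
.WINDOWS_PER_BLOCK <- 19L
.POSITIONS <- 4L
.N_TASK_BLOCKS <- 4L
.N_BLOCKS <- 5L
.PER_CAT_PER_BLOCK <- 38L

.sample_from <- function(x, n) x[sample.int(length(x), n)]

# Random 4x4 matrix with entries in {9, 10}, each row and column summing to
# 38 (two 10s per row and per column): superpose two disjoint random
# permutation matrices on a base of 9s.
.balanced_quota_matrix <- function() {
  repeat {
    p1 <- sample.int(4L)
    p2 <- sample.int(4L)
    if (all(p1 != p2)) break
  }
  M <- matrix(9L, 4L, 4L)
  for (i in 1:4) {
    M[i, p1[i]] <- 10L
    M[i, p2[i]] <- 10L
  }
  M
}

# Per-position overlap counts k_p = #(pleasant & relevant) for one task
# block, constrained to its feasible box and summing to 19 so that every
# category x relevance cell of the block holds exactly 19 trials.
.overlap_quota <- function(n_rel, n_p, total = 19L) {
  lo <- pmax(0L, n_rel + n_p - .WINDOWS_PER_BLOCK)
  hi <- pmin(n_rel, n_p)
  k <- as.integer(pmin(pmax(round(n_rel * n_p / .WINDOWS_PER_BLOCK), lo), hi))
  while (sum(k) != total) {
    if (sum(k) < total) {
      idx <- which(k < hi)
      i <- if (length(idx) > 1L) .sample_from(idx, 1L) else idx
      k[i] <- k[i] + 1L
    } else {
      idx <- which(k > lo)
      i <- if (length(idx) > 1L) .sample_from(idx, 1L) else idx
      k[i] <- k[i] - 1L
    }
  }
  k
}

# One task block: 19 windows x 4 positions with per-position relevance and
# valence-category quotas and their overlap fixed in advance.
.build_task_block <- function(n_rel_row, n_p_row, k_row) {
  parts <- vector("list", .POSITIONS)
  for (p in seq_len(.POSITIONS)) {
    w <- seq_len(.WINDOWS_PER_BLOCK)
    rel_w <- .sample_from(w, n_rel_row[p])
    irr_w <- setdiff(w, rel_w)
    pl <- c(if (k_row[p] > 0L) .sample_from(rel_w, k_row[p]),
            if (n_p_row[p] - k_row[p] > 0L) .sample_from(irr_w, n_p_row[p] - k_row[p]))
    parts[[p]] <- data.frame(
      window = w, position = p,
      relevance = ifelse(w %in% rel_w, "relevant", "irrelevant"),
      category = ifelse(w %in% pl, "pleasant", "unpleasant"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, parts)
  out$trial_index <- (out$window - 1L) * .POSITIONS + out$position
  out[order(out$trial_index), , drop = FALSE]
}

.build_control_block <- function() {
  n_p_row <- sample(c(10L, 10L, 9L, 9L)) # 38 pleasant per block; 19/position is odd
  parts <- vector("list", .POSITIONS)
  for (p in seq_len(.POSITIONS)) {
    w <- seq_len(.WINDOWS_PER_BLOCK)
    pl <- .sample_from(w, n_p_row[p])
    parts[[p]] <- data.frame(
      window = w, position = p,
      relevance = "not_applicable",
      category = ifelse(w %in% pl, "pleasant", "unpleasant"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, parts)
  out$trial_index <- (out$window - 1L) * .POSITIONS + out$position
  out[order(out$trial_index), , drop = FALSE]
}

# Assign each stimulus of one category to the blocks that will show it. Every
# block needs `per_block` distinct stimuli; a stimulus may appear in at most
# two blocks and never twice within a block.
.assign_block_stimuli <- function(ids, n_blocks, per_block, max_attempts = 1000L) {
  n <- length(ids)
  total <- n_blocks * per_block
  if (per_block > n || total > 2L * n)
    stop("catalog too small: need ", per_block, " distinct stimuli per block and ",
         total, " presentations from ", n, " stimuli (max two uses each)")
  n_twice <- max(0L, total - n)
  for (att in seq_len(max_attempts)) {
    twice <- .sample_from(ids, n_twice)
    once <- .sample_from(setdiff(ids, twice), total - 2L * n_twice)
    labels <- sample(rep.int(seq_len(n_blocks), per_block))
    res_stim <- character(total)
    res_block <- integer(total)
    pos <- 1L
    ok <- TRUE
    for (s in twice) {
      if (labels[pos + 1L] == labels[pos]) {
        later <- if (pos + 2L <= total) which(labels[(pos + 2L):total] != labels[pos]) else integer()
        if (!length(later)) { ok <- FALSE; break }
        j <- pos + 1L + later[1L]
        tmp <- labels[pos + 1L]; labels[pos + 1L] <- labels[j]; labels[j] <- tmp
      }
      res_stim[pos] <- s;      res_block[pos] <- labels[pos]
      res_stim[pos + 1L] <- s; res_block[pos + 1L] <- labels[pos + 1L]
      pos <- pos + 2L
    }
    if (!ok) next
    for (s in once) {
      res_stim[pos] <- s
      res_block[pos] <- labels[pos]
      pos <- pos + 1L
    }
    return(data.frame(stimulus_id = res_stim, block = res_block,
                      stringsAsFactors = FALSE))
  }
  stop("could not place stimuli into blocks without within-block repeats after ",
       max_attempts, " attempts")
}

.build_participant_schedule <- function(pid, catalog, control_first) {
  # block composition: relevance and valence quota matrices over the 4 task
  # blocks x 4 temporal positions, doubly balanced (38 per row and column)
  R <- .balanced_quota_matrix()
  P <- .balanced_quota_matrix()
  task_blocks <- vector("list", .N_TASK_BLOCKS)
  for (b in seq_len(.N_TASK_BLOCKS)) {
    k <- .overlap_quota(R[b, ], P[b, ])
    blk <- .build_task_block(R[b, ], P[b, ], k)
    # targets: each of the four category x relevance cells (19 trials) gets
    # 5 circle, 5 rectangle and 9 no-target trials -> 40 targets per block,
    # 160 over the task portion (52.6% of 304 images)
    blk$target <- "none"
    for (cat in c("pleasant", "unpleasant")) {
      for (rel in c("relevant", "irrelevant")) {
        cell <- which(blk$category == cat & blk$relevance == rel)
        tgt <- .sample_from(cell, 10L)
        blk$target[tgt[1:5]] <- "circle"
        blk$target[tgt[6:10]] <- "rectangle"
      }
    }
    blk$block_type <- "task"
    task_blocks[[b]] <- blk
  }
  ctrl <- .build_control_block()
  ctrl$target <- "none"
  ctrl$block_type <- "control"

  blocks <- if (control_first) c(list(ctrl), task_blocks) else c(task_blocks, list(ctrl))
  for (b in seq_len(.N_BLOCKS)) blocks[[b]]$block_index <- b
  sched <- do.call(rbind, blocks)

  # stimulus placement: per category, pick which blocks show each stimulus
  # (at most twice overall, never twice in a block), then shuffle within block
  sched$stimulus_id <- NA_character_
  for (cat in c("pleasant", "unpleasant")) {
    ids <- catalog$stimulus_id[catalog$category == cat]
    placement <- .assign_block_stimuli(ids, .N_BLOCKS, .PER_CAT_PER_BLOCK)
    for (b in seq_len(.N_BLOCKS)) {
      slots <- which(sched$block_index == b & sched$category == cat)
      pool <- placement$stimulus_id[placement$block == b]
      sched$stimulus_id[slots] <- sample(pool)
    }
  }
  sched$participant_id <- pid
  sched
}

#' Build balanced per-participant trial schedules
#'
#' Generates, for each participant, 4 task blocks and 1 control block of 76
#' trials (an affect rating after every 4th image; 19 ratings per block, 95
#' in total). Within the task portion the generator enforces, exactly and by
#' construction: 160 target trials (40 per block: 20 circles, 20 rectangles);
#' 152 relevant and 152 irrelevant images with 38 of each at every temporal
#' position between consecutive ratings; 38 pleasant and 38 unpleasant images
#' per block, 38 of each per temporal position, 76 of each per relevance
#' level, and 40/40/72 of each per target condition (circle/rectangle/none).
#' Stimuli never repeat within a block and are shown at most twice overall.
#'
#' @param n_participants Number of participants to schedule.
#' @param catalog A [generate_catalog()] catalog (needs at least 95 stimuli
#'   per category).
#' @param control_position Where the passive-viewing control block sits:
#'   `"alternating"` (first for odd participants, last for even, balancing
#'   the sample), `"first"`, or `"last"`.
#' @param seed Integer seed.
#' @param audit If `TRUE` (default) run [audit_schedule()] after generation
#'   and fail on any violated balance invariant.
#' @return A `data.frame` of class `affect_schedule`, one row per trial, with
#'   columns `participant_id`, `block_index`, `block_type`, `trial_index`,
#'   `window`, `position`, `stimulus_id`, `category`, `relevance`, `target`,
#'   `is_rating_trial`, and the standardized normative stimulus values
#'   `s_valence`, `s_arousal`.
#' @examples
#' cat200 <- generate_catalog(seed = 1)
#' sch <- build_schedule(1, cat200, seed = 7)
#' nrow(sch)                 # 380 trials
#' sum(sch$is_rating_trial)  # 95 ratings
#' @export
build_schedule <- function(n_participants, catalog,
                           control_position = c("alternating", "first", "last"),
                           seed = 1, audit = TRUE) {
  control_position <- match.arg(control_position)
  stopifnot(inherits(catalog, "data.frame"), n_participants >= 1)
  set.seed(seed)
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    first <- switch(control_position,
                    alternating = (i %% 2L == 1L),
                    first = TRUE,
                    last = FALSE)
    out[[i]] <- .build_participant_schedule(sprintf("P%03d", i), catalog, first)
  }
  sched <- do.call(rbind, out)
  sched$is_rating_trial <- sched$trial_index %% 4L == 0L
  m <- match(sched$stimulus_id, catalog$stimulus_id)
  sched$s_valence <- catalog$valence_std[m]
  sched$s_arousal <- catalog$arousal_std[m]
  sched <- sched[, c("participant_id", "block_index", "block_type",
                     "trial_index", "window", "position", "stimulus_id",
                     "category", "relevance", "target", "is_rating_trial",
                     "s_valence", "s_arousal")]
  rownames(sched) <- NULL
  class(sched) <- c("affect_schedule", "data.frame")
  attr(sched, "design") <- list(
    n_task_blocks = .N_TASK_BLOCKS, trials_per_block = .TRIALS_PER_BLOCK,
    ratings_per_block = .WINDOWS_PER_BLOCK, control_position = control_position
  )
  if (audit) {
    problems <- audit_schedule(sched)
    if (length(problems))
      stop("schedule audit failed:\n", paste(problems, collapse = "\n"))
  }
  sched
}

#' Independently audit the balance invariants of a schedule
#'
#' Recounts every design constraint of [build_schedule()] directly from the
#' trial table (it shares no bookkeeping with the generator): block sizes and
#' rating cadence, target counts, relevance balance overall and per temporal
#' position, valence-category balance per block / position / relevance level /
#' target condition, and stimulus repetition rules.
#'
#' @param schedule An `affect_schedule` data frame.
#' @return A character vector of violations; empty when the schedule is fully
#'   balanced.
#' @export
audit_schedule <- function(schedule) {
  problems <- character()
  note <- function(...) problems[[length(problems) + 1L]] <<- paste0(...)
  for (pid in unique(schedule$participant_id)) {
    s <- schedule[schedule$participant_id == pid, ]
    tag <- paste0("[", pid, "] ")
    task <- s[s$block_type == "task", ]
    ctrl <- s[s$block_type == "control", ]
    if (nrow(task) != 304L) note(tag, "task portion has ", nrow(task), " trials, expected 304")
    if (nrow(ctrl) != 76L) note(tag, "control block has ", nrow(ctrl), " trials, expected 76")
    if (!identical(sort(unique(s$block_index)), 1:5))
      note(tag, "block indices are not 1..5")
    for (b in unique(s$block_index)) {
      blk <- s[s$block_index == b, ]
      if (!identical(sort(blk$trial_index), 1:76))
        note(tag, "block ", b, " trial indices are not 1..76")
      if (sum(blk$is_rating_trial) != 19L)
        note(tag, "block ", b, " has ", sum(blk$is_rating_trial), " rating trials, expected 19")
      if (!all(blk$is_rating_trial == (blk$trial_index %% 4L == 0L)))
        note(tag, "block ", b, " rating flags disagree with every-4th-trial cadence")
      if (sum(blk$category == "pleasant") != 38L)
        note(tag, "block ", b, " has ", sum(blk$category == "pleasant"), " pleasant trials, expected 38")
      if (anyDuplicated(blk$stimulus_id))
        note(tag, "block ", b, " repeats a stimulus")
    }
    if (any(table(s$stimulus_id) > 2L))
      note(tag, "a stimulus is shown more than twice")
    if (any(ctrl$relevance != "not_applicable") || any(ctrl$target != "none"))
      note(tag, "control block carries relevance or target labels")
    # task-portion balance
    if (sum(task$target != "none") != 160L)
      note(tag, "task portion has ", sum(task$target != "none"), " target trials, expected 160")
    for (tg in c("circle", "rectangle")) {
      if (sum(task$target == tg) != 80L)
        note(tag, "task portion has ", sum(task$target == tg), " ", tg, " targets, expected 80")
    }
    if (sum(task$relevance == "relevant") != 152L)
      note(tag, "task portion has ", sum(task$relevance == "relevant"), " relevant trials, expected 152")
    for (p in 1:4) {
      tp <- task[task$position == p, ]
      if (sum(tp$relevance == "relevant") != 38L)
        note(tag, "position ", p, ": ", sum(tp$relevance == "relevant"), " relevant trials, expected 38")
      if (sum(tp$category == "pleasant") != 38L)
        note(tag, "position ", p, ": ", sum(tp$category == "pleasant"), " pleasant trials, expected 38")
    }
    for (rel in c("relevant", "irrelevant")) {
      tr <- task[task$relevance == rel, ]
      if (sum(tr$category == "pleasant") != 76L)
        note(tag, rel, " trials have ", sum(tr$category == "pleasant"), " pleasant images, expected 76")
    }
    tgt_quota <- c(circle = 40L, rectangle = 40L, none = 72L)
    for (tg in names(tgt_quota)) {
      tt <- task[task$target == tg, ]
      if (sum(tt$category == "pleasant") != tgt_quota[[tg]])
        note(tag, tg, " trials have ", sum(tt$category == "pleasant"),
             " pleasant images, expected ", tgt_quota[[tg]])
    }
  }
  problems
}
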