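# Resolve per-(participant, dimension) model parameters from the flexible
# `params` argument of simulate_ratings(): either one list(valence=, arousal=)
# recycled over participants, or a named list of such lists keyed by
# participant id.
.params_for <- function(params, pid) {
  if (all(c("valence", "arousal") %in% names(params))) return(params)
  if (!is.null(params[[pid]])) return(params[[pid]])
  stop("no model parameters supplied for participant ", pid)
}

.noise_for <- function(noise_sd, pid, dimension) {
  if (is.data.frame(noise_sd)) {
    row <- noise_sd[noise_sd$participant_id == pid, , drop = FALSE]
    if (nrow(row) != 1L) stop("no noise sd supplied for participant ", pid)
    return(row[[dimension]])
  }
  if (length(noise_sd) == 2L && !is.null(names(noise_sd))) return(noise_sd[[dimension]])
  as.numeric(noise_sd)
}

.block_trajectory <- function(model, params, stimuli, relevance, block_type) {
  rel <- if (block_type == "task" && .has_split(params)) relevance else NULL
  if (block_type == "control" && !.has_single(params))
    stop("control-block simulation needs non-split model parameters")
  if (model == "WI") wi_trajectory_recursive(params, stimuli, rel)
  else ed_trajectory(params, stimuli, rel)
}

#' Simulate affect ratings from a generative model
#'
#' Runs the chosen model's latent trajectory over every block of the schedule
#' (standardized normative stimulus values as input; trajectories restart at
#' each block boundary) and emits, at every rating trial, the trajectory
#' value plus Gaussian observation noise. The latent trajectory is never
#' conditioned on emitted ratings. Relevance-split parameters are applied in
#' task blocks; control blocks use the single (non-split) parameters.
#'
#' Simulated values live on the standardized rating scale and are stored in
#' `valence_std` / `arousal_std`. For interface parity with observed data, a
#' synthetic slider rendering `raw = 50 + 20 * value` clipped to \[0, 100\]
#' is stored in the `_raw` columns; model code never reads it.
#'
#' @param schedule An [build_schedule()] schedule (or a block subset of one).
#' @param model `"WI"` or `"ED"`.
#' @param params Either a `list(valence = , arousal = )` of parameter objects
#'   shared by all participants, or a named list per participant id of such
#'   lists.
#' @param noise_sd Observation noise sd: a scalar, a named length-2 vector
#'   `c(valence = , arousal = )`, or a data frame with columns
#'   `participant_id`, `valence`, `arousal`.
#' @param seed Integer seed.
#' @return A `data.frame` of class `ratings_table`, one row per rating, with
#'   columns `participant_id`, `block_index`, `block_type`, `rating_index`,
#'   `trial_index`, `valence_std`, `arousal_std`, `valence_raw`,
#'   `arousal_raw`.
#' @examples
#' cat200 <- generate_catalog(seed = 1)
#' sch <- build_schedule(1, cat200, seed = 1)
#' pars <- list(valence = wi_params(0, beta_rel = 0.32, beta_irr = 0.25),
#'              arousal = wi_params(0, beta_rel = 0.15, beta_irr = 0.12))
#' # give the control block a single beta as well
#' pars$valence$beta <- 0.3; pars$arousal$beta <- 0.14
#' r <- simulate_ratings(sch, "WI", pars, noise_sd = 0.5, seed = 2)
#' @export
simulate_ratings <- function(schedule, model = c("WI", "ED"), params,
                             noise_sd, seed = 1) {
  model <- match.arg(model)
  if (any(unlist(lapply(list(noise_sd), function(x)
    if (is.data.frame(x)) c(x$valence, x$arousal) <= 0 else x <= 0))))
    stop("noise_sd must be positive")
  set.seed(seed)
  rows <- list()
  for (pid in unique(schedule$participant_id)) {
    sp <- .params_for(params, pid)
    s_part <- schedule[schedule$participant_id == pid, ]
    for (dim in c("valence", "arousal")) {
      scol <- if (dim == "valence") "s_valence" else "s_arousal"
      sdd <- .noise_for(noise_sd, pid, dim)
      vals <- list()
      for (b in sort(unique(s_part$block_index))) {
        blk <- s_part[s_part$block_index == b, ]
        blk <- blk[order(blk$trial_index), ]
        traj <- .block_trajectory(model, sp[[dim]], blk[[scol]],
                                  blk$relevance, blk$block_type[1L])
        idx <- which(blk$is_rating_trial)
        vals[[as.character(b)]] <- data.frame(
          participant_id = pid, block_index = b,
          block_type = blk$block_type[1L],
          rating_index = seq_along(idx),
          trial_index = blk$trial_index[idx],
          value = traj[idx] + rnorm(length(idx), 0, sdd),
          stringsAsFactors = FALSE
        )
      }
      d <- do.call(rbind, vals)
      names(d)[names(d) == "value"] <- paste0(dim, "_std")
      rows[[paste(pid, dim)]] <- d
    }
  }
  key <- c("participant_id", "block_index", "block_type", "rating_index", "trial_index")
  vtab <- do.call(rbind, unname(rows[grepl(" valence$", names(rows))]))
  atab <- do.call(rbind, unname(rows[grepl(" arousal$", names(rows))]))
  out <- merge(vtab, atab, by = key, sort = FALSE)
  out <- out[order(out$participant_id, out$block_index, out$rating_index), ]
  out$valence_raw <- pmin(100, pmax(0, 50 + 20 * out$valence_std))
  out$arousal_raw <- pmin(100, pmax(0, 50 + 20 * out$arousal_std))
  rownames(out) <- NULL
  class(out) <- c("ratings_table", "data.frame")
  out
}

#' Standardize observed ratings within participant
#'
#' Replaces the `_std` columns with per-participant z-scores of the raw
#' slider values, pooling all of a participant's ratings in a dimension
#' across blocks (sample sd). A participant-dimension with zero variance is
#' flagged for exclusion (its z-scores are set to `NA`) instead of dividing
#' by zero.
#'
#' @param ratings A `ratings_table` with `valence_raw` / `arousal_raw`.
#' @return The ratings table with recomputed `valence_std` / `arousal_std`;
#'   flagged participant-dimensions are recorded in the `"flagged"`
#'   attribute (a data frame with columns `participant_id`, `dimension`).
#' @export
standardize_ratings <- function(ratings) {
  flagged <- list()
  for (dim in c("valence", "arousal")) {
    raw <- paste0(dim, "_raw")
    std <- paste0(dim, "_std")
    for (pid in unique(ratings$participant_id)) {
      idx <- ratings$participant_id == pid
      x <- ratings[[raw]][idx]
      if (length(unique(x)) < 2L || sd(x) == 0) {
        ratings[[std]][idx] <- NA_real_
        flagged[[paste(pid, dim)]] <- data.frame(
          participant_id = pid, dimension = dim, stringsAsFactors = FALSE)
      } else {
        ratings[[std]][idx] <- (x - mean(x)) / sd(x)
      }
    }
  }
  attr(ratings, "flagged") <- if (length(flagged)) do.call(rbind, unname(flagged))
    else data.frame(participant_id = character(), dimension = character())
  ratings
}

#' Apply slider-movement exclusion rules
#'
#' Participants who left the slider at its default position on more than
#' `no_move_threshold` of their ratings on either scale are excluded from all
#' analyses. Participants whose control-block arousal ratings are all
#' unmoved are retained but flagged for exclusion from control-block arousal
#' fits only.
#'
#' @param ratings A `ratings_table` with raw slider values.
#' @param no_move_threshold Fraction of unmoved responses beyond which a
#'   participant is dropped (strict inequality; the default 0.8 excludes
#'   anyone with more than 76 of 95 unmoved ratings).
#' @param unmoved_value Slider default position (50 on the 0-100 scale).
#' @return A list with `ratings` (the retained rows) and `report`, a data
#'   frame with per-participant unmoved counts and the flags
#'   `excluded_global` and `excluded_control_arousal`.
#' @export
apply_exclusions <- function(ratings, no_move_threshold = 0.8,
                             unmoved_value = 50) {
  pids <- unique(ratings$participant_id)
  rep_rows <- lapply(pids, function(pid) {
    r <- ratings[ratings$participant_id == pid, ]
    n <- nrow(r)
    nu_v <- sum(r$valence_raw == unmoved_value)
    nu_a <- sum(r$arousal_raw == unmoved_value)
    ctrl_a <- r$arousal_raw[r$block_type == "control"]
    data.frame(
      participant_id = pid, n_ratings = n,
      n_unmoved_valence = nu_v, n_unmoved_arousal = nu_a,
      excluded_global = (nu_v / n > no_move_threshold) ||
        (nu_a / n > no_move_threshold),
      excluded_control_arousal = length(ctrl_a) > 0 &&
        all(ctrl_a == unmoved_value),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rep_rows)
  # a globally excluded participant needs no separate control-arousal flag
  report$excluded_control_arousal[report$excluded_global] <- FALSE
  keep <- report$participant_id[!report$excluded_global]
  out <- ratings[ratings$participant_id %in% keep, ]
  rownames(out) <- NULL
  class(out) <- class(ratings)
  list(ratings = out, report = report)
}
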