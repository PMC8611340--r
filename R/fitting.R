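#' Default box bounds for maximum-likelihood fitting
#'
#' Generous bounds for models fitted to standardized ratings: update weights
#' and forgetting factors are probability-like and live in `[0, 1]`; the ED
#' constant and WI initial state in `[-3, 3]`; stimulus weights in `[-5, 5]`;
#' the observation noise sd in `[1e-3, 5]`.
#'
#' @return Named list of `c(lower, upper)` pairs for `beta`, `gamma`, `w0`,
#'   `wS`, `x0` and `sigma`.
#' @export
default_bounds <- function() {
  list(beta = c(0, 1), gamma = c(0, 1), w0 = c(-3, 3),
       wS = c(-5, 5), x0 = c(-3, 3), sigma = c(1e-3, 5))
}

# Parameter vector layout per (model, design). Control blocks use single
# parameters; task blocks split stimulus parameters by relevance.
#   WI control: x0, beta, sigma                      (k = 3)
#   WI task:    x0, beta_rel, beta_irr, sigma        (k = 4)
#   ED control: w0, wS, gamma, sigma                 (k = 4)
#   ED task:    w0, wS_rel, wS_irr, gamma_rel, gamma_irr, sigma (k = 6)
.param_layout <- function(model, design, bounds) {
  base <- function(nm) bounds[[sub("_(rel|irr)$", "", nm)]]
  names <- if (model == "WI") {
    if (design == "control") c("x0", "beta", "sigma")
    else c("x0", "beta_rel", "beta_irr", "sigma")
  } else {
    if (design == "control") c("w0", "wS", "gamma", "sigma")
    else c("w0", "wS_rel", "wS_irr", "gamma_rel", "gamma_irr", "sigma")
  }
  list(names = names,
       lower = vapply(names, function(nm) base(nm)[1], numeric(1)),
       upper = vapply(names, function(nm) base(nm)[2], numeric(1)))
}

.theta_to_params <- function(model, design, theta) {
  if (model == "WI") {
    if (design == "control") wi_params(x0 = theta[["x0"]], beta = theta[["beta"]])
    else wi_params(x0 = theta[["x0"]], beta_rel = theta[["beta_rel"]],
                   beta_irr = theta[["beta_irr"]])
  } else {
    if (design == "control") ed_params(w0 = theta[["w0"]], wS = theta[["wS"]],
                                       gamma = theta[["gamma"]])
    else ed_params(w0 = theta[["w0"]], wS_rel = theta[["wS_rel"]],
                   wS_irr = theta[["wS_irr"]], gamma_rel = theta[["gamma_rel"]],
                   gamma_irr = theta[["gamma_irr"]])
  }
}

# Precompute per-block stimulus vectors, relevance groups, rating positions
# and aligned observations for one participant and dimension.
.fit_blocks <- function(ratings, schedule, dimension) {
  pid <- unique(schedule$participant_id)
  if (length(pid) != 1L)
    stop("fitting operates on a single participant's schedule")
  r <- ratings[ratings$participant_id == pid, ]
  scol <- if (dimension == "valence") "s_valence" else "s_arousal"
  ocol <- paste0(dimension, "_std")
  blocks <- list()
  for (b in sort(unique(schedule$block_index))) {
    blk <- schedule[schedule$block_index == b, ]
    blk <- blk[order(blk$trial_index), ]
    rb <- r[r$block_index == b, ]
    rb <- rb[order(rb$rating_index), ]
    idx <- which(blk$is_rating_trial)
    if (nrow(rb) != length(idx))
      stop("ratings and schedule are misaligned in block ", b, " for ", pid,
           ": ", nrow(rb), " ratings vs ", length(idx), " rating trials")
    is_task <- blk$block_type[1L] == "task"
    blocks[[as.character(b)]] <- list(
      s = as.numeric(blk[[scol]]),
      grp_split = if (is_task) .relevance_groups(blk$relevance, nrow(blk)) else integer(nrow(blk)),
      is_task = is_task,
      rating_pos = idx,
      obs = as.numeric(rb[[ocol]])
    )
  }
  blocks
}

.blocks_nll <- function(model, design, theta, blocks) {
  nll <- 0
  for (blk in blocks) {
    if (model == "WI") {
      if (design == "task") {
        traj <- wi_filter_cpp(blk$s, blk$grp_split, theta[["x0"]],
                              c(theta[["beta_rel"]], theta[["beta_irr"]]))
      } else {
        traj <- wi_filter_cpp(blk$s, integer(length(blk$s)), theta[["x0"]],
                              theta[["beta"]])
      }
    } else {
      if (design == "task") {
        traj <- ed_filter_cpp(blk$s, blk$grp_split, theta[["w0"]],
                              c(theta[["wS_rel"]], theta[["wS_irr"]]),
                              c(theta[["gamma_rel"]], theta[["gamma_irr"]]))
      } else {
        traj <- ed_filter_cpp(blk$s, integer(length(blk$s)), theta[["w0"]],
                              theta[["wS"]], theta[["gamma"]])
      }
    }
    nll <- nll - sum(dnorm(blk$obs, traj[blk$rating_pos], theta[["sigma"]],
                           log = TRUE))
  }
  nll
}

#' Negative log-likelihood of a model for one participant
#'
#' Gaussian observation model: each observed rating is the latent trajectory
#' value at its rating trial plus N(0, sigma) noise, so
#' `NLL = -sum(log dnorm(observed, trajectory, sigma))` over all rating
#' trials of the supplied blocks.
#'
#' @param model `"WI"` or `"ED"`.
#' @param params A [wi_params()] or [ed_params()] object matching `model`.
#' @param sigma Observation noise sd (> 0).
#' @param ratings Ratings for one participant (rows for the supplied blocks).
#' @param schedule Schedule rows for the same participant and blocks; all
#'   blocks must be of one type (`task` or `control`).
#' @param dimension `"valence"` or `"arousal"`.
#' @return The negative log-likelihood (scalar).
#' @export
negative_log_likelihood <- function(model, params, sigma, ratings, schedule,
                                    dimension = c("valence", "arousal")) {
  model <- match.arg(model, c("WI", "ED"))
  dimension <- match.arg(dimension)
  stopifnot(sigma > 0)
  types <- unique(schedule$block_type)
  if (length(types) != 1L)
    stop("supply blocks of a single type (task or control); fit the two designs separately")
  design <- if (types == "task") "task" else "control"
  if (design == "task" && !.has_split(params))
    design <- "control" # single-parameter model evaluated on task blocks
  if (design == "control" && !.has_single(params))
    stop("control-block likelihoods need non-split model parameters")
  blocks <- .fit_blocks(ratings, schedule, dimension)
  theta <- c(unlist(params[!vapply(params, is.null, logical(1))]), sigma = sigma)
  .blocks_nll(model, design, theta, blocks)
}

#' Fit a model to one participant's ratings by maximum likelihood
#'
#' Bounded multi-start local optimization (`optim` L-BFGS-B) of the Gaussian
#' likelihood. Start points are drawn uniformly within the box bounds; the
#' best restart wins, ties broken by first-found, and the draw sequence is a
#' prefix-stable function of `seed` (so increasing `n_restarts` can only
#' improve the maximized likelihood). The observation noise sd is a free
#' parameter and is counted in `n_params` for the AIC.
#'
#' @param model `"WI"` or `"ED"`.
#' @param ratings Ratings table (rows for the participant are selected via
#'   the schedule's participant id).
#' @param schedule Schedule rows for one participant; blocks of the requested
#'   design are selected.
#' @param dimension `"valence"` or `"arousal"`.
#' @param design `"task"` (relevance-split stimulus parameters), `"control"`
#'   (single parameters), or `"auto"` to infer from the block types present.
#' @param bounds Box bounds, see [default_bounds()].
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed controlling the restart draws.
#' @return An object of class `affect_fit`: model, dimension, design,
#'   fitted parameter object `params`, `sigma`, `loglik`, `n_params`,
#'   `n_obs`, `aic`, `converged`, `n_restarts_used`, and the raw parameter
#'   vector `theta`.
#' @export
fit_mle <- function(model = c("WI", "ED"), ratings, schedule,
                    dimension = c("valence", "arousal"),
                    design = c("auto", "task", "control"),
                    bounds = default_bounds(), n_restarts = 10, seed = 1) {
  model <- match.arg(model)
  dimension <- match.arg(dimension)
  design <- match.arg(design)
  types <- unique(schedule$block_type)
  if (design == "auto") {
    if (length(types) != 1L)
      stop("schedule contains both task and control blocks; pick a design")
    design <- types
  }
  schedule <- schedule[schedule$block_type == design, ]
  if (!nrow(schedule)) stop("schedule has no ", design, " blocks")
  blocks <- .fit_blocks(ratings, schedule, dimension)
  n_obs <- sum(vapply(blocks, function(b) length(b$obs), integer(1)))
  if (n_obs < 8L) stop("need at least 8 ratings to fit (got ", n_obs, ")")
  lay <- .param_layout(model, design, bounds)
  k <- length(lay$names)
  obj <- function(th) {
    names(th) <- lay$names
    .blocks_nll(model, design, th, blocks)
  }
  set.seed(seed)
  best <- NULL
  converged <- FALSE
  for (i in seq_len(n_restarts)) {
    start <- lay$lower + runif(k) * (lay$upper - lay$lower)
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lay$lower,
            upper = lay$upper, control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all restarts failed for ", model, "/", dimension, "/", design)
  # guard against optimizer round-off a hair outside the box
  theta <- setNames(pmin(pmax(best$par, lay$lower), lay$upper), lay$names)
  fit <- structure(list(
    model = model, dimension = dimension, design = design,
    params = .theta_to_params(model, design, theta),
    sigma = theta[["sigma"]],
    loglik = -best$value,
    n_params = k, n_obs = n_obs,
    aic = 2 * k + 2 * best$value,
    converged = converged,
    n_restarts_used = n_restarts,
    theta = theta
  ), class = "affect_fit")
  fit
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2k - 2 logL`, where `k` counts the model parameters plus the free
#' observation noise sd.
#'
#' @param fit An `affect_fit` object, or a number interpreted as a
#'   log-likelihood together with `k`.
#' @param k Number of free parameters (only when `fit` is a log-likelihood).
#' @return The AIC (scalar).
#' @examples
#' aic(-10, k = 3) # 26
#' @export
aic <- function(fit, k = NULL) {
  if (inherits(fit, "affect_fit")) return(2 * fit$n_params - 2 * fit$loglik)
  stopifnot(is.numeric(fit), !is.null(k))
  2 * k - 2 * fit
}

#' @export
print.affect_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%s, %s design): logL = %.3f, AIC = %.3f, k = %d, n = %d\n",
              x$model, x$dimension, x$design, x$loglik, x$aic, x$n_params, x$n_obs))
  cat("  ", paste(sprintf("%s = %.3f", names(x$theta), x$theta), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fit both candidate models to every participant of a dataset
#'
#' Convenience looper over participants, models and affect dimensions.
#' Per-fit seeds are drawn from a stream seeded by `seed`, so the whole table
#' is reproducible.
#'
#' @param ratings Ratings table for one or more participants.
#' @param schedule Matching schedule.
#' @param models Character vector of models to fit.
#' @param dimensions Affect dimensions to fit.
#' @param design `"task"` or `"control"`.
#' @param bounds,n_restarts,seed Passed to [fit_mle()].
#' @return A data frame with one row per participant x model x dimension:
#'   identification columns, `k`, `loglik`, `aic`, `converged`, `sigma`, and
#'   one column per fitted parameter (NA where a parameter does not apply).
#'   The full `affect_fit` objects are attached as the `"fits"` attribute.
#' @export
fit_dataset <- function(ratings, schedule, models = c("WI", "ED"),
                        dimensions = c("valence", "arousal"),
                        design = c("task", "control"),
                        bounds = default_bounds(), n_restarts = 10, seed = 1) {
  design <- match.arg(design)
  set.seed(seed)
  pids <- unique(schedule$participant_id)
  fit_seeds <- sample.int(2147483647L, length(pids) * length(models) * length(dimensions))
  rows <- list()
  fits <- list()
  i <- 0L
  all_par_names <- c("x0", "beta", "beta_rel", "beta_irr", "w0", "wS",
                     "wS_rel", "wS_irr", "gamma", "gamma_rel", "gamma_irr")
  for (pid in pids) {
    sch_p <- schedule[schedule$participant_id == pid, ]
    for (m in models) {
      for (dim in dimensions) {
        i <- i + 1L
        fit <- fit_mle(m, ratings, sch_p, dimension = dim, design = design,
                       bounds = bounds, n_restarts = n_restarts,
                       seed = fit_seeds[i])
        pars <- setNames(rep(NA_real_, length(all_par_names)), all_par_names)
        th <- fit$theta[names(fit$theta) != "sigma"]
        pars[names(th)] <- th
        rows[[i]] <- cbind(
          data.frame(participant_id = pid, model = m, dimension = dim,
                     design = design, k = fit$n_params, n_obs = fit$n_obs,
                     loglik = fit$loglik, aic = fit$aic,
                     converged = fit$converged, sigma = fit$sigma,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(pars)))
        fits[[paste(pid, m, dim, sep = ".")]] <- fit
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Per-participant log model evidence from a fit table
#'
#' Log model evidence is approximated as `-AIC/2`. When both affect
#' dimensions are requested the per-dimension AICs are summed per
#' participant and model, treating a dataset's valence and arousal ratings
#' as jointly explained by one model.
#'
#' @param fit_table Output of [fit_dataset()].
#' @param dimensions Dimensions to pool (default both).
#' @return An N x K matrix of log evidences (participants x models), with
#'   dimnames.
#' @export
evidence_matrix <- function(fit_table, dimensions = c("valence", "arousal")) {
  ft <- fit_table[fit_table$dimension %in% dimensions, ]
  pids <- unique(ft$participant_id)
  models <- unique(ft$model)
  out <- matrix(NA_real_, length(pids), length(models),
                dimnames = list(pids, models))
  for (i in seq_along(pids)) {
    for (j in seq_along(models)) {
      sel <- ft$participant_id == pids[i] & ft$model == models[j]
      out[i, j] <- -sum(ft$aic[sel]) / 2
    }
  }
  if (anyNA(out)) stop("missing fits for some participant/model combinations")
  out
}
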