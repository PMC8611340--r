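#' Extract per-participant WI parameters and noise sds from a fit table
#'
#' Reshapes the output of [fit_dataset()] (WI rows) into the
#' `params` / `noise_sd` structures consumed by [simulate_ratings()] and
#' [validate_wi_model()].
#'
#' @param fit_table Output of [fit_dataset()] containing WI fits for both
#'   dimensions.
#' @return A list with `params` (named per-participant list of
#'   `list(valence = , arousal = )` [wi_params()] objects) and `noise`
#'   (data frame `participant_id`, `valence`, `arousal`).
#' @export
wi_params_from_fits <- function(fit_table) {
  ft <- fit_table[fit_table$model == "WI", ]
  if (!nrow(ft)) stop("fit table contains no WI fits")
  split_design <- ft$design[1] == "task"
  pids <- unique(ft$participant_id)
  one <- function(pid, dim) {
    row <- ft[ft$participant_id == pid & ft$dimension == dim, ]
    if (nrow(row) != 1L) stop("missing WI ", dim, " fit for ", pid)
    if (split_design)
      wi_params(x0 = row$x0, beta_rel = row$beta_rel, beta_irr = row$beta_irr)
    else
      wi_params(x0 = row$x0, beta = row$beta)
  }
  params <- setNames(lapply(pids, function(p)
    list(valence = one(p, "valence"), arousal = one(p, "arousal"))), pids)
  noise <- data.frame(
    participant_id = pids,
    valence = vapply(pids, function(p)
      ft$sigma[ft$participant_id == p & ft$dimension == "valence"], numeric(1)),
    arousal = vapply(pids, function(p)
      ft$sigma[ft$participant_id == p & ft$dimension == "arousal"], numeric(1)),
    stringsAsFactors = FALSE
  )
  list(params = params, noise = noise)
}

#' Posterior-predictive validation of the weighted-impact model
#'
#' Simulates `n_sims` full datasets from per-participant WI parameters on the
#' observed schedules, analyses each with the same lagged
#' affect-by-relevance regression used for the reference data, and checks
#' whether every reference coefficient estimate falls inside the central 95%
#' interval of its simulated distribution.
#'
#' @param params_by_participant Named per-participant list of
#'   `list(valence = , arousal = )` [wi_params()] objects (see
#'   [wi_params_from_fits()]).
#' @param noise_sd Observation noise: scalar or per-participant data frame.
#' @param schedule Schedule whose task blocks are reused for every
#'   simulation (relevance assignments are not regenerated).
#' @param observed_ratings Reference ratings analysed with the same
#'   regression to obtain the observed coefficient estimates.
#' @param n_sims Number of simulated datasets.
#' @param seed Integer seed.
#' @param method Regression estimator passed to [fit_lagged_model()].
#' @param dimensions Affect dimensions to validate.
#' @return An object of class `validation_report`: per dimension a data
#'   frame with the observed estimate and CI, simulated quantiles
#'   (2.5/25/50/75/97.5%), simulated mean, and a logical `covered`; plus
#'   `n_sims`, `seed` and the raw simulated coefficient draws.
#' @export
validate_wi_model <- function(params_by_participant, noise_sd, schedule,
                              observed_ratings, n_sims = 100, seed = 1,
                              method = c("two_stage", "lmm"),
                              dimensions = c("valence", "arousal")) {
  method <- match.arg(method)
  task <- schedule[schedule$block_type == "task", ]
  set.seed(seed)
  sim_seeds <- sample.int(2147483647L, n_sims)
  observed <- list()
  draws <- list()
  for (dim in dimensions) {
    d_obs <- build_lag_design(task, observed_ratings, dim,
                              include_relevance = TRUE)
    observed[[dim]] <- fit_lagged_model(d_obs, method = method)
    draws[[dim]] <- matrix(NA_real_, n_sims, length(observed[[dim]]$coef),
                           dimnames = list(NULL, names(observed[[dim]]$coef)))
  }
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    ratings_i <- simulate_ratings(task, "WI", params_by_participant, noise_sd,
                                  seed = sim_seeds[i])
    for (dim in dimensions) {
      d_i <- build_lag_design(task, ratings_i, dim, include_relevance = TRUE)
      fit_i <- tryCatch(fit_lagged_model(d_i, method = method),
                        error = function(e) NULL)
      if (is.null(fit_i)) { n_failed <- n_failed + 1L; next }
      draws[[dim]][i, ] <- fit_i$coef
    }
  }
  tables <- list()
  for (dim in dimensions) {
    obs <- observed[[dim]]
    D <- draws[[dim]]
    qs <- t(apply(D, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                  na.rm = TRUE))
    tables[[dim]] <- data.frame(
      coefficient = names(obs$coef),
      observed = as.numeric(obs$coef),
      obs_ci_low = as.numeric(obs$ci_low),
      obs_ci_high = as.numeric(obs$ci_high),
      sim_q025 = qs[, 1], sim_q25 = qs[, 2], sim_median = qs[, 3],
      sim_q75 = qs[, 4], sim_q975 = qs[, 5],
      sim_mean = colMeans(D, na.rm = TRUE),
      covered = as.numeric(obs$coef) >= qs[, 1] &
        as.numeric(obs$coef) <= qs[, 5],
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  structure(list(coverage = tables, draws = draws, n_sims = n_sims,
                 n_failed = n_failed, seed = seed, method = method),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Posterior-predictive validation (", x$n_sims, " simulations, ",
      x$method, " regression)\n", sep = "")
  for (dim in names(x$coverage)) {
    tab <- x$coverage[[dim]]
    cat(dim, ": ", sum(tab$covered), "/", nrow(tab),
        " coefficients covered by the simulated 95% interval\n", sep = "")
  }
  invisible(x)
}
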