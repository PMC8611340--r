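#' Default parameter priors for recovery simulations
#'
#' Uniform ranges used when drawing generating parameters for simulated
#' participants. They span the range plausibly recovered from standardized
#' rating data: update weights and forgetting factors away from their
#' boundaries, modest stimulus weights and constants, and observation noise
#' between about a third and one rating sd.
#'
#' @return Named list of `c(min, max)` ranges for `beta`, `gamma`, `w0`,
#'   `wS`, `x0` and `sigma`.
#' @export
default_param_priors <- function() {
  list(beta = c(0.1, 0.9), gamma = c(0.1, 0.9), w0 = c(-0.5, 0.5),
       wS = c(0.1, 1.0), x0 = c(-1, 1), sigma = c(0.3, 1.0))
}

.draw_range <- function(r) runif(1, r[1], r[2])

.draw_model_params <- function(model, design, priors) {
  one_dim <- function() {
    if (model == "WI") {
      if (design == "control")
        wi_params(x0 = .draw_range(priors$x0), beta = .draw_range(priors$beta))
      else
        wi_params(x0 = .draw_range(priors$x0),
                  beta_rel = .draw_range(priors$beta),
                  beta_irr = .draw_range(priors$beta))
    } else {
      if (design == "control")
        ed_params(w0 = .draw_range(priors$w0), wS = .draw_range(priors$wS),
                  gamma = .draw_range(priors$gamma))
      else
        ed_params(w0 = .draw_range(priors$w0),
                  wS_rel = .draw_range(priors$wS),
                  wS_irr = .draw_range(priors$wS),
                  gamma_rel = .draw_range(priors$gamma),
                  gamma_irr = .draw_range(priors$gamma))
    }
  }
  list(valence = one_dim(), arousal = one_dim())
}

.draw_dataset_params <- function(model, design, priors, pids,
                                 noise_sd = NULL) {
  params <- setNames(lapply(pids, function(p)
    .draw_model_params(model, design, priors)), pids)
  noise <- data.frame(
    participant_id = pids,
    valence = if (is.null(noise_sd)) runif(length(pids), priors$sigma[1], priors$sigma[2])
              else rep(noise_sd, length(pids)),
    arousal = if (is.null(noise_sd)) runif(length(pids), priors$sigma[1], priors$sigma[2])
              else rep(noise_sd, length(pids)),
    stringsAsFactors = FALSE
  )
  list(params = params, noise = noise)
}

#' Model-recovery simulation
#'
#' Simulates datasets (per-participant valence and arousal ratings) from
#' each candidate model with parameters drawn from `priors`, fits both
#' models to every participant of every dataset, and selects a dataset-level
#' winner by group-level Bayesian model selection on the AICs (argmax of the
#' protected exceedance probability). The confusion matrix counts selected
#' against generating models; a pxp tie (difference below 1e-6) is recorded
#' in the winner table and, counting against recovery, tallied in the
#' off-diagonal cell.
#'
#' @param design `"task"` (4 blocks, 76 ratings per participant,
#'   relevance-split parameters) or `"control"` (1 block, 19 ratings, single
#'   parameters).
#' @param n_datasets_per_model Simulated datasets per generating model.
#' @param n_participants Participants per dataset.
#' @param seed Integer seed; the whole harness is reproducible given it.
#' @param priors Parameter ranges, see [default_param_priors()].
#' @param catalog Stimulus catalog (a default one is generated when `NULL`).
#' @param noise_sd Fixed observation noise sd; `NULL` (default) draws per
#'   participant and dimension from `priors$sigma`.
#' @param n_restarts Restarts per individual fit.
#' @return An object of class `recovery_report` with `confusion` (2 x 2
#'   counts), `winners` (per-dataset records incl. pxp), and `settings`.
#' @export
model_recovery <- function(design = c("task", "control"),
                           n_datasets_per_model = 10, n_participants = 20,
                           seed = 1, priors = default_param_priors(),
                           catalog = NULL, noise_sd = NULL, n_restarts = 10) {
  design <- match.arg(design)
  set.seed(seed)
  if (is.null(catalog)) catalog <- generate_catalog(seed = sample.int(2147483647L, 1))
  models <- c("WI", "ED")
  n_total <- 2L * n_datasets_per_model
  seeds <- matrix(sample.int(2147483647L, n_total * 4L), n_total, 4L)
  confusion <- matrix(0L, 2, 2, dimnames = list(generated = models,
                                                selected = models))
  winners <- list()
  row <- 0L
  for (gen in models) {
    for (d in seq_len(n_datasets_per_model)) {
      row <- row + 1L
      sch <- build_schedule(n_participants, catalog, seed = seeds[row, 1L])
      sch <- sch[sch$block_type == design, ]
      set.seed(seeds[row, 2L])
      dp <- .draw_dataset_params(gen, design, priors,
                                 unique(sch$participant_id), noise_sd)
      ratings <- simulate_ratings(sch, gen, dp$params, dp$noise,
                                  seed = seeds[row, 3L])
      ft <- fit_dataset(ratings, sch, models = models, design = design,
                        n_restarts = n_restarts, seed = seeds[row, 4L])
      bms <- rfx_bms(evidence_matrix(ft))
      tie <- abs(diff(range(bms$pxp))) < 1e-6
      sel <- if (tie) "tie" else models[which.max(bms$pxp)]
      tallied <- if (tie || sel != gen) setdiff(models, gen) else gen
      confusion[gen, tallied] <- confusion[gen, tallied] + 1L
      winners[[row]] <- data.frame(
        generated = gen, dataset = d, selected = sel,
        pxp_WI = bms$pxp[["WI"]], pxp_ED = bms$pxp[["ED"]],
        correct = !tie && sel == gen, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    confusion = confusion,
    winners = do.call(rbind, winners),
    parameter_recovery = NULL,
    settings = list(design = design,
                    n_datasets_per_model = n_datasets_per_model,
                    n_participants = n_participants, seed = seed,
                    priors = priors, noise_sd = noise_sd,
                    n_restarts = n_restarts)
  ), class = "recovery_report")
}

#' Parameter-recovery simulation
#'
#' Simulates one participant per "dataset" from the chosen model with
#' parameters drawn from `priors`, refits the same model by maximum
#' likelihood, and reports true-vs-estimated pairs with their Pearson
#' correlation and mean bias per parameter and affect dimension.
#'
#' @inheritParams model_recovery
#' @param model Generating (and fitted) model, `"WI"` or `"ED"`.
#' @param n_datasets Number of simulated participants.
#' @return A `recovery_report` whose `parameter_recovery` field holds the
#'   per-parameter pairs and whose `summary` holds correlation and bias per
#'   parameter x dimension.
#' @export
parameter_recovery <- function(model = c("WI", "ED"),
                               design = c("task", "control"),
                               n_datasets = 50, seed = 1,
                               priors = default_param_priors(),
                               catalog = NULL, noise_sd = NULL,
                               n_restarts = 10) {
  model <- match.arg(model)
  design <- match.arg(design)
  set.seed(seed)
  if (is.null(catalog)) catalog <- generate_catalog(seed = sample.int(2147483647L, 1))
  seeds <- sample.int(2147483647L, 4L)
  sch <- build_schedule(n_datasets, catalog, seed = seeds[1L])
  sch <- sch[sch$block_type == design, ]
  pids <- unique(sch$participant_id)
  set.seed(seeds[2L])
  dp <- .draw_dataset_params(model, design, priors, pids, noise_sd)
  ratings <- simulate_ratings(sch, model, dp$params, dp$noise, seed = seeds[3L])
  ft <- fit_dataset(ratings, sch, models = model, design = design,
                    n_restarts = n_restarts, seed = seeds[4L])
  par_cols <- names(ft)[!names(ft) %in%
    c("participant_id", "model", "dimension", "design", "k", "n_obs",
      "loglik", "aic", "converged")]
  pairs <- list()
  for (i in seq_len(nrow(ft))) {
    pid <- ft$participant_id[i]
    dim <- ft$dimension[i]
    true_par <- dp$params[[pid]][[dim]]
    true_vec <- c(unlist(true_par[!vapply(true_par, is.null, logical(1))]),
                  sigma = dp$noise[dp$noise$participant_id == pid, dim])
    for (nm in names(true_vec)) {
      est <- ft[[nm]][i]
      if (nm == "sigma") est <- ft$sigma[i]
      pairs[[length(pairs) + 1L]] <- data.frame(
        participant_id = pid, dimension = dim, parameter = nm,
        true = as.numeric(true_vec[[nm]]), estimated = as.numeric(est),
        stringsAsFactors = FALSE)
    }
  }
  pr <- do.call(rbind, pairs)
  summ <- do.call(rbind, lapply(split(pr, list(pr$parameter, pr$dimension),
                                      drop = TRUE), function(g) {
    data.frame(parameter = g$parameter[1], dimension = g$dimension[1],
               correlation = if (sd(g$true) > 0 && sd(g$estimated) > 0)
                 stats::cor(g$true, g$estimated) else NA_real_,
               bias = mean(g$estimated - g$true),
               rmse = sqrt(mean((g$estimated - g$true)^2)),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(
    confusion = NULL, winners = NULL,
    parameter_recovery = pr, summary = summ,
    settings = list(model = model, design = design, n_datasets = n_datasets,
                    seed = seed, priors = priors, noise_sd = noise_sd,
                    n_restarts = n_restarts)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report (", x$settings$design, " design)\n", sep = "")
  if (!is.null(x$confusion)) {
    cat("Confusion (generated x selected):\n")
    print(x$confusion)
  }
  if (!is.null(x$summary)) {
    cat("Parameter recovery:\n")
    print(x$summary, digits = 3)
  }
  invisible(x)
}
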