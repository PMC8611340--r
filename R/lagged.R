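#' Build the lagged design table for the affect regression
#'
#' One row per affect rating, carrying the standardized normative affect of
#' the four images viewed since the previous rating: `S_lag1` is the image
#' immediately before the rating (temporal position 4 of the window),
#' `S_lag4` the earliest of the four. Valence models use normative valence
#' lags, arousal models normative arousal lags (no cross-dimension
#' predictors). With `include_relevance = TRUE` the table is restricted to
#' task blocks and gains 0/1 relevance indicators `rel_lag1..rel_lag4`
#' (1 = task-relevant), which enter the regression only through
#' affect-by-relevance interactions.
#'
#' @param schedule Schedule rows (any number of participants).
#' @param ratings Matching standardized ratings.
#' @param dimension `"valence"` or `"arousal"`.
#' @param include_relevance Add relevance indicators (task blocks only).
#' @return A data frame with columns `participant_id`, `block_index`,
#'   `rating_index`, `rating`, `S_lag1..S_lag4` and, optionally,
#'   `rel_lag1..rel_lag4`.
#' @export
build_lag_design <- function(schedule, ratings,
                             dimension = c("valence", "arousal"),
                             include_relevance = FALSE) {
  dimension <- match.arg(dimension)
  scol <- if (dimension == "valence") "s_valence" else "s_arousal"
  rcol <- paste0(dimension, "_std")
  if (include_relevance) schedule <- schedule[schedule$block_type == "task", ]
  s <- schedule[order(schedule$participant_id, schedule$block_index,
                      schedule$trial_index), ]
  if (nrow(s) %% 4L != 0L) stop("schedule rows are not whole rating windows")
  # rows come in groups of 4 (positions 1..4 of one rating window)
  S <- matrix(s[[scol]], nrow = 4L)
  key <- s[s$position == 4L, c("participant_id", "block_index", "window")]
  out <- data.frame(
    participant_id = key$participant_id,
    block_index = key$block_index,
    rating_index = key$window,
    S_lag1 = S[4L, ], S_lag2 = S[3L, ], S_lag3 = S[2L, ], S_lag4 = S[1L, ],
    stringsAsFactors = FALSE
  )
  if (include_relevance) {
    R <- matrix(as.integer(s$relevance == "relevant"), nrow = 4L)
    out$rel_lag1 <- R[4L, ]; out$rel_lag2 <- R[3L, ]
    out$rel_lag3 <- R[2L, ]; out$rel_lag4 <- R[1L, ]
  }
  m <- match(paste(out$participant_id, out$block_index, out$rating_index),
             paste(ratings$participant_id, ratings$block_index,
                   ratings$rating_index))
  if (anyNA(m)) stop("ratings are missing for some rating trials of the schedule")
  out$rating <- ratings[[rcol]][m]
  out
}

.lag_terms <- function(design) {
  terms <- paste0("S_lag", 1:4)
  if ("rel_lag1" %in% names(design))
    terms <- c(terms, paste0("S_lag", 1:4, ":rel_lag", 1:4))
  terms
}

.two_stage_fit <- function(design, fml_fixed, terms) {
  pids <- unique(design$participant_id)
  if (length(pids) < 2L) stop("need at least 2 participants")
  B <- t(vapply(pids, function(pid) {
    d <- design[design$participant_id == pid, ]
    if (nrow(d) < 8L) stop("participant ", pid, " has fewer than 8 ratings")
    coef(lm(fml_fixed, data = d))
  }, numeric(length(terms) + 1L)))
  if (anyNA(B)) {
    bad <- pids[apply(B, 1L, anyNA)]
    warning("dropping participants with rank-deficient individual fits: ",
            paste(bad, collapse = ", "))
    B <- B[!apply(B, 1L, anyNA), , drop = FALSE]
  }
  N <- nrow(B)
  est <- colMeans(B)
  covm <- stats::cov(B) / N
  list(coef = est, cov = covm, n_participants = N)
}

#' Hierarchical regression of momentary affect on lagged stimulus affect
#'
#' Fits the rating as a linear function of the four lagged normative-affect
#' predictors (plus affect-by-relevance interactions when present in the
#' design), with participant-level random intercepts and random slopes on
#' every fixed predictor. The mixed model is estimated with `lme4::lmer`
#' (diagonal random-effects covariance, ML). If that fit is singular or
#' fails, the function falls back to a two-stage summary-statistics
#' estimator — per-participant least squares, then the across-participant
#' mean with its empirical covariance — and flags the fallback; in this
#' balanced design the two agree closely. `method = "two_stage"` requests
#' the fallback directly (useful inside large simulation loops).
#'
#' P-values are two-sided Wald/normal.
#'
#' @param design Output of [build_lag_design()].
#' @param method `"lmm"` (default) or `"two_stage"`.
#' @return An object of class `lagged_fit` with `coef`, `se`, `cov`,
#'   `pvals`, `ci_low`, `ci_high`, `n_obs`, `n_participants`,
#'   `method_used` and `fallback`.
#' @export
fit_lagged_model <- function(design, method = c("lmm", "two_stage")) {
  method <- match.arg(method)
  terms <- .lag_terms(design)
  fml_fixed <- as.formula(paste("rating ~", paste(terms, collapse = " + ")))
  fallback <- FALSE
  method_used <- method
  res <- NULL
  if (method == "lmm") {
    # interaction terms are not valid inside a (.||.) bar; expand to the
    # product columns by hand
    slope_terms <- gsub(":", "_x_", terms, fixed = TRUE)
    d2 <- design
    if ("rel_lag1" %in% names(design)) {
      for (l in 1:4)
        d2[[paste0("S_lag", l, "_x_rel_lag", l)]] <-
          d2[[paste0("S_lag", l)]] * d2[[paste0("rel_lag", l)]]
    }
    fml <- as.formula(paste(
      "rating ~", paste(slope_terms, collapse = " + "),
      "+ (1 +", paste(slope_terms, collapse = " + "), "|| participant_id)"))
    lfit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = d2, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(lfit) && !lme4::isSingular(lfit, tol = 1e-5)) {
      est <- lme4::fixef(lfit)
      names(est) <- c("(Intercept)", terms)
      covm <- as.matrix(vcov(lfit))
      dimnames(covm) <- list(names(est), names(est))
      res <- list(coef = est, cov = covm,
                  n_participants = length(unique(design$participant_id)))
    } else {
      fallback <- TRUE
      method_used <- "two_stage"
    }
  }
  if (is.null(res)) res <- .two_stage_fit(design, fml_fixed, terms)
  names(res$coef) <- c("(Intercept)", terms)
  dimnames(res$cov) <- list(names(res$coef), names(res$coef))
  se <- sqrt(diag(res$cov))
  z <- res$coef / se
  structure(list(
    coef = res$coef, se = se, cov = res$cov,
    pvals = 2 * pnorm(-abs(z)),
    ci_low = res$coef - 1.959964 * se,
    ci_high = res$coef + 1.959964 * se,
    n_obs = nrow(design), n_participants = res$n_participants,
    method_used = method_used, fallback = fallback
  ), class = "lagged_fit")
}

#' @export
print.lagged_fit <- function(x, ...) {
  cat("Lagged affect regression (", x$method_used,
      if (x$fallback) ", fallback" else "", "): ",
      x$n_obs, " ratings, ", x$n_participants, " participants\n", sep = "")
  tab <- data.frame(estimate = x$coef, ci_low = x$ci_low, ci_high = x$ci_high,
                    p = x$pvals)
  print(round(tab, 4))
  invisible(x)
}

#' Wald comparison of two regression coefficients
#'
#' `z = (b_i - b_j) / sqrt(var_i + var_j - 2 cov_ij)` with a two-sided
#' normal p-value; invariant to shifting both coefficients by a constant and
#' antisymmetric in the argument order.
#'
#' @param fit A `lagged_fit` (or any list with `coef` and `cov`).
#' @param name_i,name_j Coefficient names to compare.
#' @return A list with `z` and `p`.
#' @examples
#' f <- list(coef = c(a = 0.3, b = 0.1),
#'           cov = matrix(c(0.01, 0, 0, 0.01), 2, dimnames = list(c("a","b"), c("a","b"))))
#' wald_compare(f, "a", "b") # z = 1.414, p = 0.157
#' @export
wald_compare <- function(fit, name_i, name_j) {
  b <- fit$coef
  V <- fit$cov
  if (!all(c(name_i, name_j) %in% names(b)))
    stop("unknown coefficient name")
  v <- V[name_i, name_i] + V[name_j, name_j] - 2 * V[name_i, name_j]
  z <- (b[[name_i]] - b[[name_j]]) / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Holm-Bonferroni step-down multiple-comparison correction
#'
#' Standard step-down Holm procedure (via `p.adjust`); adjusted p-values are
#' monotone non-decreasing in the rank of the raw p-values, and the Holm
#' rejections always contain the plain Bonferroni rejections.
#'
#' @param pvals Named numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return A data frame with `p_raw`, `p_adjusted` and logical `reject`.
#' @examples
#' holm_bonferroni(c(a = 0.01, b = 0.03, c = 0.04))
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- p.adjust(pvals, method = "holm")
  data.frame(p_raw = as.numeric(pvals), p_adjusted = as.numeric(adj),
             reject = as.numeric(adj) <= alpha,
             row.names = names(pvals))
}

#' Sample size for a paired (one-sample) t test
#'
#' Smallest n whose noncentral-t power reaches the target for effect size
#' `dz` (mean difference in sd units), using noncentrality `dz * sqrt(n)` and
#' `n - 1` degrees of freedom.
#'
#' @param dz Standardized paired effect size (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return The required sample size (integer).
#' @examples
#' paired_ttest_sample_size(0.5, power = 0.95, alpha = 0.05) # 54
#' @export
paired_ttest_sample_size <- function(dz, power = 0.95, alpha = 0.05,
                                     two_sided = TRUE) {
  stopifnot(dz > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  pow_at <- function(n) {
    df <- n - 1
    ncp <- dz * sqrt(n)
    crit <- qt(1 - alpha / if (two_sided) 2 else 1, df)
    p <- 1 - pt(crit, df, ncp)
    if (two_sided) p <- p + pt(-crit, df, ncp)
    p
  }
  n <- 2L
  while (pow_at(n) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size search did not terminate")
  }
  n
}
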