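#' Exponential-decay (ED) model parameters
#'
#' The ED model writes momentary affect after the t-th stimulus of a block as
#' a constant plus an exponentially discounted sum of the normative affect of
#' all stimuli seen so far in the block:
#' \deqn{V_t = w_0 + \sum_{j=1}^{t} w_S \, \gamma^{t-j} S_j}
#' with forgetting factor \eqn{0 \le \gamma \le 1}. As \eqn{\gamma \to 1}
#' every stimulus is weighted evenly; as \eqn{\gamma \to 0} only the most
#' recent stimulus matters (with the convention \eqn{0^0 = 1}).
#'
#' For task blocks the stimulus weight and forgetting factor may be split by
#' goal-relevance: the weight and decay applied to stimulus j are chosen by
#' stimulus j's own relevance class, while the exponent \eqn{t-j} counts all
#' intervening stimuli.
#'
#' @param w0 Constant term around which affect fluctuates.
#' @param wS,gamma Single (non-split) stimulus weight and forgetting factor,
#'   used for control/passive-viewing blocks.
#' @param wS_rel,wS_irr,gamma_rel,gamma_irr Relevance-split weights and
#'   forgetting factors for task blocks.
#' @return An object of class `ed_params`.
#' @examples
#' ed_params(w0 = 0, wS = 1, gamma = 0.5)
#' ed_params(w0 = 0, wS_rel = 1, wS_irr = 0.5, gamma_rel = 0.6, gamma_irr = 0.6)
#' @export
ed_params <- function(w0, wS = NULL, gamma = NULL,
                      wS_rel = NULL, wS_irr = NULL,
                      gamma_rel = NULL, gamma_irr = NULL) {
  has_single <- !is.null(wS) || !is.null(gamma)
  has_split <- !is.null(wS_rel) || !is.null(wS_irr) ||
    !is.null(gamma_rel) || !is.null(gamma_irr)
  if (has_single && (is.null(wS) || is.null(gamma)))
    stop("both `wS` and `gamma` must be given for a non-split ED model")
  if (has_split && (is.null(wS_rel) || is.null(wS_irr) ||
                    is.null(gamma_rel) || is.null(gamma_irr)))
    stop("all of wS_rel, wS_irr, gamma_rel, gamma_irr must be given for a relevance-split ED model")
  if (!has_single && !has_split)
    stop("ED parameters need either (wS, gamma) or the relevance-split set")
  for (g in c(gamma, gamma_rel, gamma_irr))
    if (!is.finite(g) || g < 0 || g > 1)
      stop("forgetting factors gamma must lie in [0, 1]")
  for (w in c(w0, wS, wS_rel, wS_irr))
    if (!is.finite(w)) stop("ED weights must be finite")
  structure(list(w0 = w0, wS = wS, gamma = gamma,
                 wS_rel = wS_rel, wS_irr = wS_irr,
                 gamma_rel = gamma_rel, gamma_irr = gamma_irr),
            class = "ed_params")
}

#' Weighted-impact (WI) model parameters
#'
#' The WI model updates momentary affect toward each incoming stimulus'
#' normative affect by a fraction \eqn{\beta} (a delta rule, mathematically
#' akin to Rescorla-Wagner learning):
#' \deqn{V_t = V_{t-1} + \beta (S_t - V_{t-1}), \qquad V_0 = x_0}
#' \eqn{\beta = 0} freezes affect at the initial state; \eqn{\beta = 1} makes
#' affect track only the most recent stimulus. For task blocks \eqn{\beta}
#' may be split by stimulus goal-relevance.
#'
#' @param x0 Initial affective state at the start of each block.
#' @param beta Single (non-split) update weight in `[0, 1]`.
#' @param beta_rel,beta_irr Relevance-split update weights for task blocks.
#' @return An object of class `wi_params`.
#' @examples
#' wi_params(x0 = 0, beta = 0.4)
#' wi_params(x0 = 0, beta_rel = 0.32, beta_irr = 0.25)
#' @export
wi_params <- function(x0, beta = NULL, beta_rel = NULL, beta_irr = NULL) {
  has_split <- !is.null(beta_rel) || !is.null(beta_irr)
  if (has_split && (is.null(beta_rel) || is.null(beta_irr)))
    stop("both beta_rel and beta_irr must be given for a relevance-split WI model")
  if (is.null(beta) && !has_split)
    stop("WI parameters need `beta` or the relevance-split pair")
  for (b in c(beta, beta_rel, beta_irr))
    if (!is.finite(b) || b < 0 || b > 1)
      stop("update weights beta must lie in [0, 1]")
  if (!is.finite(x0)) stop("x0 must be finite")
  structure(list(x0 = x0, beta = beta,
                 beta_rel = beta_rel, beta_irr = beta_irr),
            class = "wi_params")
}

.has_split <- function(params) {
  if (inherits(params, "wi_params")) !is.null(params$beta_rel)
  else !is.null(params$wS_rel)
}

.has_single <- function(params) {
  if (inherits(params, "wi_params")) !is.null(params$beta)
  else !is.null(params$wS)
}

# Map a relevance vector to 0-based group indices plus per-group parameter
# vectors. relevance may be NULL (single-parameter model), a logical vector
# (TRUE = relevant) or a character vector with values "relevant"/"irrelevant".
.relevance_groups <- function(relevance, n) {
  if (is.null(relevance)) return(integer(n))
  if (length(relevance) != n)
    stop("length mismatch between stimuli and relevance flags")
  if (is.character(relevance) || is.factor(relevance)) {
    relevance <- as.character(relevance)
    bad <- !relevance %in% c("relevant", "irrelevant")
    if (any(bad))
      stop("relevance flags must be 'relevant' or 'irrelevant' (got: ",
           paste(unique(relevance[bad]), collapse = ", "), ")")
    ifelse(relevance == "relevant", 0L, 1L)
  } else {
    as.integer(!as.logical(relevance)) # TRUE -> group 0 (relevant)
  }
}

#' Exponential-decay affect trajectory
#'
#' Computes the latent ED-model affect trajectory over one block of stimuli.
#' The discounted sum starts afresh at the block boundary.
#'
#' @param params An [ed_params()] object.
#' @param stimuli Ordered standardized normative stimulus values for one block.
#' @param relevance Optional relevance flags, one per stimulus (`"relevant"`/
#'   `"irrelevant"` or logical). Must be supplied iff `params` are
#'   relevance-split.
#' @return Numeric vector of trajectory values, one per stimulus.
#' @examples
#' ed_trajectory(ed_params(0, wS = 1, gamma = 1), c(0.2, 0.3, 0.5)) # cumulative sum
#' ed_trajectory(ed_params(0.1, wS = 2, gamma = 0), c(1, -1))       # most recent only
#' @export
ed_trajectory <- function(params, stimuli, relevance = NULL) {
  stopifnot(inherits(params, "ed_params"))
  n <- length(stimuli)
  if (is.null(relevance)) {
    if (!.has_single(params))
      stop("ED params are relevance-split but no relevance flags were supplied")
    grp <- integer(n); wS <- params$wS; gam <- params$gamma
  } else {
    if (!.has_split(params))
      stop("relevance flags supplied but ED params are not relevance-split")
    grp <- .relevance_groups(relevance, n)
    wS <- c(params$wS_rel, params$wS_irr)
    gam <- c(params$gamma_rel, params$gamma_irr)
  }
  as.numeric(ed_filter_cpp(as.numeric(stimuli), grp, params$w0, wS, gam))
}

#' Weighted-impact affect trajectory (recursive form)
#'
#' Runs the WI delta-rule recursion over one block of stimuli, starting from
#' the initial state `x0` at the block boundary. The latent trajectory is
#' purely feedforward: it is never re-anchored to observed ratings.
#'
#' @inheritParams ed_trajectory
#' @param params A [wi_params()] object.
#' @return Numeric vector of trajectory values, one per stimulus.
#' @examples
#' wi_trajectory_recursive(wi_params(0, beta = 0.5), c(1, 1)) # 0.5, 0.75
#' @export
wi_trajectory_recursive <- function(params, stimuli, relevance = NULL) {
  stopifnot(inherits(params, "wi_params"))
  n <- length(stimuli)
  if (is.null(relevance)) {
    if (!.has_single(params))
      stop("WI params are relevance-split but no relevance flags were supplied")
    grp <- integer(n); beta <- params$beta
  } else {
    if (!.has_split(params))
      stop("relevance flags supplied but WI params are not relevance-split")
    grp <- .relevance_groups(relevance, n)
    beta <- c(params$beta_rel, params$beta_irr)
  }
  as.numeric(wi_filter_cpp(as.numeric(stimuli), grp, params$x0, beta))
}

#' Weighted-impact affect trajectory (closed form)
#'
#' Evaluates the WI model through its closed-form expansion
#' \deqn{V_t = x_0 (1-\beta)^t + \sum_{j=1}^{t} \beta (1-\beta)^{t-j} S_j}
#' which is defined for a single (non-split) update weight. Equivalent to
#' [wi_trajectory_recursive()] up to floating-point error; kept as an
#' independent route for verification.
#'
#' @inheritParams wi_trajectory_recursive
#' @return Numeric vector of trajectory values, one per stimulus.
#' @examples
#' wi_trajectory_closed(wi_params(1, beta = 0.5), c(0, 0)) # geometric decay of x0
#' @export
wi_trajectory_closed <- function(params, stimuli, relevance = NULL) {
  stopifnot(inherits(params, "wi_params"))
  if (!is.null(relevance) || .has_split(params))
    stop("the closed form is defined for a single update weight only; use wi_trajectory_recursive() for relevance-split parameters")
  b <- params$beta
  s <- as.numeric(stimuli)
  n <- length(s)
  out <- numeric(n)
  for (t in seq_len(n)) {
    # (1-b)^0 at j = t: R's 0^0 == 1 gives the beta = 1 limit correctly
    out[t] <- params$x0 * (1 - b)^t + sum(b * (1 - b)^(t - seq_len(t)) * s[seq_len(t)])
  }
  out
}
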