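#' Generate a synthetic normed stimulus catalog
#'
#' Emulates a catalog of affect-inducing images carrying normative valence
#' and arousal ratings on a 7-point scale: `n_pleasant` pleasant stimuli
#' (normative valence > 4.5) and `n_unpleasant` unpleasant stimuli
#' (normative valence < 3.5), with the neutral band 3.5-4.5 excluded, and the
#' two categories matched on mean normative arousal. Valence is drawn
#' uniformly on \[4.6, 6.8\] (pleasant) and \[1.2, 3.4\] (unpleasant);
#' arousal uniformly on \[3.0, 5.5\] for both categories, resampled until the
#' category means agree within `arousal_match_tol`.
#'
#' Standardized columns are catalog-wide z-scores (sample sd); models operate
#' on these so that normative stimulus values and standardized ratings share
#' a scale.
#'
#' @param n_pleasant,n_unpleasant Number of stimuli per category.
#' @param arousal_match_tol Maximum allowed absolute difference between the
#'   category means of normative arousal.
#' @param seed Integer seed; catalogs are reproducible given the seed.
#' @param max_attempts Resampling attempts before the matching is declared
#'   unsatisfiable.
#' @return A `data.frame` of class `stimulus_catalog` with columns
#'   `stimulus_id`, `category`, `valence_raw`, `arousal_raw`, `valence_std`,
#'   `arousal_std`.
#' @examples
#' cat200 <- generate_catalog(100, 100, arousal_match_tol = 0.1, seed = 1)
#' table(cat200$category)
#' @export
generate_catalog <- function(n_pleasant = 100, n_unpleasant = 100,
                             arousal_match_tol = 0.05, seed = 1,
                             max_attempts = 1000) {
  stopifnot(n_pleasant >= 1, n_unpleasant >= 1, arousal_match_tol > 0)
  set.seed(seed)
  val_p <- runif(n_pleasant, 4.6, 6.8)
  val_u <- runif(n_unpleasant, 1.2, 3.4)
  ok <- FALSE
  for (att in seq_len(max_attempts)) {
    aro_p <- runif(n_pleasant, 3.0, 5.5)
    aro_u <- runif(n_unpleasant, 3.0, 5.5)
    if (abs(mean(aro_p) - mean(aro_u)) < arousal_match_tol) { ok <- TRUE; break }
  }
  if (!ok)
    stop("could not match category arousal means within tolerance ",
         arousal_match_tol, " in ", max_attempts, " attempts")
  n <- n_pleasant + n_unpleasant
  out <- data.frame(
    stimulus_id = sprintf("img%03d", seq_len(n)),
    category = rep(c("pleasant", "unpleasant"), c(n_pleasant, n_unpleasant)),
    valence_raw = c(val_p, val_u),
    arousal_raw = c(aro_p, aro_u),
    stringsAsFactors = FALSE
  )
  out$valence_std <- as.numeric(scale(out$valence_raw))
  out$arousal_std <- as.numeric(scale(out$arousal_raw))
  class(out) <- c("stimulus_catalog", "data.frame")
  out
}
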