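---
title: "Modelling momentary affect under goal-relevance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling momentary affect under goal-relevance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectdyn)
```

## The problem

Momentary affective experience — self-reported valence and arousal — is not
a sequence of independent snapshots. When people view a stream of evocative
images and report how they feel after every fourth one, each report reflects
a temporal integration of the affective impact of the recent images with the
previous affective state. `affectdyn` implements two generative accounts of
that integration, the machinery to fit and compare them per participant and
at the group level, and a synthetic-experiment generator so that every stage
of the analysis can be exercised and validated without human data.

The experimental paradigm emulated here adds a goal-relevance manipulation:
before each image a cue marks it as task-relevant (a target shape appearing
on it must be identified) or task-irrelevant (responses do not count).
Relevance is orthogonal to the images' affective content, so any difference
between the model parameters fitted to relevant versus irrelevant stimuli
isolates the effect of voluntary attentional selection on affective
dynamics.

## The two models

Within a block, let `S_1, ..., S_t` be the standardized normative affect
values (valence or arousal) of the images seen so far. Both models produce a
latent affect trajectory evaluated at rating trials; ratings are the
trajectory plus Gaussian noise.

**Exponential decay (ED).** Affect after image `t` is a constant plus a
geometrically discounted sum of all images so far:

$$V_t = w_0 + \sum_{j=1}^{t} w_S\,\gamma^{t-j} S_j, \qquad 0 \le \gamma \le 1.$$

`gamma` is a forgetting factor: 1 weights every image evenly, 0 leaves only
the most recent image. We adopt the convention $0^0 = 1$ so that the
`gamma = 0` limit reproduces exactly the "most recent stimulus only"
behaviour.

**Weighted impact (WI).** Affect is updated toward each incoming stimulus by
a fraction `beta`, a delta rule akin to Rescorla–Wagner learning:

$$V_t = V_{t-1} + \beta\,(S_t - V_{t-1}), \qquad V_0 = x_0,\ 0 \le \beta \le 1.$$

Its closed form
$V_t = x_0 (1-\beta)^t + \sum_j \beta (1-\beta)^{t-j} S_j$ is implemented as
an independent route (`wi_trajectory_closed`) and tested to agree with the
recursion to below `1e-10` over a thousand random cases.

Modelling decisions the equations leave open, and how they are resolved
here:

* **Block boundaries.** Trajectories restart at every block: the ED sum is
  emptied and the WI state returns to `x0`. A single shared `x0` is reused
  at the start of each task block (one extra parameter per dimension, not
  four); the data barely constrain per-block initial states because their
  influence decays as $(1-\beta)^4$ by the first rating.
* **Relevance splits.** For task blocks, the stimulus parameters are split
  by the stimulus' *own* relevance class: in the ED model both the weight
  and the forgetting factor applied to image `j` are chosen by `j`'s
  relevance, while the exponent `t - j` counts all intervening images. In
  the WI model the update weight on trial `t` is `beta_rel` or `beta_irr`.
  Control (passive-viewing) blocks use single, non-split parameters.
* **Feedforward latent state.** The latent trajectory is never re-anchored
  to the observed ratings; it is a deterministic function of the stimulus
  sequence and the parameters.
* **Scale.** The WI model has no affine freedom — the state is pulled toward
  `S` itself — so stimulus norms and ratings must share a scale. Normative
  values are standardized catalog-wide; observed slider ratings are
  standardized per participant (pooling all of that participant's ratings in
  a dimension). The ED model could absorb offsets through `w_0` but uses the
  same standardized stimuli for comparability.

## The synthetic experiment

`generate_catalog()` emulates a normed image set: 100 pleasant (normative
valence above 4.5 on the 1–7 scale) and 100 unpleasant (below 3.5) stimuli,
with the neutral band excluded and the two categories matched on mean
normative arousal (default tolerance 0.05; arousal is resampled up to 1,000
times, then the call fails). Valence is drawn uniformly on [4.6, 6.8] and
[1.2, 3.4] and arousal on [3.0, 5.5]: a plausible spread for normed
affective picture sets, chosen once — the generator is a study-condition
definition, not a tuning knob.

`build_schedule()` produces, per participant, four task blocks and one
control block of 76 trials (control first or last, alternating across
participants), with a rating after every fourth image. The generator
enforces the design's balance *exactly, by construction*: 160 targets in
the task portion (20 circles and 20 rectangles per block); 152 relevant and
152 irrelevant images with 38 of each at every temporal position between
consecutive ratings; equal pleasant/unpleasant counts per block, per
temporal position, per relevance level and per target condition; no image
twice in a block and none more than twice overall. The balancing works by
quota matrices: per participant, a doubly balanced 4 x 4 matrix of {9, 10}
counts allocates relevant images over blocks and temporal positions (19 per
cell is odd, so exact within-cell balance is impossible; the 9/10 pattern
makes every row and column sum 38), an analogous matrix allocates pleasant
images, and the pleasant-and-relevant overlap per block is pinned to 19 so
that every category-by-relevance cell holds exactly 19 trials. Within the
control block the pleasant counts per position are a 10/10/9/9 split — one
block alone cannot balance an odd 19 trials per position. An independent
audit (`audit_schedule()`) recounts every constraint from the emitted trial
table.

`simulate_ratings()` emits, at each rating trial, the latent trajectory
value plus `N(0, noise_sd)` noise. Simulated values live directly on the
standardized rating scale; a synthetic slider rendering
(`raw = 50 + 20 * value`, clipped to [0, 100], default position 50) exists
only so that the exclusion rules and file formats behave as they would with
observed data. Recovery analyses fit the simulated standardized values as
emitted — re-z-scoring them would shift the WI scale and break the
true-versus-estimated comparison.

What the generator does *not* emulate: image content, reaction times,
sequential dependencies in human noise (drift, anchoring, slider inertia),
or rating-scale discreteness. Passing recovery tests therefore show that the
*analysis* is sound under the model's own assumptions — not that human data
obey those assumptions.

## Fitting

Each participant x dimension x model is fitted by maximum likelihood under a
Gaussian observation model. The noise sd `sigma` is a free parameter and is
counted in the AIC's `k` (control fits: WI 3, ED 4 parameters; task fits:
WI 4, ED 6). Optimization is bounded L-BFGS-B with 10 uniform random
restarts inside the box bounds (`beta`, `gamma` in [0, 1]; `w0`, `x0` in
[-3, 3]; `wS` in [-5, 5]; `sigma` in [1e-3, 5] — generous for standardized
data), relative convergence tolerance about `2e-9` (`factr = 1e7`), ties
between restarts broken by first-found. The restart draws are a
prefix-stable function of the seed, so enlarging `n_restarts` can only
improve the maximized likelihood, and fits are bit-reproducible given
(data, seed, bounds, restarts). The inner trajectory recursions are
compiled (Rcpp); a task-design WI fit takes ~0.1 s.

## Group-level model selection

`rfx_bms()` implements random-effects Bayesian model selection from
per-participant log evidences (`-AIC/2`): a variational loop alternating
multinomial responsibilities with a Dirichlet update (`alpha0 = 1`,
tolerance `1e-6` on alpha, at most 500 iterations). Exceedance
probabilities use the exact regularized-incomplete-beta form for two models
and seeded Monte Carlo (1e6 Dirichlet draws) otherwise. The Bayes omnibus
risk compares the variational free energy against the equal-frequency null
(`F0 = sum_n log mean_k exp(lme_nk)`), and
`pxp = xp * (1 - bor) + bor / K`.

A consequence worth knowing: with few participants pxp has a hard ceiling
even under unanimous, infinitely strong evidence, because the omnibus risk
only decays like `exp(-N log 2)` against the Beta-function term — about
0.944 at N = 6, 0.98 at N = 10. Indecisive pxp at small N is the method
working as designed, not a fitting failure.

## Recovery harnesses

`model_recovery()` simulates datasets from each model, fits both to every
participant, and selects a dataset winner by pxp argmax on the summed
valence + arousal AICs (one model is assumed to generate both dimensions of
a dataset). Ties below `1e-6` are recorded and counted against recovery.
"Randomly selected parameters" is made concrete as uniform priors:
`beta, gamma ~ U(0.1, 0.9)`, `w0 ~ U(-0.5, 0.5)`, `wS ~ U(0.1, 1)`,
`x0 ~ U(-1, 1)`, `sigma ~ U(0.3, 1)` — spanning the range plausibly fitted
on standardized data while avoiding the degenerate boundaries.

`parameter_recovery()` reports true-versus-estimated scatter, correlation
and bias per parameter. The update weights recover sharply (correlation
above 0.9 at 76 ratings and `sigma = 0.5`); the WI initial state `x0` is
intrinsically weakly identified (its influence on the first observable
rating is attenuated by $(1-\beta)^4$), which is expected, not a defect.
Recovery accuracy improves from the 19-rating control design to the
76-rating task design.

The shipped checks run scaled-down problem sizes chosen as a sensible
desk-scale default: 10 datasets per model with 20 simulated participants for
model recovery, and 50 simulated participants for parameter recovery. At
these sizes the task-design confusion matrix is perfectly diagonal and the
control design misclassifies at most an occasional dataset, consistent with
the near-zero confusion expected at full scale.

## The lagged regression

`build_lag_design()` attaches to each rating the standardized norms of the
four images seen since the previous rating (`S_lag1` = most recent) and,
for task blocks, their relevance indicators. Valence models use valence
lags only and arousal models arousal lags only; relevance enters only
through affect x relevance interactions (no main effects — a relevance cue
carries no affective content by itself, so its main effect is not part of
the estimand).

`fit_lagged_model()` estimates fixed effects with participant-level random
intercepts and random slopes on every predictor via `lme4::lmer`. Two
choices the contract leaves open are resolved as: *diagonal*
random-effects covariance (correlations among nine random effects are far
outside what these data can support) and *ML* rather than REML (fits are
compared and simulated under a fixed fixed-effects structure). If the
mixed fit is singular or fails, the function falls back — and says so — to
a two-stage summary-statistics estimator (per-participant OLS, then the
across-participant mean with empirical covariance), which in this balanced
design agrees closely and is also exposed directly for simulation loops
where thousands of mixed fits would be wasteful. Post hoc coefficient
contrasts use Wald z tests on the coefficient covariance;
family-wise control uses Holm's step-down procedure.
`paired_ttest_sample_size()` reproduces the paradigm's a-priori power
computation via the noncentral t distribution (dz = 0.5, power 0.95,
alpha = 0.05, two-sided gives n = 54).

## Posterior-predictive validation

`validate_wi_model()` takes fitted per-participant WI parameters and noise
sds, simulates `n_sims` datasets on the *observed* schedules (relevance
assignments are reused, not regenerated — the question is whether the model
reproduces the regression pattern given the design actually run), analyses
each with the same lagged regression, and checks whether each observed
coefficient lies inside the central 95% of its simulated distribution. The
95% interval is a fixed convention; with `n_sims = 1` the interval
degenerates to a point and coverage to near-equality.

## Degenerate inputs and numerical conventions

* Zero-variance ratings: flagged for exclusion per participant-dimension
  rather than divided by zero; slider-based exclusion drops participants
  with more than 80% unmoved ratings on either scale, and all-unmoved
  control-block arousal excludes only the control-arousal fit.
* `0^0 = 1` in both the ED kernel and the WI closed form (the `gamma = 0`
  and `beta = 1` limits).
* Optimizer output is clamped to the box bounds to absorb floating-point
  round-off at the boundary.
* Every stochastic stage takes an explicit integer seed; the pipeline
  manifest records stage seeds and MD5 content hashes and contains no
  timestamps, so identical configurations produce byte-identical manifests.

## Limitations

Synthetic ratings are conditionally independent Gaussian deviations from
the latent trajectory; human rating noise is not. The models couple valence
and arousal only through the shared schedule, not dynamically. No
reaction-time or target-detection behaviour is modelled. And all recovery
and validation results certify the analysis under the generator's
assumptions — with real data, conclusions additionally rest on those
assumptions being adequate.
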