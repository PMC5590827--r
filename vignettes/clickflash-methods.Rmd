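---
title: "Models and methods behind clickflash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clickflash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clickflash)
```

## The scientific problem

When an observer hears a train of clicks and sees a train of flashes, should
the two streams be attributed to one physical source and integrated, or kept
separate? `clickflash` implements the computational machinery for studying
this question with stochastic audiovisual sequences: generating the stimuli,
extracting the temporal cues an observer could use for causal inference,
fitting psychophysical performance, and testing which integration strategy
and which cues best explain behaviour.

Everything runs on synthetic data. A pair of observer models — one for
rate discrimination, one for causality judgements — generates complete
datasets with the statistical structure the analyses assume, so every stage
of the pipeline is exercised and testable without any experimental data.

## Sequence generation

Two stochastic event-train generators are provided.

**Frame-triplet algorithm** (`generate_triplet_sequence()`). The 60-Hz frame
grid of a display is divided into triplets of 3 frames (50 ms). The number
of events is `round(rate × duration)`, and the event-bearing triplets are a
uniformly random subset (at most one event per triplet). Within a triplet
the event occupies one frame, chosen uniformly from the three positions —
except that when the preceding triplet also bears an event, the position is
copied from it. This guarantees at least two blank frames (≥ 33 ms) between
consecutive events while keeping inter-event intervals highly variable.

**Fixed-interval algorithm** (`generate_raposo_sequence()`). Inter-event
intervals are restricted to 60 or 120 ms; the integer mix `(n60, n120)` is
chosen to bring the mean interval as close as possible to `1000/rate`, and
the order of intervals is shuffled. This reproduces the much more regular
trains used in earlier rate-discrimination work, where temporal-conflict
trains were additionally offset by 20 ms between modalities so that no click
and flash ever coincide. The original description does not say where the
first event was placed; here it is drawn uniformly from the leading slack
left after the train's span is fixed (configurable via `start_ms`).

`generate_pair()` builds condition-specific pairs: without temporal conflict
both modalities share one draw; with conflict two independent draws are
made. Spatial conflict is metadata only — no acoustics or spatial model is
implemented. For the causality-judgement design, `generate_exp2_trial()`
regenerates any conflict pair whose maximum click-flash offset exceeds
200 ms (a rejection loop capped at 10,000 attempts), which concentrates the
stimulus set on temporally ambiguous pairs.

Comparison-stimulus durations are jittered by `jitter_duration()` on an
11-value grid (±250 ms in 50-ms steps) to dissociate counting from genuine
rate estimation.

## Temporal causal-inference cues

Three per-pair cues are extracted (`feature_table()`):

* **Proportion synchronous** — the fraction of events coded at identical
  times in both modalities (same frame for triplet trains, same onset for
  fixed-interval trains).
* **Maximum click-flash offset** — the largest distance from an event to
  the nearest event of the other modality. Three readings of "maximum offset
  between any sequential click and flash" are implemented:
  `"directional"` (each click to its nearest flash, maximum over clicks),
  `"symmetric"` (both directions; the Hausdorff distance), and
  `"sequential"` (largest adjacent cross-modal gap in the merged train).
  The directional reading is the default because it is the one that
  reproduces the published simulation statistic for the triplet generator
  at the standard stimulus settings (~18% of 8-events/s 2-s conflict pairs
  below the 103-ms boundary, vs ~4% and ~5% for the other two readings);
  the alternatives are kept selectable because the verbal definition is
  genuinely ambiguous.
* **Windowed pattern similarity** — the maximum of the normalized
  cross-correlogram within ±200 ms of lag.

The cross-correlogram (`normalized_xcorr()`) binarizes both trains on the
frame grid and, for each lag `m` from −1000 to +1000 ms at frame resolution,
takes the overlapping portions of the two trains, subtracts their means,
scales them to unit norm, and takes the dot product — i.e., the Pearson
correlation of the overlap, guaranteed to lie in [−1, 1]. Two conventions
are fixed once and used everywhere: positive lag means the auditory train is
delayed relative to the visual train, and a zero-variance overlap (e.g., an
empty segment) is assigned the neutral value 0.

## Psychometric model and sampler

Rate-discrimination responses are modelled with a cumulative Gaussian:
`P("faster") = Φ((x − μ)/σ)`, where `x` is the rate difference from the
8-events/s standard, `μ` is the point of subjective equality (PSE) and `σ`
the sensitivity threshold. Priors are flat: `μ ~ U(−7, 7)` and
`log σ ~ U(−2.3, 1.6)`; there is no lapse parameter.

`fit_psychometric()` samples the posterior with random-walk Metropolis on
`(μ, log σ)`. The proposal scale adapts toward ~30% acceptance during a
2000-iteration burn-in, after which 2000 thinned draws are retained
(thinning 5 by default). Point estimates are posterior means; intervals are
central 95% percentile intervals; a split-half potential-scale-reduction
diagnostic is recorded with each fit. The likelihood is evaluated on
response counts aggregated by stimulus level, so a fit costs milliseconds
and replicate studies (coverage, recovery) are cheap. Reproducibility is at
the level of a seeded chain: the same seed gives identical draws, but no
claim is made that any particular draw sequence matches other samplers —
posterior summaries are the unit of comparison.

Degenerate inputs are handled explicitly: fewer than two distinct stimulus
levels is an error; all-identical responses trigger a `fit-degenerate`
warning and the posterior concentrates at the prior bounds (step-like data
drive `σ` toward `e^{−2.3} ≈ 0.1`).

## Group-level pooling and splits

Raw data cannot be pooled across observers whose psychometric functions
differ, so `z_transform()` rescales each trial's stimulus level by its
cell's fitted parameters, `z = (x − μ̂)/σ̂`, putting all trials in
signal-to-noise units where every function has `μ = 0`, `σ = 1` (a pooled
refit of z-scored synthetic data recovers exactly that, within estimation
noise). Three split analyses then refit psychometric functions in SNR units
with the same priors:

* `split_fit_switch()` — trials preceded by the same vs a different
  modality condition (attention-switch cost).
* `split_fit_duration()` — short (−250 to −100 ms jitter) vs long (+100 to
  +250 ms) trials, omitting smaller jitters, plus a per-jitter-level PSE
  regression over the 11 durations. A counting observer (judging total
  events rather than rate) produces a negative PSE-vs-jitter slope; a pure
  rate observer a flat one. The synthetic observer's `counting_weight`
  mixes the two decision variables linearly, so both regimes are testable.
* `split_fit_causal()` — temporal-conflict trials split at the integration
  boundary of the causal-judgement model (common-likely: maximum offset at
  or below the boundary).

## Cue combination and model comparison

From the unisensory posteriors, `predict_best_cue()` selects the modality
with the smaller posterior-mean `σ` (ties broken deterministically toward
audition) — the best-cue prediction `σ²_best = min(σ²_A, σ²_V)` with that
modality's PSE. `predict_optimal()` propagates the optimal-integration
prediction `1/σ²_opt = 1/σ²_A + 1/σ²_V` by drawing independently from the
two sigma posteriors and applying the formula pairwise, giving a full
posterior for `σ_opt` (draw-wise always below both sources).

`classify_integration()` labels observed multisensory behaviour by 95%
credible-interval comparison, in this order: *optimal* (observed interval
overlaps the optimal prediction), *enhancement* (entirely below the
best-cue interval), *worse-than-best* (entirely above), *best-cue*
(overlaps best-cue but not optimal), else *suboptimal*. The original
report does not state its interval-comparison rule; overlap of 95% CIs was
chosen as the most conservative symmetric criterion and the rule order is
documented because it determines which label wins when several descriptions
apply (an interval strictly between the two predictions counts as
enhancement relative to the best cue).

For a group-level verdict, `model_evidence()` scores each subject's
multisensory responses under each fixed-parameter model (best-cue:
`μ = μ_best`, `σ = σ_best`; optimal: `μ = 0`, `σ = σ_opt` — the unbiased
PSE is deliberate, handicapping the optimal model rather than inventing a
bias theory). Because the parameters are fixed, the evidence is exactly the
Bernoulli likelihood; a posterior-averaged variant
(`model_evidence_posterior()`) is provided, with the plug-in point estimate
as the default. `rfx_bms()` then treats the model identity as a random
effect across subjects, fitting a Dirichlet over model frequencies by the
standard variational fixed-point iteration (uniform `α₀ = 1`, convergence
tolerance 1e-8 on the concentrations) and reporting exceedance
probabilities — exactly from the Beta CDF for two models, by Dirichlet
Monte Carlo otherwise.

## Cross-correlogram difference analysis

For causality-judgement data, `ccg_difference()` averages per-trial CCGs
within each response class, subtracts ("common" minus "different"), and
smooths with a Gaussian kernel of SD 80 ms, truncated at ±4 SD and
renormalized at the grid edges (the source description is silent on edge
handling; renormalization avoids shrinking the function toward zero at the
boundaries). Since class means are linear, subtract-then-smooth equals
smooth-then-subtract. `permutation_bounds()` shuffles response labels 1000
times (per-trial CCGs are computed once and cached; only labels move),
yielding pointwise 2.5/97.5-percentile null bounds and a signed
significance mask. Significance is deliberately pointwise and uncorrected,
matching the analysis it reproduces; because isolated flagged lags are
plausible Type I errors, run-lengths of consecutive significant lags are
also reported.

## The causal-judgement model

`fit_causal_glmm()` models "common source" judgements on temporal-conflict
trials as logistic in the proportion synchronous and the maximum offset (in
seconds), with a per-subject random intercept, estimated by maximum
likelihood with the Laplace approximation (via `lme4::glmer`). Covariates
are left uncentered and unscaled on purpose: with the reduced model
(intercept + offset), `−β₀/β_offset` is directly the offset at which
P(common) = 0.5 — the integration boundary, returned in ms by
`integration_boundary()`. With the published coefficients (intercept 1.76,
offset effect −17.00 per second) the boundary is 1760/17 ≈ 103.5 ms. The
boundary is computed from the reduced model by default because the sync and
interaction terms must be absent (or zero) for a pure offset-axis boundary;
the full model remains available for inference on all cues.

Inference is by parametric bootstrap (`bootstrap_pvalues()`): responses are
simulated from the fitted model, each replicate refit, and percentile
intervals (90% by default) formed per coefficient; the two-sided p-value is
the bootstrap tail probability of zero, floored at `1/(n_boot + 1)`.
Replicates whose refit fails are excluded and counted.

## Synthetic observers

`simulate_exp1_dataset()` draws, per trial, internal rate estimates
`r̂_m ~ N(rate + μ_m, σ²_m)` per modality and combines them by the
observer's strategy — reliability-weighted (optimal), lower-σ modality only
(best-cue), or a directly specified multisensory σ — responding "faster"
when the combined estimate exceeds the 8-events/s standard. The
`counting_weight` parameter mixes in a count-based decision variable
(events divided by the standard duration), reproducing duration-dependent
biases. The stimulus design is a fixed ±{0.5, 1, 2, 3, 4, 6} events/s grid
(method of constant stimuli): an adaptive stimulus-placement procedure is
out of scope, and a fixed grid exercises every fitting path. Standard
presentations requiring no response are not represented as trials;
`prev_modality` refers to the preceding comparison trial.

`simulate_exp2_dataset()` generates the canonical causality-judgement
design — per session, 75 temporal-conflict and 15 no-conflict trials at
each of 8, 10, 12, 14 events/s (360 trials), 2-s triplet sequences with the
200-ms rejection filter — extracts the cues, and draws responses from the
logistic model with per-subject random intercepts. Defaults follow the
published fit where it exists (intercept 1.76, offset −17 per second, zero
sync and interaction effects) and field-typical choices where it does not:
a random-intercept SD of 0.5 log-odds (moderate inter-subject variability)
and a 0.971 "common" rate on no-conflict trials (the reported group mean).

What the generator does *not* emulate: sensory adaptation, attention
lapses, learning across sessions, perceptual (as opposed to coded)
synchrony, and any spatial/acoustic structure. Passing tests therefore
demonstrate that the analysis code is correct under its own model
assumptions, not that those assumptions hold for real observers.

## Numerical and design choices

* Event counts use round-to-nearest of rate × duration (exact for the
  integer rates at 2 s); the same convention is applied to jittered
  durations.
* The fixed-interval generator errors when the train cannot fit the
  requested duration; rates outside `[1000/120, 1000/60]` use the nearest
  achievable all-120 or all-60 mix.
* MCMC settings (2000 burn-in, 2000 kept draws, thinning 5) are defaults,
  not dogma; tests use lighter settings where many replicate fits are
  needed. Replicate counts in the test suite (e.g., 100 coverage
  replicates at 2000 trials for the psychometric fit, 100 causal-model
  recovery replicates at 2400 trials, 30 permutation-calibration datasets)
  were chosen so the whole suite completes in a few minutes on one CPU
  while keeping binomial noise on the checked proportions well inside the
  asserted bounds.
* All stochastic entry points take an explicit `seed`; `run_pipeline()`
  derives deterministic per-stage substreams from one master seed, so each
  stage can be rerun in isolation and two runs with the same configuration
  are identical.

## Known limitations

* The psychometric model has no lapse rate; data from inattentive
  observers will inflate `σ` rather than be absorbed by an asymptote.
* Group-level fits in SNR units reuse the raw-scale prior ranges; after
  standardization these are effectively uninformative, but extremely large
  pooled datasets could in principle press against them.
* Exceedance probabilities are plain (not protected); with very few
  subjects they can look decisive under weak evidence, which is a known
  property of the method rather than a defect of the implementation.
* The "suboptimal" classification label is reachable only for interval
  configurations not covered by the preceding rules; with tight intervals
  the effective label set is optimal / enhancement / best-cue /
  worse-than-best.
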