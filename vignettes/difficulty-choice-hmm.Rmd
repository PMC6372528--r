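---
title: "Modeling difficulty choices in self-adapted tests with covariate-dependent HMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling difficulty choices in self-adapted tests with covariate-dependent HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sathmm)
```

## The problem

In a self-adapted test the examinee, not an algorithm, picks the difficulty
of every item. A 40-item test with seven difficulty levels therefore yields,
per participant, a sequence of 40 choices in 1..7 alongside answer
correctness (0/1, with feedback after each item) and a confidence rating
(0--100 in 10-point steps, the usual elicitation of feeling-of-knowing).
Participants are randomized to a goal framing — *performance* (maximize the
score, `d = 1`) or *learning* (use the test to learn, `d = 0`) — and bring a
pre-test proportion correct `p` from a separate non-adaptive test.

Raw choice sequences are strongly serially dependent: most participants
park at a preferred band of difficulty and move occasionally. The package
models that behavior with a hidden Markov model in which a small number of
latent *difficulty-preference states* drives the manifest choices, and the
dynamics of the latent chain — where you start and how you move — are
regressed on observed covariates.

## The model

Scaled choices `y_ij = level_ij / 7` are treated as conditionally
independent given a latent first-order Markov chain `S_ij` with `M` states:

* **Measurement model.** `y_ij | S_ij = m ~ N(mu_m, sigma_m^2)`. The
  seven-level choice is ordinal, but with seven approximately equally
  spaced categories the continuous treatment is the standard pragmatic
  choice (five-plus categories), and it keeps every parameter
  interpretable on the difficulty axis.
* **Initial-state model.** A multinomial logit:
  `P(S_i1 = m) = softmax_m(a_m + b_m' I_i)` with `I_i = (d, p, dp)` in the
  fullest specification.
* **Transition model.** One multinomial logit per origin state `l`:
  `P(S_ij = m | S_i,j-1 = l) = softmax_m(c_lm + d_lm' h_ij)` with
  `h_ij = (d, f, r, fr, df, dr, dfr)` in the fullest specification, where
  `r_ij` and `f_ij` are the *accumulated* correctness and confidence —
  running means of the per-item values — so the transition matrix varies
  by person and item.

One destination class per regression is a reference with its coefficient
column pinned to zero; probabilities are invariant to that choice. The
free-parameter count is `2M + (1+q_I)(M-1) + (1+q_h)M(M-1)`.

Six specifications form the comparison ladder: `A` (M = 2, intercepts
only), `B` (M = 3, intercepts only), `B1` (initial-state covariates
`d, p, dp`), and `B2a`/`B2b`/`B3` adding transition covariates `d` /
`f, r, fr` / all seven. Fits are compared by AIC, BIC and likelihood-ratio
tests along the nested chain B⊂B1, B1⊂B2a, B1⊂B2b, B2b⊂B3.

```{r ladder}
vapply(c("A", "B", "B1", "B2a", "B2b", "B3"),
       function(nm) count_params(model_def(nm)), integer(1))
```

### Accumulated covariates: two windows

The accumulated tracks are defined as the running mean "from the beginning
to item j". Read literally, the covariate entering the transition *into*
item j includes item j's own outcome. The package implements this
`inclusive` window as the default (fidelity to the definition) and
provides a `lagged` window (through item j−1) as a configuration option,
because the inclusive reading lets the current item's outcome inform the
transition that precedes its answer. Neither reading is asserted as the
original intent; transitions are only defined for j ≥ 2, so the lagged
track's undefined first value is never consumed. The synthetic-data
generator, by contrast, is necessarily causal: when generating item j the
only available history runs through item j−1, and that is what its
covariate-dependent transitions use.

The leakage is not hypothetical. Fitting the ladder under the inclusive
window to a cohort generated with *intercept-only* transitions, the
`f, r, fr` rung comes out likelihood-ratio significant while the
condition rungs correctly do not: the current item's own outcome — part of
the inclusive track — depends on the chosen level and hence on the current
state, so the covariate genuinely predicts it. Refitting the same cohort
under the `lagged` window cuts the statistic by about half (72.3 to 34.4
on 18 df in one run), though not to the null: correctness history remains
correlated with the level history, and posterior state assignments are
soft, so some association survives even without any generative covariate
effect. Comparisons of covariate effects should state which window they
were fitted under, and significant accumulated-outcome effects should be
read with this baseline in mind.

## Estimation

Parameters are estimated by EM:

* **E step.** A scaled forward–backward pass with per-item transition
  matrices returns state posteriors `gamma`, joint transition posteriors
  `xi`, and the exact marginal log-likelihood. Emission densities are
  rescaled by their per-observation maximum before the recursion, so
  underflow is impossible by construction even at the variance floor.
  All participants share the item count, so the recursions run vectorized
  across the cohort.
* **M step.** Emission means and SDs are `gamma`-weighted moments pooled
  over participants and items. The initial-state block is a weighted
  multinomial-logistic fit of the item-1 posteriors on `I`; each origin
  state's transition block is a weighted multinomial-logistic fit of its
  `xi` slab on `h`. With no covariates these fits reduce to closed-form
  normalized expected counts. The covariate fits are quasi-Newton (BFGS)
  with analytic gradients, warm-started from the previous outer iteration,
  and carry a tiny ridge (1e-6) on slope coefficients only — enough to
  keep quasi-separated quadrants (e.g. covariate corners with almost no
  posterior mass) finite without noticeably biasing estimates. The fit is
  cross-checked in the test suite against `nnet::multinom` on identical
  weighted problems.

Numerical choices, all of them package decisions where the source analysis
is silent:

* convergence when `|ΔlogLik| / (1 + |logLik|) < 1e-8`, at most 500 outer
  iterations;
* emission SD floor of 1e-3 on the scaled axis — constant choosers (a
  material share of real cohorts) would otherwise drive a state's variance
  to zero and the likelihood to infinity;
* deterministic initialization: emission means at the `(m - 0.5)/M`
  quantiles of pooled `y`, SDs at the pooled SD, all logit coefficients
  zero; optional restarts jitter the starting means with seed-controlled
  Gaussian noise (SD 0.08) and the best log-likelihood wins;
* the estimation reference class is state 1 in estimation order; reporting
  relabels states by ascending emission mean (the low/medium/high
  convention) via `relabel_states()`, which permutes every block and
  re-pins the reference by a probability-preserving column shift;
* Viterbi decoding breaks exact ties toward the lower state index.

The EM ascent property (outer log-likelihood non-decreasing to 1e-8) and
the equivalence of the forward pass and Viterbi with brute-force path
enumeration (M ≤ 3, T ≤ 6, tolerance 1e-9) are enforced as tests.

### Information criteria

`AIC = -2 logLik + 2k` and `BIC = -2 logLik + k log(n_obs)` with
`n_obs` the total number of item observations (participants × items;
23,320 at the study size). This observation count is the only choice that
makes the published BIC values consistent with the published
log-likelihoods and parameter counts across all six models — the
derivation is retained as a test rather than asserted. LRT p-values use
the naive chi-square reference, as in the original analysis; regularity
conditions for covariate tests in HMMs are asserted, not proven, and the
p-values should be read accordingly.

## Reference estimates and effect surfaces

The original study's data are not deposited. The package therefore embeds
the published fit indices and coefficient blocks (`reference_estimates()`,
printed to two decimals, states in ascending-mean order with the medium
class as the logit reference — the published reporting's convention, where
the estimation-order first class turned out to be the medium state).
Two reproducible surfaces rest on them:

* arithmetic closure: parameter counts, AIC, BIC and the LRT chain
  recomputed from the embedded log-likelihoods reproduce the published
  values to two decimals;
* effect-surface closure: `expected_transitions()` evaluates the embedded
  `B2b`/`B3` blocks at the extreme quadrants of the accumulated scales,
  `f, r ∈ {0, 1}` — the published description names the anchors ("all
  incorrect"/"all correct", lowest/highest confidence) without printing
  the evaluation points, so the exact corners are the package's
  assumption, and under it the reported quadrant percentages (66.1%,
  22.3%, 27.7%, 73.8%) are reproduced to a few tenths of a point, the
  attainable agreement given two-decimal coefficients.

```{r quadrants}
ref <- reference_estimates()
eff <- expected_transitions(ref$B2b$params, covariate_grid(f = c(0, 1), r = c(0, 1)))
subset(eff, f == 1 & r == 0 & from == "L", c(from, to, prob, stay, up, down))
```

One reported quantity is ambiguous: the 27.7% downward figure for the
high state at the over-confident corner could denote the total downward
mass or a single destination's probability. `expected_transitions()`
returns both (the `down` aggregate and the per-destination `prob`), and
the package's checks target the total-downward reading, which matches the
printed value.

## The synthetic cohort

`simulate_dataset()` generates cohorts with the statistical structure the
analysis assumes, replacing the non-public study data everywhere a test
needs data. Defaults are the study conditions: 583 participants × 40
items; Bernoulli(0.5) condition assignment; pre-test scores from a
truncated normal (mean 0.75, SD 0.16, range 0.22–1); a three-state
intercept-only generating chain with emission means (0.19, 0.51, 0.86),
SDs (0.07, 0.12, 0.13), initial probabilities (0.36, 0.45, 0.19) and
sticky transition rows with diagonal (0.93, 0.92, 0.90); per-level success
probabilities (92, 80, 68, 55, 41, 30, 16)%.

Channels the source does not specify generatively are package choices:

* **Correctness** depends on the *chosen level* and the pre-test score
  only — not on the latent state directly — mirroring a design where the
  item's difficulty determines success. The per-level success probability
  is shifted on the logit scale by `ability_slope × (pretest − 0.75)`,
  default slope 2, so the plausible pre-test range (±0.25 around its
  mean) moves success odds by about ±0.5 logits — individual differences
  that matter without overwhelming the level effect.
* **Confidence** is the simplest link achieving the reported
  confidence–correctness association: `clamp01(0.40 + 0.35·correct +
  N(0, 0.23))`, rounded to the 0.1 rating grid. The noise SD was
  calibrated once, by simulation at the default cohort size, so the pooled
  point-biserial correlation sits at 0.60; across seeds it lands in
  0.59–0.61. Negative level–correctness and level–confidence correlations
  then emerge from the monotone success table rather than being injected.
* **Discretization.** Continuous emissions are rounded to the nearest
  1/7 and clamped to [1/7, 1]. This deliberately mild misspecification
  matches the ordinality of real choices; for the default SDs it moves
  each state's mean by less than 0.01 (a tested property), and the
  recovery tolerances below absorb it.

What the generator does *not* emulate: goal-condition effects on the
latent dynamics (unless covariate slopes are switched on in the generating
parameters), day-two learning, feedback-condition manipulations, and the
real data's long constant runs at the manifest level — discretization
noise makes synthetic participants wiggle between adjacent levels more
than real constant choosers do, so manifest switch counts run higher than
in real cohorts even though the latent chain is equally sticky. Passing
recovery tests therefore demonstrate that the estimator recovers the
generating structure under the model's own assumptions plus realistic
discretization; they do not certify behavior under the unmodeled features
of real data.

Recovery, at the defaults and study size, is tested at: emission means
within ±0.02 of the generating values after ascending relabeling,
intercept-only transition diagonals within ±0.03, Viterbi decoding under
the true model above 85% state accuracy.

## Descriptives

`sequence_summary()` reproduces the standard sequence description:
pooled choice distribution, top-k exact sequences split by condition,
strict up/down manifest transition counts, pooled correlations
(point-biserial against correctness computed as Pearson with 0/1 coding),
and the average per-participant lag autocorrelation of residuals. For the
residual ACF the original analysis removed participant and item effects
with a generalized additive mixed model; this package substitutes two-way
fixed-effects demeaning (subtract participant and item means, add the
grand mean) — simpler, deterministic, and free of smoothing choices. The
documented consequence is that the real-data lag-1 value (≈0.44) is
context, not a target, for this pipeline. Constant choosers are excluded
from the ACF average with a warning: after item demeaning their residuals
merely mirror the item means and carry no within-person signal.

## Problem sizes and runtime

The test suite exercises full-size (583 × 40) cohorts only where the claim
is about study-size behavior (parameter recovery, generator calibration);
structural and property tests run on cohorts of 25–150 participants and
toy sequences short enough for exact enumeration (M ≤ 3, T ≤ 6), keeping
the default suite around a minute on one core. The covariate rungs of the
ladder on a full cohort take minutes each; `analysis/03_fit_ladder.R`
accepts a `--models` subset for quick passes.

## Known limitations

* No standard errors or confidence intervals for the HMM parameters (none
  are produced by the EM fit, matching the original reporting).
* No Bayesian estimation, higher-order or continuous-time chains, or
  multivariate emissions; state counts beyond 4 are configurable but
  untested.
* LRT p-values rely on asserted regularity conditions.
* The confidence channel is one admissible calibration, not a behavioral
  model of feeling-of-knowing; conclusions about confidence dynamics
  should not be read off the generator.
* Item counts must be equal across participants; incomplete sequences are
  rejected rather than imputed.
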