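---
title: "Modelling perceptual and value-based generalisation of aversive expectancies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perceptual and value-based generalisation of aversive expectancies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gengrad)
library(dplyr)
```

## The scientific problem

After learning that a particular stimulus (the conditioned stimulus, CS+)
predicts an aversive outcome, people also report elevated outcome
expectancies for stimuli that merely resemble it. Two mechanisms can produce
such a generalisation gradient and are behaviourally almost indistinguishable
at the level of averages:

* **perceptual generalisation** — the person sometimes *misidentifies* a
  generalisation stimulus (GS) as the CS+ and responds with the learned CS+
  expectancy; averaged over trials this yields a smooth, Gaussian-looking
  gradient even though each single rating is essentially binary;
* **value-based generalisation** — the learned value itself *transfers* to
  neighbouring stimuli as a graded function of similarity, so every single
  rating changes smoothly with distance from the CS+.

`gengrad` implements trial-level generative models of both mechanisms (plus
their combination), a censored-normal mixture likelihood with global
optimisation, BIC model comparison, the adaptive staircase used to
personalise the stimulus continuum, a synthetic-cohort generator, and the
model/parameter recovery protocols that establish when the models are
identifiable. The key empirical lever is the *trial-level response
distribution*: bimodal for misidentification, graded for value transfer.

## Stimulus space

The task uses a nine-item continuum of shapes parameterised by spikiness
`kappa` in (0, 1), with the CS+ of medium spikiness (`kappa = 0.5`) at the
centre and four GSs on each side, spaced by a step `delta_kappa` titrated
per person and condition. `build_space()` enforces the design invariants:
exactly 9 stimuli, uniform spacing, and `delta_kappa < 0.125` — a larger
step would push the endpoints out of the open interval (0, 1), which is also
the study's participant-exclusion rule. We reject the boundary value 0.125
itself (the printed rule excludes "> 0.125") because the endpoint shapes at
exactly `kappa = 0` and `1` are degenerate; this is a deliberate tightening.

All model distances are measured in integer stimulus-index units, not kappa
units: the titration equates the perceptual discriminability of neighbouring
stimuli, which makes index distance the psychologically uniform scale. The
likelihood therefore never depends on the personalised `delta_kappa`, only
on the 1..9 layout.

## The generative models

Let `v` be the participant's learned CS+ outcome expectancy (their final
learning-phase rating, fixed during fitting) and `d` the index distance of a
stimulus from the CS+.

**Value model.** The rating prediction is `y = alpha + v * G(d)` with a
kernel `G` of strength `lam` in (0, 10] and binary shape `omega`:
Gaussian-like `G = 2 / (1 + exp(d^2 / lam))` (`omega = 1`), or monotonic
(`omega = 0`), which reflects the Gaussian decay above 1 on the peak side
(`2 - G`) and keeps the decay on the other side, producing a strictly
monotone profile through 1 at the CS+. The upper bound of 10 on `lam` is
retained because larger values produce nearly identical flat profiles. The
offset `alpha` in [-1, 1] captures global over-/under-estimation.

**Perceptual model.** The shown stimulus `s` is perceived as some `q`;
ratings reflect the value of the *perceived* stimulus: `v + alpha` when
`q` is the CS+, `alpha` otherwise. The confusion table `P(q | s)`
(`misperception_matrix()`) honours both printed statements of the model:
the diagonal is `1 - rho`, and a GS is mistaken for the CS+ with probability
`rho^d` exactly. The confusion mass left over in a row is spread over the
remaining stimuli with the same distance weights. We note the printed
equations over-determine the row distribution (the literal entries need not
sum to 1), so some renormalisation choice is unavoidable; we anchored the
CS+ column because only `P(cs | s)` enters the perceptual likelihood — the
spread of the remainder matters only for the hybrid model. An alternative
reading that renormalises *all* off-diagonal mass with `rho^d` weights makes
CS+ confusions from near neighbours quadratically rare in `rho`, and in our
recovery experiments that reading leaves the confusion parameter poorly
identifiable (generative-recovered r plateaus near 0.45 regardless of
optimisation effort), while the CS+-anchored reading restores
identifiability; we consider that decisive.

**Hybrid model.** Value transfer *and* misidentification: the perceived
stimulus is drawn from the misperception row and the rating centres on the
value-model prediction at the perceived stimulus. With `rho = 0` it reduces
exactly to the value model; with `lam -> 0, alpha = 0` to the perceptual
model (both nestings are asserted numerically in the test suite).

## Observation stage and likelihood

Ratings come from a bounded 0-100% slider (rescaled to [0, 1]); a large
share of real ratings sit exactly at 0. We model the observation as a
**normal censored at 0 and 1** with free scale `sigma`: interior ratings get
the normal density, boundary ratings get the clipped tail mass. A censored
density accommodates exact zeros naturally, which a plain normal or a Beta
density cannot. For the perceptual and hybrid models the density is
marginalised over the perceived-stimulus mixture with a log-sum-exp guard.
Predictions are clamped to [0, 1] before the observation stage, since the
rating scale is bounded; `sigma` is a free parameter of every model and is
counted in the BIC parameter count.

`bic()` is `k * log(n) + 2 * nll` with `k = 3` (perceptual: `rho, alpha,
sigma`; value: `lam, alpha, sigma`) or `k = 4` (hybrid). The kernel-shape
switch `omega` is *not* counted: it is a model-structure label used to
classify gradients, not a continuously estimated quantity.

## Fitting protocol

`fit_gradient()` minimises the negative log likelihood of one
participant-condition block (36 trials: 9 stimuli x 4 repetitions) with the
DIRECT-L global optimisation algorithm over the bounded box, followed by
bounded L-BFGS-B polish from (i) the global solution, (ii) two deterministic
moment-based warm starts computed from the data, and (iii) `n_restarts - 1`
seeded random interior starts; the best restart wins. `lam` and `sigma` are
optimised in log space — both act multiplicatively and their basins near 0
are far wider on that scale. `sigma` is floored at 1e-3. The warm starts
matter because the mixture likelihood is multimodal and the clamping of
predictions creates flat plateaus (e.g. any `alpha <= 0` yields the same
zero-mean GS component); a start placed at the data-implied offset and noise
scale reliably escapes them.

Because a binary switch inside a continuous optimiser is ill-posed, `omega`
is enumerated: the Gaussian-like and monotonic variants are fitted
separately and the lower-NLL variant kept.

`compare_fits()` selects the winner by lowest BIC and reports the relative
model fit `BIC(perceptual) - BIC(value)` (positive favours value transfer).
BICs within 1e-6 are treated as tied — differences at that scale are
optimiser noise, and the models can mimic one another *exactly* (a
confusion-free perceptual dataset is indistinguishable from a collapsed
value kernel), in which case the tie goes to the more parsimonious model,
then to the fixed order perceptual, value, hybrid, with the tie flagged.

Pre-processing before fitting follows the study: gradients whose right-half
mean exceeds their left-half mean are flipped horizontally so monotonic
gradients peak left (the half-mean rule is our choice; the original
detection rule is not printed), and the monotonic kernel is canonically
left-peaking. An explicit `peak_side` argument supports unflipped pipelines.

## Titration staircase

The perceptual titration finds the `delta_kappa` at which two neighbouring
shapes are judged "different" at a target rate (60% or 80%). Only
different-trials move the staircase. The weighted up-down steps are not
printed in full; we chose them from the equilibrium condition
`p * step_down = (1 - p) * step_up` with the smaller step pinned to the
printed base step of 0.005 kappa units, giving 0.005 down / 0.020 up at the
80% target and 0.005 / 0.0075 at 60%. The expected drift then vanishes
exactly where P(correct | delta_kappa) equals the target, which the test
suite verifies against a long-run Monte-Carlo oracle (±2%). The starting
step defaults to 0.0625 (mid-range; the original is unstated) and the step
is floored at one base step. Target accuracy is interpreted as
different-trial accuracy, since the staircase adjusts only on those trials.
`check_inclusion()` applies the study's three participation criteria:
above-chance accuracy everywhere (point estimate > 50%; how "above chance"
was tested originally is unstated), a high-minus-low discriminability
accuracy gap above 10 points, and no condition ending with
`delta_kappa > 0.125`.

## Synthetic cohorts

`simulate_cohort()` generates the full study structure so that every
downstream stage is testable without participant data: per participant a
trait-anxiety score, a generalisation mechanism, a pattern, simulated
titrations per discriminability level, and 6 conditions x (24 learning + 36
generalisation) trials. The defaults *are* the study conditions:

* mechanism mix 84.76% value / 15.24% perceptual (the observed best-fit
  shares; no hybrid generators by default),
* 55.12% monotonic patterns among value generalisers, with 75% of
  participants keeping one pattern across all six conditions,
* learning blocks with exact reinforcement counts (24 x rr is integral for
  all design rates; a Bernoulli mode exists for off-design rates), with
  rating bias and noise chosen so cohort-mean final CS+ ratings land at the
  observed 0.31 / 0.54 / 0.77 for rr = 25/50/75% — the small positive biases
  (0.055, 0.04, 0.02) reproduce the observed overestimation, and the noise
  scales (0.18, 0.14, 0.11) the observed spread, after accounting for
  clamping at the slider bounds,
* trait anxiety floored at the questionnaire minimum of 21 with a
  right-skewed gamma tail (shape 1.4, scale 6), matching the observed mean
  near 29.3 and long upper tail,
* an anxiety-to-mechanism log-odds coupling (default 0.08 per anxiety point)
  calibrated once so that, at the study scale of 140 participants, the
  cohort-level correlation between trait anxiety and relative model fit
  lands near the observed r = 0.1.

Generative parameters are drawn uniformly from documented ranges
(`param_ranges()`: `lam` 0.1-8, `rho` 0.05-0.6, `alpha` -0.3-0.3, `sigma`
0.05-0.25). These stand in for the empirical 5th-95th percentile ranges of
fitted participant parameters, which are not published; every recovery
result below is conditional on these stand-ins, and they are configurable
should the empirical quantiles become available.

What the generator does *not* emulate: sequential effects within blocks,
attention lapses, slider anchoring habits, memory biases, or any
learning-induced perceptual change. Passing recovery tests therefore show
that the *models are identifiable from data generated by the models* under
study-sized designs — the essential precondition for interpreting fits —
not that real behaviour is exhausted by these two mechanisms.

## Recovery protocols

`model_recovery()` draws parameter sets per generating model, simulates one
36-trial block each (CS+ value sampled in [0.2, 0.9]), fits all candidate
models and classifies by lowest BIC; `parameter_recovery()` refits the
generating model and correlates generative with recovered values (Pearson
throughout; Spearman additionally for `lam`, whose effect on predictions is
strongly nonlinear). Both are deterministic given a seed. The default is a
fast mode (5 restarts); `scripts/acceptance.R` runs the full 30-restart
protocol at 120 datasets per model, the sizes used in the original
assessment.

Two structural degeneracies are worth knowing about. First, a perceptual
dataset in which no confusion happened to be sampled is *exactly*
reproducible by the value model with a collapsed kernel — the BIC tie rule
above handles this, and it is the main source of residual misclassification
at low `rho`. Second, under censoring the value model has a `lam`-`alpha`
ridge: a strongly negative offset clamps most of the gradient to 0 and
leaves the kernel width weakly determined. With the documented stand-in
ranges (noise up to 0.25, offsets down to -0.3, CS+ values down to 0.2)
this caps achievable parameter-recovery correlations: initialising the
optimiser *at the generative truth* yields r ~ 0.84 for `lam`, so values in
the low-to-mid 0.7s from honest blind fitting reflect an information limit
of the simulated data, not a search failure. The same reasoning cuts the
other way for model classification: the warm-started search separates the
two mechanisms *more* reliably for value-generated data than a plainer
multistart would, so recovery percentages move with optimiser quality, not
only with the data. Narrower, empirically derived parameter ranges would
raise the parameter-recovery ceilings.

## Gradient summaries

`gradient_auc()` integrates the 9-point mean gradient with the trapezoidal
rule (unit stimulus spacing). `flip_and_standardise()` implements the
pre-processing transform: after flipping, monotonic gradients have their
left-of-CS+ stimuli referenced to the condition CS+ mean. The printed
transform ("subtracting stimuli to the left of the CS+ from the mean CS+")
is implemented literally (`cs_mean - rating`); a plausible reflection
alternative (`2 * cs_mean - rating`) is available behind `method =
"reflect"` since the sentence is ambiguous. Min-max rescaling of ratings
within each reinforcement-rate condition (`rescale_condition()`) follows the
same literal reading of the pooling step. `classify_pattern()` labels value
fits by the fitted `omega`; `majority_pattern()` aggregates across the six
conditions with even splits reported as ties. `anxiety_association()`
computes the Pearson correlation of participant-mean relative fit with
trait anxiety and a seeded percentile bootstrap CI; inferential mixed-model
analyses are deliberately out of scope — the summary tables are written so
any statistics environment can consume them.

## Numerical choices, sizes and limitations

* Problem sizes: recovery runs use 120 datasets per model (30 restarts in
  the acceptance script, 5 in the fast default); the test suite exercises
  the full cohort pipeline at 140 participants with reduced restarts, and
  smaller cohorts elsewhere. These sizes keep a complete run in the minutes
  range on a single core.
* Determinism: every stochastic stage derives its own stream from one
  top-level seed (`derive_seed`); fitting never perturbs the caller's RNG
  state.
* Degenerate inputs: empty trial sets, out-of-range ratings, missing
  conditions and constant generative parameters raise informative errors or
  NA-with-warning (correlations).
* The hybrid model is excluded from default recovery (the original
  assessment recovered the two primary models); it can be added via the
  `models` argument.
* The binary-choice response model explored in the original supplementary
  analysis is not implemented (its form is unavailable), and trial-by-trial
  learning dynamics inside generalisation are deliberately absent (they fit
  worse in the original exploration and were excluded there).
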