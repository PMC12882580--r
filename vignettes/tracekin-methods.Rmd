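---
title: "Models and methods behind tracekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tracekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tracekin)
```

`tracekin` analyses stylus traces of closed shapes to quantify movement
differences between autistic (ASD), parkinsonian (PD) and control (CTRL)
adults. This vignette explains the models the package implements, the
choices made where the procedures admit more than one reasonable reading,
and what the synthetic-data generator does and does not emulate.

## Pure-frequency shapes

The four task shapes are members of the pure-frequency family: curves
whose log-curvature is sinusoidal in the heading (tangent) angle θ,

$$\kappa(\theta) = \kappa_0\,\exp\big(\varepsilon\,\sin(\nu\theta)\big),$$

where the angular frequency ν = p/q (in lowest terms) counts curvature
oscillations per 2π of angular displacement: 4/5 for the clover, 4/3 for
the petals, 2 for the ellipse, 4 for the rounded square. Position follows
by integrating dx/dθ = cos θ / κ, dy/dθ = sin θ / κ over θ ∈ [0, 2πq];
because the Fourier spectrum of exp(ε sin νθ) contains only multiples of
p/q, and q/p is non-integral for all four shapes, the closure integrals
vanish analytically and the generated curve closes up to quadrature error.
The integrator is a fixed-step fourth-order scheme (for a state-independent
right-hand side it reduces to composite Simpson quadrature) with at least
2048 steps per 2π. Residual drift — typically below 10⁻⁹ of the
perimeter — is removed by a per-point translation growing linearly in θ
whose total magnitude equals the endpoint gap; the curve is then uniformly
rescaled so its larger bounding-box dimension equals the size cap
(9 cm at the reference device scale of 8.83 px/mm, i.e. 795 px).

**Oscillation amplitudes.** The task literature fixes the frequencies but
not the amplitudes ε. The defaults (clover 1.2, petals 1.0, ellipse 0.7,
rounded square 0.8) were chosen once so the rendered shapes are clearly
differentiated and inflection-free; every quantitative check in the
package is amplitude-insensitive (the oscillation count, closure, and
scale equivariance hold for any ε > 0).

**Winding.** A closed pure-frequency curve with ν = p/q has tangent
rotation index q: the clover's heading turns five times before the curve
closes, and the lobes of the clover and petals are genuine loops. About
its own centroid, however, each curve winds a net ±1 once the loops are
accounted for (the petals wind clockwise even though the heading advances
counter-clockwise). The package therefore counts completed traces as the
unwrapped polar angle about the centroid divided by 2π times the curve's
own winding number, so "one trace = 2π" holds for every shape and
direction conventions stay consistent.

## Trial simulation

The generator is the minimal model under which the downstream estimators
are unbiased: target speed follows the speed–curvature power law
v(s) = c·κ(s)^(−β) with the normalisation c set so the time-averaged
speed equals the profile's base speed. Three perturbations are layered on
top:

* a slow multiplicative speed noise (log-scale SD 0.08, correlation time
  1 s) representing drifts in effort and attention;
* a **sub-movement perturbation**: Ornstein–Uhlenbeck-style band-limited
  multiplicative noise with a 150 ms correlation time, scaled by the
  group's `submovement_gain`. Its sample-path roughness is what produces
  intermittent acceleration sign changes;
* a spatial tracing error: an offset along the curve normal built from
  Gaussian-kernel-smoothed white noise (SD 4 px, correlation length
  150 px). Smoothness matters here: an OU offset of the same amplitude
  carries fine-scale roughness whose own curvature rivals the shape's and
  attenuates the speed-modulation estimate several-fold, which is a
  measurement artefact, not a behavioural signal. The kernel-smoothed
  process adds negligible curvature of its own.

Timestamps are produced by integrating ds/v and sampling near 60 Hz with
2 ms jitter. Trials whose offset crosses the deviation boundary (15% of
the larger shape dimension) are marked unsuccessful, mirroring the task's
online failure rule.

Scheduling follows the printed design exactly: eight blocks per day, two
per shape in random order, up to seven attempts per block until four
successes, hence at most eight successful trials per shape per day.
Reaction times are shifted lognormals (shift 0.44/0.50/0.45 s for
ASD/PD/CTRL, log-SD 0.35); the shift ordering encodes the qualitative
ASD < PD finding and is a calibration knob, not a reproduced quantity.
Questionnaire scores and ages are zero-truncated normals with the
published group means and SDs; gender labels match the published counts.

**Sub-movement calibration.** The percentage of acceleration sign changes
is invariant to the amplitude of a dominating perturbation (scaling a
zero-mean process does not move its zero crossings), so the measure
saturates in `submovement_gain`. The default perturbation SD (0.06) was
chosen so the three group gains (CTRL 0.9, PD 1.0, ASD 1.3) sit in the
responsive part of the curve; the vignette's advice to anyone
recalibrating is to check monotonicity of the group means over a gain
grid, which the test suite does.

## Preprocessing

Rules applied per trial, in order: trace counting on the raw samples
(unwrapped centroid angle, winding-normalized), removal of trials with
fewer than 2.5 traces, of trials never reaching 200 px/s within the 5 s
grace period, of timeouts (90 s) and acquisition-marked lifts; then the
first π/2 of angular displacement is discounted — implemented as a
time-prefix cut (later samples are never removed even when a loop of the
shape makes the angle dip transiently below the threshold); finally
natural cubic-spline resampling of x(t), y(t) onto a uniform 60 Hz grid,
with duplicate timestamps averaged first. Trace counting happens before
the angular trim, so the 2.5-trace rule sees the full trial.

## Kinematic features

Differentiation uses a least-squares local-polynomial (Savitzky–Golay)
derivative filter, window 11 samples (≈183 ms at 60 Hz), polynomial
order 3, applied stage-wise: velocity components from position, signed
tangential acceleration a = dv/dt from speed, jerk from acceleration, and
component accelerations for the curvature κ = |vₓa_y − v_y aₓ|/v³.
Samples within three half-windows of either end are flagged and excluded
from aggregation. Sub-movements use the signed tangential acceleration
(alternation between acceleration and deceleration), with zeros
inheriting the preceding sign; accelerations below 10⁻³ × mean speed per
second are treated as exact zeros so a constant-speed trace scores 0%
rather than counting numerical ripple (the deadband is ~100× below
physiological accelerations and scales with the trajectory, preserving
scale invariance).

The speed-modulation regression smooths v and κ (same filter class),
discards speeds below their 1st percentile and curvatures outside
[10⁻⁴, 1] px⁻¹ (guarding the log transform), and reports |slope| of
log v on log κ; fits with fewer than 50 retained points are flagged
unreliable and propagate as missing. Curvature comes from the traced
trajectory, not the ideal shape, as in the established regression
procedure for this task family.

SPARC is computed per repeated sub-element because its value grows with
trajectory length and is only comparable across identical movements. The
trial is split at the ideal curve's curvature maxima — p elements per
traversal — located on the trace through the nearest-point mapping; the
unwrapped arc position is passed through a running median (31 samples) so
transient flips of the mapping between overlapping windings of the
looped shapes shed only short fragments instead of corrupting the split.
Elements shorter than 0.25 s are skipped. Per element the speed profile
is zero-padded (pad level 4), the magnitude spectrum normalized by its DC
value, truncated at an adaptive cutoff (amplitude threshold 0.05 within a
20 Hz cap), and the negative arc length of the normalized spectrum
returned; element values are averaged. Cutoff and threshold are the
standard published defaults for the measure.

Per-trial speed, acceleration and jerk summaries are means of v, |a|,
|j| over retained samples (the aggregator is not specified by the task
literature; means with absolute values avoid signed cancellation).
Minimum and maximum speed are the means of the bottom and top deciles of
log speed with decile size ⌈0.1N⌉.

## Statistics

Outlier screening pools one mean and SD per feature over all trials of
all participants and removes values beyond 2 SDs (population SD — the
rule is a fixed-threshold filter, not an inference). Speed, acceleration
and jerk are log-transformed, minimum speed reciprocal-transformed, and
all features z-scored over retained rows before modelling. Reaction-time
outliers are removed within participant, matching the construction of the
participant-level score.

The mixed models are effects-coded (sum-to-zero contrasts for group and
shape), fit by REML, with random intercepts for day, trial number and
participant; the reaction-time variant omits shape and the trial-number
intercept, and the single-day switch drops the day intercept. Term tests
are Type-III F tests with Satterthwaite denominator degrees of freedom
(the marginal hypotheses that "effects-coded" plus per-term ANOVA
implies); confidence intervals are Wald. Singular random-effect variances
are retained at the boundary and flagged. When a random factor has as
many levels as observations (single-day reaction times), the model
degrades to ordinary least squares with marginal F tests rather than
failing.

Follow-up contrasts run only when the omnibus group main effect or
group-by-shape interaction is significant at α = .05 (uncorrected, as
reported; multiplicity is a documented limitation): each group pair is
refit as a two-group model, and pairwise interactions are decomposed into
per-shape two-group models. Bayes factors for null group effects use the
BIC approximation, BF₀₁ = exp((BIC₊group − BIC₋group)/2), on models fit
by maximum likelihood (REML likelihoods are not comparable across fixed
effects) after residualizing the DV on age, depression and anxiety; the
method tag records the approximation, and numerical agreement with
JZS-prior Bayesian ANOVAs is not claimed.

## Classification

The participant table averages each feature per shape over trials and
days (9 features × 4 shapes + mean reaction time = 37 kinematic columns),
imputes wholly missing cells with the pooled column mean (logged), and
residualizes every kinematic and questionnaire column on age, depression
and anxiety. The discriminatory-feature rule is a pure function of the
contrast report: a significant pairwise main effect contributes the DV on
all four shapes, an interaction-only effect contributes the specific
significant shapes, and the clinical-vs-non-clinical selection is the
union of the two control contrasts. Classification uses a stratified
80/20 participant split (unstratified splits at n ≈ 30 per class are
frequently degenerate), predictors standardized on training statistics,
KNN with k ∈ 1..10 tuned by 5-fold cross-validation on the training
portion, a random forest with the tree count ∈ {100..500} selected on
out-of-bag accuracy (the forest's internal validation), and a
linear-kernel SVM at unit cost. A single split is reported per seed, as
in the original procedure; accuracies from one small split carry
substantial seed-to-seed variance, which is why the tests assert only
separability, chance behaviour and grid structure, never specific
accuracies.

## What the generator does and does not emulate

The synthetic cohort reproduces the statistical structure the analysis
assumes — power-law speed control with group-dependent exponents,
band-limited sub-movement intermittency, smooth spatial error, shifted
lognormal reaction times, published questionnaire marginals and group
sizes (31/32/31, two days) — and is byte-deterministic under a fixed
seed. It does not emulate biomechanics (no arm model, no tremor
oscillation), practice or fatigue trends beyond random day/trial
intercepts, correlations between questionnaires within participant
(marginals only, a correlation matrix is accepted), or ON-medication
states. Passing tests therefore demonstrate that the estimators and
models recover the structure they assume, not that real clinical data
satisfy that structure.

## Problem sizes and numerical notes

The test suite runs simulations at reduced scale chosen as the smallest
sizes at which the properties under test are stable: cohorts of 6 per
group, one day, 3 cycles per trial for pipeline checks; 20 seeded
replicates of 5+5 participants for exponent-separation power; 200
feature-level replicates of 8 per group for the 5% ± 3 pp Type-I
calibration of the group test; 50 label permutations for classifier
chance behaviour. Curves are generated at 256–512 samples per cycle
(nearest-point queries refine the nearest vertex against its adjacent
segments, so densities above ~256/cycle change distances by far less than
a pixel). The speed-modulation tolerance of 5% on noiseless recovery
absorbs the bias of the Savitzky–Golay stages at 60 Hz; the estimator is
exact to three decimals on the ellipse and rounded square and within a
percent on the looped shapes.

## Known limitations

Uncorrected follow-up contrasts; BIC Bayes factors approximate (they
asymptotically favour the null more readily than JZS priors at these
sample sizes); the nearest-point mapping on looped shapes relies on a
running-median repair rather than a global correspondence; the single
80/20 split reports seed-dependent accuracies by design; and the
generator's group parameters are calibration knobs expressing qualitative
orderings, not estimates of real effect sizes.
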