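---
title: "Methods: from respirometry traces and telemetry tracks to repeatability models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from respirometry traces and telemetry tracks to repeatability models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldscope)
```

`fieldscope` chains five analyses that are usually scattered across lab
notebooks and ad-hoc scripts: extraction of metabolic phenotypes from
intermittent-flow respirometry, morphometric and multivariate phenotype
summaries, behavioural-state classification of telemetry tracks, daily
activity metrics, and heteroscedastic random-intercept models of
repeatability. This vignette documents the models, their assumptions, the
defaults and the numerical choices, and what the synthetic-data validation
does and does not demonstrate.

## Respirometry

### Model

Intermittent-flow respirometry alternates flush phases (the chamber is
re-oxygenated) with closed measure phases in which oxygen partial pressure
declines. Within each measure phase the package fits an ordinary
least-squares line of O2 (kPa) on time (h); the decline rate `K`
(sign-flipped to be positive) converts to mass-specific uptake through

$$\dot M_{O_2} = K \, V \, \beta \, M^{-1},$$

with `V` the chamber volume minus the fish's volume (litres; the fish is
assumed neutrally buoyant at density 1 g ml⁻¹, so a 54 g fish displaces
0.054 l), `β` the oxygen solubility at the working temperature
(0.4755 mg O2 l⁻¹ kPa⁻¹ at 16 °C) and `M` the body mass in kg. Background
(microbial) respiration is handled as a constant blank slope subtracted
from every cycle's `K`; time-varying microbial growth is out of scope, so
blanks should bracket the trial in practice.

Assumptions: the chamber is well mixed after a short transient (a
configurable leading clip, default 30 s, is discarded from each phase);
the decline is linear within a phase (checked by the per-cycle r², with
cycles below 0.90 rejected outright rather than re-fit — the filter is
treated as quality control, not as a model-selection step).

### Trait definitions

From the per-cycle uptake series spanning ~22 h after an exhaustive chase:

* **SMR** — mean of the cycles at or below the 10th percentile of all
  retained values (percentile by linear interpolation, type-7; membership
  is `mo2 ≤ q10`, which guarantees a non-empty set). The percentile
  parameter is exposed; SMR is non-decreasing in it by construction.
* **MMR** — the highest of the first three post-chase measurements
  (measurement starts within seconds of the chase). "Three consecutive"
  admits a second reading — the best three-cycle rolling window across the
  whole trace — which is available as `mmr_mode = "sliding3"` (the rolling
  *mean* of three, so the two modes answer slightly different questions);
  the default follows the immediate-post-chase intent. If fewer than three
  retained cycles fall in the first hour, MMR is reported missing rather
  than fabricated from later cycles.
* **AMS** — `MMR − SMR`, an exact identity maintained by construction.
* **Recovery rate** — OLS slope of uptake on time over the first five
  retained cycles (negative during recovery); missing with fewer than five.
* **Average / variability** — mean and SD over the final 19 h.
* **Routine, spontaneous min/max, spontaneous scope** — over the final 4 h.

All trailing windows are anchored at the last retained cycle, so a trace
slightly shorter or longer than 22 h keeps its windows aligned with the end
of confinement. The SMR percentile is taken over the full trace including
the recovery hours, following the protocol's "all measurements within the
22 h" reading; early post-chase cycles are far above the 10th percentile,
so their inclusion is immaterial in practice.

## Phenotype summaries

Fineness ratio is `FL / maximal body depth`. Metabolic rates scale
allometrically with body mass, so traits are log10-transformed and
regressed on log10 mass across the cohort; the per-fish residuals are the
mass-independent phenotypes used downstream. Recovery rate (a slope, not a
level) and metabolic variability are left uncorrected. The seven secondary
traits — recovery, 19 h average, variability, routine, spontaneous
min/max, spontaneous scope, with the five level-type ones mass-corrected —
enter a PCA on the correlation matrix (centred, unit sample-SD scaling,
n−1). Axes are ordered by eigenvalue; signs are fixed so each axis's
largest-magnitude loading is positive (signs are otherwise arbitrary and
not comparable across data sets). Fish with any missing trait are dropped
listwise with a warning — the simplest defensible rule at these sample
sizes.

## Behavioural states from step lengths

The telemetry system yields fixes every 30 s with ~0.2 m positional noise.
Speed-type metrics must only use fixes where the fish was actually moving,
otherwise noise masquerades as swimming. The package classifies each fix
with a two-state hidden Markov model on step lengths:

* **Inactive** — the true displacement is zero, so the observed step is
  the distance between two independent isotropic Gaussian position errors:
  Rayleigh with scale `σ_noise · √2`. `σ_noise` can be estimated or held
  at a known system precision.
* **Active** — gamma-distributed step lengths (shape and scale free).

This is deliberately the smallest model that produces the required
posterior activity probability; it conditions on neither turning angles
nor location, and continuous-time formulations and joint location-state
smoothing are out of scope. Estimation is EM (Baum–Welch) with scaled
forward–backward recursions in compiled code; the log-likelihood ascends
monotonically and the recursions are validated in the test suite against
brute-force enumeration of all state paths on short chains. Five seeded
random restarts (default) blunt local optima; the fitted states are
canonicalized so "active" is the larger-mean-step state. Gaps longer than
twice the burst interval split the series into independent segments — no
imputation. A fix's `p_active` is that of the step it initiates, matching
the pair convention of the speed filter.

## Activity metrics

Days are midnight-anchored 24 h blocks by default (`day_anchor =
"release_time"` is available); timestamps are treated as seconds since a
midnight epoch. After dropping the first 7 days post-release and keeping
the next 12 (closed lower, open upper bound):

* `A_day` — sum of consecutive Euclidean distances within the day. With
  0.2 m noise at 30 s this estimator is positively biased (noise adds in
  quadrature to every step); the bias is a property of the definition and
  is documented, not corrected.
* `U_inst` — distance/time over consecutive pairs at the full temporal
  resolution only (Δt within ±1 s of the burst interval, a tolerance for
  real-system jitter), retained when the first fix's `p_active ≥ 0.75`
  (closed threshold).
* `U_max` — the daily maximum of retained `U_inst`; missing if none.
  Pairs straddling midnight belong to the day of their first fix.
* `AR_day` — area of the 0.5 m buffer around the day's polyline, with
  self-overlaps merged. Merging is within-day; `AR_day` is a per-24 h
  quantity, so cross-day merging would change its meaning.

`AR_day` is computed without any polygon boolean machinery: the buffer is
exactly the sub-level set `{p : d(p, track) ≤ r}` of the distance-to-
polyline field, and its area is integrated by an adaptive quadtree —
square cells whose centre distance proves them entirely inside or outside
are resolved exactly, and only boundary cells are refined (to r/512 for
short tracks, r/64 for long daily tracks, where boundary-cell
misclassification cancels). This avoids arc discretisation entirely; the
test suite bounds the result against the closed-form stadium area and a
10⁶-point Monte-Carlo oracle.

## Repeatability models

Each activity measure `y` (with `U_inst` transformed as `log(y + 0.1)` to
tame its right skew and zero floor) is modelled as

$$y_{ij} = \alpha + \beta_{FL}\,FL_j + \beta_X\,X_j + a_j + \varepsilon_{ij},
\qquad a_j \sim N(0, \sigma_a^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_j^2),$$

with a residual variance per fish `j` — fish differ not only in level but
in day-to-day consistency, and a common residual variance would both
misweight fish and force a single repeatability. The likelihood is
maximized numerically over the log-scale variance parameters
(L-BFGS-B, three seeded starts), with the fixed effects profiled out by
generalized least squares at every evaluation; per-fish blocks are handled
by Woodbury-style closed forms, so evaluations are O(n). REML is used for
reported estimates, ML for likelihood-ratio tests — mixing the two would
invalidate the tests, and REML likelihoods of models differing in fixed
effects are not comparable. `σ_a` may hit its lower boundary (~0); this is
reported, not treated as an error. Fish with a single observation are
allowed but flagged, since their `σ_j` is weakly identified.

Model selection fits, per measure, the intercept-only model M0, M1
(+fork length) and M1a–g (+FL + one candidate: FR, SMR, MMR, AMS,
MET1–3 — one at a time, since the candidates are correlated), compares
them by AIC and by χ²(1) likelihood-ratio tests, and refits the AIC-best
model with REML. The AIC parameter count includes all `J` residual SDs
plus `σ_a` plus the fixed effects; conventions differ on counting variance
parameters, so AIC *differences between variance structures* should not be
compared across software. Repeatability is the per-fish intraclass
correlation `ICC_j = σ_a²/(σ_a² + σ_j²)`, summarized by median and range.

The equal-variance restriction of the same code path is verified in the
tests against the closed-form balanced one-way ANOVA solutions and against
an independent mixed-model implementation (`nlme::lme` with a per-fish
variance function); the heteroscedastic fit itself is this package's own.

## The synthetic cohort: what it emulates, and what it does not

The generator is a first-class module, and its defaults are the study
conditions every validation runs under: ~23 fish (body mass 54.2 ± 15.3 g,
fork length 16.4 ± 1.4 cm, fineness ratio 5.9 ± 0.3), true SMR and MMR
centred at 79.0 and 392.8 mg O2 kg⁻¹ h⁻¹ with the observed cohort SDs and
a mild mass-scaling exponent (−0.2 on mass-specific rates, i.e. 0.8
whole-animal), 22 h traces at 16 °C, and 19 days of 30 s fixes in a 1 ha
lake with 0.2 m noise. Choices the protocol leaves open were fixed once at
field-realistic values: 300 s flush / 600 s measure cadence; a 1 h
post-chase recovery half-life; additive lognormal spontaneous-activity
excursions (median 10% of SMR) that ramp in with recovery — an exhausted
fish cannot stack spontaneous activity on its maximum — and carry an
optional diel modulation so "stable low overnight uptake" has an analogue;
O2 sampled every 5 s (1 Hz in the original hardware; the tests use coarser
sampling for speed, and the slope estimator is insensitive to this);
a two-state switching walk (gamma steps, wrapped-normal turns, specular
boundary reflection) with mean active speed 0.25 m s⁻¹ and switching
probabilities 0.02 (to active) and 0.10 (to inactive) per 30 s step,
giving a ~17% stationary activity rate; 5% independent fix dropout.

Within each measure phase the generator emits a *linear* O2 decline whose
slope inverts the uptake equation at that cycle's true mean rate — which
is exactly the quantity slope-based respirometry estimates, and what makes
the noise-free round trip an identity. Real traces curve within phases,
carry drift and spikes, and violate linearity in ways the r² filter only
partially catches. Likewise the movement model has no home ranges, no
schooling, no habitat preference, and its active/inactive dichotomy is the
same structure the HMM assumes. Passing the round-trip and recovery tests
therefore demonstrates the *estimators* are correct and well-calibrated
under the design conditions — not that the models are adequate for any
particular field system.

## Numerical choices and degenerate inputs

* Percentiles: type-7 (linear interpolation); SMR set membership closed.
* Flat measure phases (zero variance) get r² = 0 and fall to the filter;
  phases shorter than 3 samples are skipped with a warning.
* A blank slope exceeding a cycle's decline clamps uptake at 0 (warning).
* EM stops at relative log-likelihood change < 1e-8 or 500 iterations;
  step lengths are floored at 1 nm so zero displacements cannot produce
  −∞ gamma log-densities.
* The gamma-shape M-step solves its score equation by Newton iteration
  with a Stirling-based start.
* Variance parameters are bounded in log space (σ ≥ 1e-6·sd(y)) with the
  random-intercept SD allowed down to 1e-8·sd(y) for boundary fits; a
  constant response short-circuits to the degenerate solution.
* All generators derive per-fish sub-seeds from the master seed (32-bit
  safe), so cohorts are bit-reproducible and individual fish can be
  regenerated in isolation.

## Validation scale

The test suite validates at reduced problem sizes chosen to exercise every
code path with tight oracles: cohorts of 4–50 fish, 1–4 day tracks,
10 s O2 sampling, 200-replicate operating-characteristic simulations for
the mixed model (coverage of `β_FL`, type-I error of the null-covariate
LRT) and 10–12 replicate ICC-recovery runs. `scripts/acceptance.R` runs
the full default design (23 fish, 19-day tracks, 16 analysed). These sizes
are the package's validation design; the estimators themselves have no
built-in scale limits beyond memory and patience.

## Known limitations

* Background respiration is a constant; growing microbial load biases late
  cycles upward (SMR is taken over the whole trace and is exposed to this).
* The HMM ignores turning angles and location; slow directed drift below
  the noise floor is classified inactive.
* `A_day` inherits the positive noise bias of summed noisy steps.
* Per-fish residual variances make the AIC parameter count grow with the
  number of fish; with few days per fish, `σ_j` estimates are noisy and
  the per-fish ICC range is wide — a faithful property of the design, not
  an artifact.
* The LRT χ²(1) reference is asymptotic; at 16 fish it is adequate for
  fish-level covariates (verified by simulation) but would be liberal for
  variance-component tests, which the package does not perform.
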