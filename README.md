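# fieldscope

Linking laboratory metabolic phenotypes to in-situ fish activity.

`fieldscope` implements, as one tested R pipeline, the analysis chain used in
lab-to-field studies of fish ecophysiology: individual metabolic phenotypes
are measured by intermittent-flow respirometry in the laboratory, the fish
are released and followed by high-resolution acoustic telemetry, and mixed
models ask whether the laboratory phenotype predicts activity in the wild.
It is aimed at movement ecologists and ecophysiologists who want each stage
— trait extraction, behavioural-state classification, activity metrics and
the repeatability models — as reusable, testable functions rather than a
one-off script.

## What it computes

**Respirometry.** Oxygen partial pressure declines while the chamber is
closed; each measure phase yields an uptake estimate via

    MO2 = K · V · β / M

with `K` the background-corrected linear decline rate (kPa h⁻¹), `V` the
chamber volume corrected for fish volume (l), `β` the oxygen solubility
(0.4755 mg O2 l⁻¹ kPa⁻¹) and `M` the body mass (kg). Cycles with r² < 0.90
are rejected. From a 22 h post-chase trace the package derives the standard
metabolic rate (SMR, mean of the lowest-decile uptake values), maximal
metabolic rate (MMR, highest of the first three post-chase measurements),
aerobic scope (AMS = MMR − SMR) and seven secondary traits (recovery slope,
19 h mean and SD, 4 h routine mean, spontaneous min/max and spontaneous
scope).

**Phenotype.** Fineness ratio FR = fork length / maximal body depth;
mass-independent trait residuals from log10–log10 OLS regressions on body
mass; a centred, unit-variance PCA reducing the seven secondary traits to
three axes (MET1–MET3).

**Telemetry.** From 30 s burst-interval position fixes (0.2 m noise): a
two-state hidden Markov model on step lengths (Rayleigh noise state vs
gamma active state, EM/forward–backward in compiled code) yields a per-fix
activity probability `p_active`; daily distance `A_day`, instantaneous
speeds `U_inst` (full-resolution pairs with `p_active ≥ 0.75` only), daily
maximum speed `U_max`, and daily covered area `AR_day` (merged 0.5 m buffer
around the daily track, computed by adaptive integration of the
distance-to-track field). The first 7 days after release are discarded and
the following 12 days analysed.

**Mixed models.** For each activity measure, random-intercept models
`y_ij = α + β·FL_j + β·X_j + a_j + ε_ij` with `a_j ~ N(0, σ_a²)` and
fish-specific residual variances `ε_ij ~ N(0, σ_j²)`, fitted by ML/REML
with fixed effects profiled out by GLS. AIC and likelihood-ratio tests
compare nested candidate models; repeatability is reported per fish as
`ICC_j = σ_a² / (σ_a² + σ_j²)`.

**Synthetic cohort.** Because the original field data are not public, a
first-class generator simulates the whole study design (cohort phenotypes,
raw O2 traces, two-state movement tracks with known hidden states) so every
stage can be validated against known ground truth.

## Worked example

```r
library(fieldscope)

cfg <- sim_config(n_fish = 4, seed = 42, n_days_track = 2, sample_period = 10)
cohort <- generate_cohort(cfg)

trace  <- simulate_respirometry_trace(cohort[1, ], cfg)
traits <- trace_traits(trace)
round(as.data.frame(traits)[, c("smr", "mmr", "ams")], 1)
#>   smr   mmr   ams
#> 1  68 376.8 308.8
cohort$true_smr[1]  # ground truth the trace was generated from
#> [1] 66.28844

track <- simulate_track(cohort[1, ], cfg)
steps <- track_steps(track, cfg$burst_interval)
fit   <- fit_activity_hmm(steps$steps, steps$seg_start, seed = 1)
fit
#> <hmm_fit> loglik -892.832 after 14 EM iterations (converged)
#>   noise sd 0.201 m; active steps gamma(shape 1.56, scale 3.96), mean 6.20 m
#>   P(inactive->active) 0.017, P(active->inactive) 0.124
mean(classify_active(fit$p_active))   # fraction of fixes classified active
#> [1] 0.1153424
```

The extracted SMR (68.0 mg O2 kg⁻¹ h⁻¹) sits ~2.6% above the phenotype the
trace was simulated from — the lowest-decile estimator rides slightly above
the true floor because spontaneous activity only adds uptake. The HMM
recovers the positional-noise SD (0.201 m vs 0.2 simulated) and the
switching probabilities of the underlying behaviour chain.

The full pipeline — cohort, exclusions, traits, PCA, HMM, activity metrics
and the model-selection grid — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
res$accounting
#>                 stage  n
#> 1              tagged 23
#> 2            predated  3
#> 3 transmitter_failure  4
#> 4            analysed 16
```

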