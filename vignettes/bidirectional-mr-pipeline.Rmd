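---
title: "Bidirectional Mendelian randomization with risk-score trajectories: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional Mendelian randomization with risk-score trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirmr)
```

## The scientific question

Hypertension and type 2 diabetes coexist far more often than chance would
predict, and observational associations between blood pressure and glycemia
are hopelessly confounded by adiposity, lifestyle, and reverse causation.
Mendelian randomization (MR) breaks that deadlock by using genetic variants
as instruments: alleles are assigned at conception, so a variant that raises
systolic blood pressure (SBP) can only associate with fasting blood sugar
(FBS) through the blood-pressure pathway — provided it has no direct
("pleiotropic") effect on glucose.

`bidirmr` implements the full analysis chain for a *bidirectional* MR study
of SBP and FBS in a longitudinal middle-aged cohort, plus the two downstream
stages that give the question a life-course reading: group-based trajectory
models (GBTM) of genetically predicted phenotype series, and Cox regression
linking trajectory membership to incident type 2 diabetes (T2D) and
hypertension (HTN). Because individual-level biobank data of this kind are
not publicly deposited, the package ships a synthetic cohort generator whose
structure matches the assumptions of every stage, so the entire pipeline is
testable end to end.

## The estimators

**Instrument construction.** Variants pass QC on call rate (≥ 0.96), an
exact Hardy–Weinberg test (p ≥ 1e-4; full-enumeration conditional
distribution, stable at low minor allele frequency), and minor allele
frequency (≥ 0.01); subjects with more than 5% missing genotypes are dropped
first. Per-SNP association is an additive-model OLS adjusted for age and
sex. Greedy LD clumping visits variants by ascending p-value and discards
any candidate whose squared dosage correlation with an already-retained
variant on the same chromosome within 1 Mb reaches the threshold (default
r² < 0.01, with an optional relaxation ladder 0.01 → 0.02 → 0.03 that stops
once a requested instrument count is reached — the printed description of
the original selection is ambiguous between a single threshold and a
sequential scheme, so both are supported with the strict threshold as the
default). The weighted genetic risk score is

wGRS_i = Σ_k β_k · G_ik,

with each SNP oriented to its trait-increasing allele so all weights are
nonnegative ("reverse beta correction" is read as orientation, which leaves
every subject's rank unchanged and keeps the score's distribution
single-signed), and missing dosages imputed by their expectation
2·(effect-allele frequency).

**Individual-level MR.** Two-stage least squares with the wGRS as the single
instrument: stage 1 regresses the exposure on wGRS and covariates, stage 2
regresses the outcome on the fitted exposure. Standard errors use the
structural residual (outcome minus the structural fit at the *observed*
exposure) — the naive stage-2 residual understates the variance. Instrument
strength is the first-stage partial F (weak below 10); endogeneity is the
Wu–Hausman augmented-regression t-test on the stage-1 residual.

**Summary-statistic MR.** Four estimators on per-variant coefficients
(β_X, β_Y) with their standard errors:

- IVW: fixed-effect pooling of Wald ratios β_Yj/β_Xj with weights
  β_Xj²/se_Yj², equivalently the weighted regression of β_Y on β_X through
  the origin;
- simple median of Wald ratios, and the weighted median via cumulative-weight
  interpolation (consistent while valid instruments carry > 50% of weight);
  their SEs come from a seeded parametric bootstrap;
- MR-Egger: weighted regression *with* intercept after orienting β_X ≥ 0;
  the intercept estimates average directional pleiotropy. SEs use the
  weighted residual dispersion floored at 1 (the multiplicative
  random-effects convention) and t tests with m − 2 degrees of freedom,
  which keeps the intercept's type-I error near nominal under balanced
  pleiotropy.

A leave-one-out pass refits the chosen estimator dropping each variant in
turn and flags variants whose exclusion moves the Egger-intercept p-value
across 0.05 — the signature of a single variant (in the emulated study, the
one SNP shared by both instrument lists) driving the apparent pleiotropy.
`run_bidirectional()` assembles all of this in both directions, adds the
shared-variant-excluded re-analysis and sex-stratified 2SLS (instruments are
not re-selected within strata), and reports effects per exposure unit, per
1 SD, and per the clinical increments 0.5 mmol/L FBS and 10 mmHg SBP.
Glucose can be expressed in mg/dL via the constant 18.016
(`fbs_mmol_to_mgdl()`), since reports in this literature mix the two unit
systems.

**Two-sample construction.** Summary inputs are built by split-sample GWAS —
exposure coefficients from odd-indexed subjects, outcome coefficients from
even-indexed subjects — so the two-sample independence assumption holds by
construction; a same-sample mode exists for comparisons against 2SLS.

**Trajectories.** `predict_series()` regresses each visit's phenotype on
the wGRS and assigns every subject the fitted value, giving one predicted
value per visit (default 8 biennial visits; the "14 predicted values over
14 years" phrasing of the source design conflicts with its own biennial
8-visit schedule, so one value per visit is the default and `n_visits` is
configurable up to annual spacing). `fit_gbtm()` maximizes the normal
mixture

L = Π_i Σ_k π_k Π_t φ(y_it; poly_k(t), σ)

by EM with shared residual σ (per-group σ behind a flag is deliberately not
offered: with small risk classes it invites degenerate spikes), polynomial
orders up to 3, multi-start (one level-split start plus random
responsibilities), and a σ floor of 1e-6 so zero-noise fixtures cannot blow
up the likelihood. A censored-normal variant is unnecessary here because
wGRS-predicted values are unbounded. Groups are canonically ordered by
intercept; the group whose fitted curve spans the widest range over the
observation window is labeled "uncontrolled" (the fluctuating,
reverse-U-shaped pattern), the rest "controlled". `select_model()` compares
BIC = −2 logL + p log n across K and order, excludes models whose smallest
assigned group falls below 5% of subjects, and — when every candidate
violates that rule — returns the best violator with a warning, mirroring
the pragmatic two-group choice such analyses fall back on. Average posterior
probability per group is reported against the conventional 0.7 adequacy
bar.

**Survival.** `build_records()` applies the healthy-cohort rule (exclude
baseline T2D, hypertension, or stroke history), with optional left
truncation at the second visit (follow-up in the emulated design starts at
visit 2 for cases; entry-time handling respects risk sets exactly).
Incidence is events per 1,000 person-years with the exact Poisson interval
(qchisq(α/2, 2x)/2 to qchisq(1−α/2, 2x+2)/2, scaled by person-years) —
this reproduces the published example cells to their printed precision.
`fit_cox()` maximizes the Efron partial likelihood by Newton–Raphson
(score-norm tolerance 1e-9, risk sums via reverse cumulative sums so
left-truncated risk sets cost O(n log n)); Efron rather than Breslow because
visit-based onset times tie heavily. Onset times between visits are placed
at the midpoint of the bracketing visits by the generator, matching the
usual convention when diagnosis dates are interval-censored. The three
covariate sets mirror the published models: (1) age and sex; (2) plus BMI,
smoking, alcohol, exercise, and medication flags; (2c) plus baseline
risk-score quartiles computed on the analysis cohort after exclusions.

## The synthetic cohort: what it emulates and what it does not

The generator (`sim_config()` / `generate_cohort()`) encodes the study
design as defaults: ~8,500 genotyped subjects aged 40–69 (demo analyses in
`analysis/` use 2,000 to stay interactive), 91 FBS- and 68 SBP-associated
variants sharing exactly one SNP, biennial visits over 14 years, baseline
prevalence of T2D/HTN/stroke history at the published proportions
(892/1293/34 of 8,510), administrative censoring at 16 years, and baseline
hazards (0.055 and 0.075 events/person-year) chosen to land near the
published controlled-group incidence of ~58 and ~78 per 1,000
person-years. The uncontrolled class's default T2D log hazard ratio is
log 1.25 and the HTN one log 1.77, the published headline contrasts.

The two phenotypes obey a simultaneous structural system

FBS = γ_X'G + b_SF·SBP + U + ε_F,  SBP = γ_Y'G + b_FS·FBS + U + ε_S,

solved in reduced form so *both* causal coefficients (defaults: 0.063
mmol/L per mmHg and 3.26 mmHg per mmol/L, the published per-increment
effects) hold simultaneously; configurations with |b_SF · b_FS| ≥ 1 are
rejected as singular. One honest consequence: at these paper-scale causal
coefficients the cross-trait variance injection inflates the marginal SDs
well beyond the published 0.5 mmol/L and 18.1 mmHg — the published effect
sizes and the published marginal SDs cannot both hold in a linear
structural model, and the generator keeps the causal effects and lets the
SDs float. The shared variant receives 3×-scale direct effects on both
phenotypes, making it the planted pleiotropic outlier that the
shared-variant-excluded re-analysis removes. Optional horizontal
pleiotropy adds direct effects of each exposure set on the other phenotype
(balanced: zero mean, preserving InSIDE; directional: nonzero mean).
Latent class membership is tilted toward high combined genetic burden
(logistic link, population share calibrated to `traj_group_shares`), so
genetically predicted trajectory groups carry disease risk as in the
emulated study; setting `traj_genetic_link = 0` severs the link for null
experiments.

Covariate distributions (BMI normal 24.5 ± 3.1 kg/m², smoking 60/15/25%,
alcohol 45/40/15%, regular exercise 30%, 47.4% male) are documented
package choices, not published values — the source reports only summary
demographics. Missingness is uniform at 2% by default.

What the generator does *not* emulate: linkage disequilibrium beyond what
the clumping fixtures construct explicitly (draws are independent across
SNPs), population stratification and relatedness, genotype imputation
noise, time-varying covariates, and informative censoring. Passing tests
therefore demonstrate correctness of the estimators under the stated
structural model, not robustness to those real-data complications.

One instructive artifact of the strong bidirectional structure: selecting
instruments for one phenotype by scanning *all* variants lets the other
phenotype's variants through (their mediated associations are comparably
strong), which biases MR estimates upward exactly as instrument
contamination does in practice. The pipeline therefore supports restricting
each phenotype's candidate list to its own associated set
(`clump$candidates = "phenotype_set"`), the analog of taking instrument
lists from a dedicated external discovery GWAS, and the demo configuration
does so. Recovery experiments use each phenotype's own variant set with
external (true) weights — the package supports both internal re-estimation
and external weight files, since either reading of the original weighting
is defensible.

## Numerical choices

- GWAS per-SNP regressions use QR least squares per variant with complete
  cases for that variant; zero-variance dosages are flagged, never fatal.
- Clump ties are broken lexicographically by snp_id so output is
  independent of input row order; windows are inclusive, coordinates
  1-based.
- The weighted-median bootstrap and the GBTM multi-start are the only
  stochastic estimator components; both take explicit seeds and the
  pipeline derives per-stage sub-seeds deterministically from one global
  seed, so a rerun with the same configuration is bit-identical (the run
  manifest records MD5 hashes to prove it).
- The weighted-median interpolation estimator is invariant to duplicating
  a variant with its weight split in half only when the 50% crossing falls
  inside that variant's weight mass; the tests pin exactly that regime.
- EM convergence is declared below 1e-6 log-likelihood gain; a start that
  empties a group restarts, and only if all starts degenerate does the fit
  error.
- Newton–Raphson for the Cox model declares monotone likelihood when a
  coefficient passes ±20 on the log scale, naming the covariate.

## Problem sizes in the test suite

The suite exercises recovery at deliberately moderate sizes chosen as the
package's own testing conditions: 2SLS bidirectional recovery over 200
replicates of n = 2,000; Egger-intercept calibration over 500 summary-level
replicates of 60 variants; trajectory selection over 50 planted cohorts of
250 subjects × 8 visits; Cox hazard-ratio recovery over 200 replicates of
n = 5,000. Oracle-equivalence checks (normal equations, Wald ratios, the
reference Cox implementation, full-enumeration HWE) run on fixtures of at
most 50 subjects or 20 variants.

## Known limitations

- The generator's linear structural model cannot reproduce published
  marginal SDs together with the published causal effects (see above).
- GBTM on wGRS-predicted series partitions what is ultimately a continuum
  (predicted values are monotone in the score), so the selected K reflects
  discretization of that continuum rather than distinct latent biology;
  the observed-phenotype input mode exists precisely because the source
  design is ambiguous about which series feeds the final trajectory figure,
  and no default is asserted as "the original's".
- Sex-stratified F statistics depend on the realized cohort and are
  reported, not asserted.
- Competing risks, time-varying covariates, and proportionality testing
  beyond fit diagnostics are out of scope.
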