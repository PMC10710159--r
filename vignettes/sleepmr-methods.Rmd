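---
title: "Methods: one-sample MR and survival analysis of sleep traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-sample MR and survival analysis of sleep traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmr)
```

# The estimation problem

Sleep traits measured in population biobanks — diurnal preference
(chronotype, four ordinal levels), habitual sleep duration (integer hours,
binned ≤5/6/7/8/≥9 h), and insomnia symptoms (never-rarely / sometimes /
usually) — are self-reported behaviours entangled with health status,
socioeconomic position and psychiatric comorbidity. Their observational
associations with cancer incidence and with survival after a cancer
diagnosis therefore admit confounded and reverse-causal explanations.
`sleepmr` implements both sides of the comparison: conventional
multivariable Cox models, and one-sample Mendelian randomization (MR) in
which an unweighted genetic risk score (GRS) over trait-associated
variants serves as an instrumental variable.

MR identifies a causal effect under three assumptions: the instruments
associate with the exposure (relevance, checked by the first-stage F
statistic), they share no common cause with the outcome (independence,
checked empirically by the GRS-confounder screen), and they affect the
outcome only through the exposure (exclusion restriction, probed by the
pleiotropy-sensitive estimators: MR-Egger, weighted median, radial MR,
leave-one-out).

# Models

## Two-stage estimator

Stage 1 is a linear regression of the exposure on the GRS and the tier
covariates; stage 2 regresses the outcome on the stage-1 fitted values and
the same covariates — logistic for binary endpoints, reported as an odds
ratio per exposure category. Both stages share covariates so the
instrument only carries exposure variation orthogonal to them.

Two deliberate choices:

* **Ordinal exposures enter as numeric category indices** (0-based,
  lowest category as reference): the estimand is "per category increase",
  matching how per-category odds ratios are conventionally reported.
* **Second-stage standard errors are model-based by default** and ignore
  first-stage uncertainty. With instrument-strength F in the hundreds or
  thousands the understatement is negligible; for weak-instrument settings
  a participant-resampling bootstrap (`bootstrap`, seeded) is provided,
  and a warning fires whenever F < 10. Both modes are labelled in the
  output (`se_source`).

The Wald-ratio identity (two-stage estimate = `β_GY/β_GX` for a single
instrument without shared covariates) is exact and is used as a test
oracle.

## Nonlinear MR by residual stratification

Stratifying on the raw exposure would condition on a collider (the
exposure is caused by both the instrument and the confounders). Instead
the sample is split into `K` quantile groups (default `K = 3`) of the
residual exposure `X − fitted(X ~ G + C)`. Within stratum `k`, the
localized average causal effect is the ratio of the stratum genetic
associations,

`LACE_k = β_GY,k / β_GX,k`,
`se_k = |1/β_GX,k| sqrt(se_GY,k² + LACE_k² se_GX,k²)`,

and nonlinearity is tested two ways:

* **Cochran's Q**: `Q = Σ w_k (LACE_k − θ_IVW)²`, `w_k = 1/se_k²`,
  referred to χ² on `K − 1` df.
* **Quadratic (trend) test**: fixed-effect inverse-variance-weighted
  meta-regression of `LACE_k` on the stratum mean exposure, Wald test of
  zero slope. The named "quadratic test" of this framework is not given a
  formula in most applied reports; the trend realization is the default
  here because it operates on the same stratum summaries as Q and needs no
  refitting. A pooled alternative — adding the squared fitted exposure to
  the second stage — is available via `quadratic = "pooled"` and reported
  alongside, never silently substituted.

Design decisions made where the method family is genuinely open: the LACE
denominator uses the **stratum-specific** first-stage coefficient (the
`denominator = "global"` option reuses the whole-sample coefficient); the
residual regression includes the basic covariate tier, for consistency
with the linear models; quantile ties are broken by stable participant
order so stratum sizes differ by at most one (the tie policy is recorded
on the assignment).

## Summary-statistic sensitivity suite

Per-variant associations are derived in-sample (`derive_variant_assocs`):
`β_GX,j` from a linear exposure regression and `β_GY,j` from a logistic
outcome regression per variant, basic-tier adjusted, orientation
normalized to `β_GX ≥ 0`. Monomorphic variants are dropped with a log
entry; variants with `|β_GX| < 2 se` are flagged `near_null` because their
Wald ratios are unstable.

* **IVW** uses first-order ratio weights `w_j = (se_GY,j/|β_GX,j|)⁻²`
  (second-order weights are a documented alternative in the radial
  literature; first-order is the default here as the common reporting
  convention), fixed-effect SE `(Σw)^{-1/2}`, with a multiplicative
  random-effects option.
* **MR-Egger** is WLS of `β_GY` on `β_GX` with weights `1/se_GY²`;
  residual dispersion is bounded below by 1 so SEs are never deflated
  below the known-variance level, and p-values use a t reference on
  `m − 2` df. A near-zero spread in `β_GX` triggers a
  regression-dilution warning.
* **Weighted median**: linear interpolation of the ordered ratios at
  cumulative normalized weight 0.5; SE by seeded parametric bootstrap of
  the `(β_GX, β_GY)` pairs (default 1000 replicates; a warning below
  100).
* **Radial MR**: `Q_j = w_j (θ_j − θ_IVW)²` sums exactly to the global Q;
  outliers exceed the χ²₁ quantile at `0.05/m` (Bonferroni, mirroring the
  multiplicity convention used throughout), and the IVW fit after removal
  is returned rather than applied silently.
* **Leave-one-out** flags variants whose omission moves the pooled
  estimate across zero or by more than a configurable fraction (default
  20%).

## Cox tiers, survival curves, multiplicity

The three covariate tiers are nested by construction: *basic* (age, sex,
assessment centre, 10 genetic principal components, genotyping array),
*further* (adds BMI, employment, area deprivation, smoking, drinking,
mental health, diet, sedentary time, comorbidity count, physical
activity, education, ethnicity, family history; mortality endpoints also
add self-reported cancer count, operation and treatment count), *full*
(adds the other two sleep traits, entered numerically). Exposures enter
as category indicators against declared references — 7 h duration,
never/rarely insomnia, definite-morning chronotype — so per-level hazard
ratios are reported. Ties use the Efron approximation (less biased than
Breslow with heavy ties at integer event times); tie handling and whether
centre is a covariate rather than a stratification factor are
config-exposed since conventions differ across analyses. Fitting is
delegated to `survival::coxph`; a brute-force Efron partial-likelihood
oracle in the test suite pins the coefficient independently of that
delegation.

Kaplan-Meier curves carry Greenwood standard errors; censored
observations tied with events remain at risk for those events. Adjusted
curves raise the Breslow baseline cumulative hazard to
`exp(linear predictor)` at a reference profile (covariate means for
continuous, modes for categorical — the profile is attached to the
output). The log-rank statistic is the standard observed-vs-hypergeometric
form with `G − 1` df.

Across estimator grids the familywise threshold is `0.05 / number of
fits`, with p-values between the threshold and 0.05 labelled
*suggestive* — the same Bonferroni convention as the confounder screen
(`0.05 / number of tests`, computed from the tests actually performed;
untestable constant candidates do not enter the denominator).

## Eligibility filters

Exclusions apply in a fixed, logged order — target population (baseline
cancer status; for the 5-year mortality cohort also the 2-year
pre-enrollment diagnosis window and removal of non-cancer deaths), missing
covariates, current shift work, extreme sleep duration (<4 h or >11 h),
minimum age — with each removed row counted once under the first matching
rule. The order is a package convention chosen for ledger
reproducibility; applied reports rarely state one. Dates are reduced to
year offsets from enrollment, which every downstream computation needs and
nothing more. The "interferential trait" exclusion (e.g. removing insomnia
cases before instrumenting short sleep) is driven by the screen's flags
plus an explicit rule map, never hard-coded.

# The synthetic cohort generator

`simulate_cohort()` draws independent biallelic variants in Hardy-Weinberg
and linkage equilibrium (instrument panels are LD-clumped GWAS hits, so
independence is the clean emulation), builds unit-variance latent
exposures as genetic component + shared confounder `U` + noise, and
discretizes them by fixed quantile cut-points to ordinal margins taken
from published baseline tables of a large population cohort (≈26/36/28/9%
chronotype, ≈5/19/40/29/7% duration bins, ≈26/47/27% insomnia).
Instrument-set sizes default to 12 (evening chronotype), 27 (short
sleep), 8 (long sleep), 78 (continuous duration) and 57 (insomnia)
variants. Small cross-trait genetic effects (short-sleep variants on
insomnia, long-sleep variants on chronotype) reproduce the interferential
structure the screen is designed to detect.

Outcomes are exponential proportional-hazards draws: incident cancer
among the cancer-free with the log-hazard linear (or a supplied function,
for J-shaped scenarios) in the realized exposure plus `confounder × U`
plus age/sex terms; death after a baseline cancer diagnosis from a second
such model, with cause labels assigned by competing risks at a
configurable cancer:non-cancer ratio (default ≈2864:823 ≈ 78%). Baseline
hazards are calibrated so marginal incidence ≈ 13% and case mortality ≈
15% over the 11-year administrative censoring horizon, matching the
follow-up scale of the emulated design. A Weibull option is deliberately
out of scope here; exponential baselines make closed-form checks exact.

Causal effects default to zero — the generator's null is the reference
condition for calibration tests — and every realized parameter (variant
effects, cut-points, confounder values, baseline hazards) is returned in
`$truth` so recovery tests compare estimates against known values, not
against other estimates. A summary-level companion,
`simulate_variant_assocs()`, plants a causal slope, pleiotropy and invalid
fractions directly at the `(β_GX, β_GY)` level for replicate-based
estimator studies, where individual-level cohorts would add runtime
without adding evidence.

What the generator does **not** emulate: linkage disequilibrium and
imputation uncertainty, ascertainment/selection into the cohort,
calendar-time structure, informative censoring, and registry coding
error. Passing tests therefore demonstrate estimator correctness under
the stated generative assumptions, not robustness to those real-data
features.

# Numerical choices and degenerate inputs

* Confidence intervals are `estimate ± z_{0.975} se` on the log scale
  before exponentiation; p-values are Wald unless stated (t for Egger,
  χ² for Q and log-rank).
* Percentages in cohort summaries round half away from zero to two
  decimals, the convention of printed baseline tables (base R rounds to
  even).
* A constant GRS is an error ("uninformative instrument"); second-stage
  separation is flagged, not fatal. Stratum denominators below `1e-8` in
  absolute value mark the stratum unstable and exclude it from the
  nonlinearity tests. An exact Egger fit (zero residual) keeps finite
  SEs via a dispersion floor at machine epsilon.
* Missing dosages are mean-imputed per variant with the affected
  participants flagged (strict runs can set `missing = "fail"`);
  strand-ambiguous A/T and C/G variants are dropped and logged by default
  since orientation cannot be decided from alleles alone without
  reference allele frequencies.
* Exposure levels with zero events in a Cox fit are reported as
  undefined and flagged rather than dropped or given ±∞ estimates.

# Problem sizes

The test suite and the acceptance script run their simulations at sizes
chosen to make each check informative at desk scale: single-run parameter
recovery at n = 100,000 (rare-outcome two-stage) and n = 20,000 (Cox,
Kaplan-Meier limits); calibration at 500 replicates of n = 2,000 cohorts
(nonlinearity tests), 1,000 replicates for the screen and the log-rank
null; estimator-level replicate studies (Egger, weighted median, radial)
at 200 replicates of 21-35 variants. Strong instruments
(`first_stage_r2` 0.2-0.4) are used in recovery runs so the recovery
tolerance reflects estimator bias rather than instrument noise; the
generator's default (5%) is the realistic regime and is what the
pipeline and examples use.

# Known limitations

* One-sample MR with model-based second-stage SEs understates uncertainty
  when instruments are weak; the bootstrap option exists but is not the
  default for runtime reasons.
* Logistic second stages estimate conditional odds ratios;
  non-collapsibility makes these differ from marginal effects away from
  the rare-outcome limit. Recovery tests therefore plant effects at low
  incidence.
* The ordinal exposures are treated as equally spaced when entered
  numerically — the "per category" estimand inherits that convention.
* No competing-risks decomposition (cause-specific mortality handles
  non-cancer deaths by exclusion, as the emulated design does), no
  time-varying covariates, and proportionality is assumed rather than
  formally tested.
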