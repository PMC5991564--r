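---
title: "Methods: tissue-specific adjustment and modelling of m.3243A>G heteroplasmy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific adjustment and modelling of m.3243A>G heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(het3243)
```

## Scope

`het3243` implements the quantitative workup of an m.3243A>G carrier
cohort: making heteroplasmy measures comparable across tissues
(age-corrected blood, sex-corrected urine), characterising longitudinal
blood decline and measurement variability, quantifying mtDNA copy number
from qPCR plates, and relating heteroplasmy and copy number to disease
burden (NMDAS) and its progression. Everything is exercised against a
synthetic-cohort generator whose ground truth is known, so each estimator
can be validated by parameter recovery.

Heteroplasmy is a proportion in [0, 1] internally; CSV output uses
percent. All stochastic routines take an explicit seed.

## The adjustment models

**Blood.** Blood heteroplasmy decays multiplicatively with age. The
forward model is `blood = p * b^(age + k)` for latent load `p`, retention
base `b = 0.977` per year (a compound ~2.3%/yr decline) and age offset
`k = 12` years capturing a rapid early-life reduction; the adjustment
inverts it, `adjusted = blood / b^(age + k)`. Because the inversion can
exceed 1 for high levels at high ages, adjusted values are truncated to 1
and flagged (`capped`); the flag preserves the information that the raw
adjusted value overflowed the proportion scale, where silently returning
values above 100% would not be interpretable as a mutant fraction.

**Urine.** On the log-odds scale urine relates to the latent load through
a proportionality factor `s = 0.791` and a sex offset: generatively
`logit(urine) = s * (logit(p) + offset_sex)` with `offset_male = +0.625`
and `offset_female = -0.608`. The published inverse formulas follow
verbatim: `inv_logit(logit(urine)/s - 0.625)` for males,
`inv_logit(logit(urine)/s + 0.608)` for females. This sign convention was
chosen so that the generative round trip is exact — data generated from
the forward model are recovered perfectly by the adjustment, which is the
backbone of the noise-free acceptance checks.

**Clamping.** `logit()` clamps its argument into `[eps, 1 - eps]` with
`eps = 0.005` and flags clamped values. The clamp sits below the assay's
3% sensitivity, so it only ever fires on levels the assay cannot resolve;
it keeps the transforms finite at exactly 0 or 1 and is configurable.

**Composite.** The "mean adjusted blood and urine" measure is the
unweighted arithmetic mean of the two adjusted proportions. Whether any
weighting should apply is undocumented in the source methodology;
unweighted is the simplest reading and is what the package uses. Subjects
missing either component are dropped from composite analyses (with a
message) rather than imputed.

## Estimating the constants

**Compound decline** (`fit_compound_decline`). Least squares of
`blood_i - init_i * b^(age_i + k)` over `b ∈ [0.90, 1.00]`,
`k ∈ [0, 30]` — bounds that bracket the published (0.977, 12) with wide
margin — by a 25×25 coarse grid followed by Nelder–Mead refinement (the
refinement returns `Inf` outside the box, keeping the optimum inside).
An exhaustive fine-grid brute force serves as the oracle in the tests.
Residuals are minimised on the raw proportion scale; the derivation of the
published constants is not public, and raw-scale least squares is the
simplest reading of "modelling the decline". A logit-scale objective is
exposed via `scale = "logit"` as a robustness option. Both `b` and `k` are
fitted; whether `k` was originally fitted or fixed is unknown. Fewer than
10 pairs is an error — with `b` and `k` trading off through
`b^(age+k) = b^k * b^age`, small samples do not identify the pair.

**Rate-vs-initial-level regression** (`estimate_linear_decline`).
Under exponential decline `dp/dt = -r p` the annual change is proportional
to the level, so `(last - first)/span` is regressed on `first` *through
the origin*; the proportionality argument (and the methodology this
extends) implies no intercept, though the original description leaves
this unstated. The age-extended model `-(r0 + r1 * age_first) * first`
remains through the origin. Note a structural subtlety the tests
deliberately preserve: on truly exponential trajectories the first/last
difference quotient underestimates the instantaneous rate by roughly
`r * span / 2` (~7% at the default 4–12-year spans); the estimator is
faithful to the published procedure rather than corrected for this.

**Urine sex model** (`fit_urine_sex_model`). OLS of `logit(urine)` on
`logit(muscle)` plus a male indicator, with muscle standing in for the
latent load. The slope estimates `s`; the offsets are read off the
intercepts (`female = -intercept/s`, `male = (intercept + beta_male)/s`).
Because muscle itself carries observation noise, the slope is attenuated
slightly (classical errors-in-variables); at the generator's default
muscle noise this attenuation is ~2%, visible in the recovery tests. The
percentage-scale description (`fit_urine_linear_model`,
`urine% ~ muscle% + sex`) is kept as a separate parameterisation because
the sex gap is most naturally reported in percentage points.

## Variability

Per-subject SDs of repeated measurements (n ≥ 3) are divided by
`c4(n) = sqrt(2/(n-1)) * Γ(n/2) / Γ((n-1)/2)` to remove the small-sample
downward bias (~11% at n = 3), then by the population mean of the measure
to give a CV. The population mean is the mean over per-subject means, so
heavily resampled subjects do not dominate — consistent with the
one-point-per-individual convention used elsewhere in the workflow. The
mean CV's 95% CI is a t-based normal approximation (the original CI
construction is unstated; the symmetric form matches how such CIs are
reported). Distributions of CVs are compared by two-sided Wilcoxon
rank-sum tests with continuity correction; all-tied input returns P = 1
with a warning rather than an error.

## qPCR copy number

Standard curves are OLS of mean Ct on log10 relative quantity over a
six-point ten-fold dilution series; QC requires R² > 0.999 and slope in
[-3.6, -3.3] (100% efficiency gives exactly -1/log10(2) = -3.3219).
Samples are quantified from Ct triplicates after removing wells with
|Ct - median| > 0.5 — the "within-sample outlier" rule is not specified in
the source protocol; the 0.5-Ct median rule is common qPCR practice and is
configurable — and fail QC if fewer than 2 wells survive, Ct SD > 0.3, or
mean Ct > 33. Copies per nucleus combine the mitochondrial and nuclear
targets as `2 * (nd1 * dilution_ratio) / b2m`: the diploid factor (two B2M
copies per nucleus) and the 100-fold concentration ratio between the two
assays' working dilutions are explicit, configurable parameters, since the
source formula states neither. Inter-plate standardisation scales each
plate by (grand-mean control)/(on-plate control), which cancels a
multiplicative plate effect exactly; plates without a QC-passing control
are excluded. Standardisation buys inter-plate comparability at the cost
of folding the control's own measurement noise into every sample on the
plate — the recovery tests therefore check the quantification chain on raw
values and plate-effect removal separately.

## Disease burden and progression

**NMDAS scaling.** The respiratory-function item is excluded from the
score sum (it is hard to record reliably); which of the 29 item indices it
is, is not fixed by the instrument's published form, so it is a
configurable argument (default 10). Assessments with fewer than 25 of 29
responses are excluded; otherwise the sum of answered non-respiratory
items is divided by the number of answered items and multiplied by 29.
The denominator counts all answered items, including the respiratory one —
this is the reading under which a fully answered assessment's scaled score
equals its (non-respiratory) raw sum.

**Burden.** One independent point per subject: the maximum scaled score at
the earliest age reached. OLS on the square root of the scaled score
(taken to keep residuals near normal; Shapiro–Wilk P on residuals is
reported), with age plus one heteroplasmy measure — or age, muscle
heteroplasmy and copy number for the muscle model. Models are compared by
adjusted R² with subject-level bootstrap (default 1,000 replicates):
subjects, not observations, are the exchangeable unit. The reported P is
the bootstrap probability that the second model is at least as good as the
first, with exact ties counted half — hence a self-comparison gives
exactly P = 0.5.

**Progression.** A linear mixed model on longitudinal sqrt-NMDAS with
*no intercept anywhere* (subjects are assumed asymptomatic at birth, so
every trajectory passes through the origin): fixed effects age and
age×heteroplasmy; by-subject random slopes on the same two terms; fitted
with `nlme` by maximum likelihood. ML rather than REML because AICs are
compared across models with different fixed-effect content, where REML
likelihoods are not comparable. The heteroplasmy main effect is excluded
by default (it was dropped as non-significant in the reference analysis)
but can be re-enabled with `include_het_main = TRUE` to replicate the
selection step. `include_random = FALSE` collapses the model to
through-origin OLS — the degenerate-case oracle used in the tests, and the
only identifiable model for single-visit data. AIC comparisons bootstrap
subjects and report P as the fraction of replicates with
`AIC(a) - AIC(b) < 0` (first model better), ties counted half.

## The synthetic cohort generator

The generator reproduces the statistical *structure* the estimators
assume, with defaults matching the reference cohort where that cohort's
values are known: 242 subjects with 147/242 female, ages uniform on
[19.7, 79.9] years, tissue copy numbers log-normal with medians/IQRs
3523/1708 (muscle), 144/81 (blood), 1181/2870 (urine), the forward
adjustment models above with their published constants, a continuous
decline rate of 0.0185/yr for the trajectory generator, a within-subject
CV of 0.189 for the repeated-measurement generator, and burden
coefficients +0.027 per % heteroplasmy and -0.00055 per copy on the
sqrt-NMDAS scale.

Values the reference cohort does not pin down are free choices, made once
for realism and documented here:

* latent heteroplasmy uniform on [0.05, 0.95] — the real latent
  distribution is unobservable; a wide uniform maximises identifiability
  in recovery experiments;
* observation noise: logit-scale SD 0.2 (muscle) and 0.35 (urine),
  proportion-scale SD 0.02 (blood) — small enough to keep simulated
  between-tissue correlations in the regime reported for the real cohort;
* percentage-linear urine mode: female intercept 0, residual SD 8 pp;
* burden model: intercept 3, residual SD 1.5 (sqrt-NMDAS units), giving
  realistic score ranges and explained-variance fractions;
* progression: fixed slopes 0.04 (age) and 0.06 (age×het, per
  proportion), random-slope SDs 0.02 each, residual SD 0.5;
* qPCR: undiluted-standard intercepts 18 (ND1) and 24 (B2M) Ct, well
  noise SD 0.1 Ct, per-plate log-normal effect sdlog 0.15 (control CV
  near the reported ~17%), amplification efficiency 95% — at exactly 100%
  the theoretical slope (-3.3219) sits 0.02 Ct from the QC window edge,
  so any well noise would reject half the simulated curves, which real
  curves (all inside the window) do not do;
* simulated tissue levels below the 3% assay sensitivity are recorded
  as 0, as the pyrosequencing assay would report them;
* NMDAS totals are decomposed into 29 integer item scores by a
  deterministic largest-remainder split over the 28 scored items (cap 5
  each, respiratory item scored 0), so scaled totals round to integers —
  a ±0.5 quantisation the progression models absorb as noise.

What the generator does **not** emulate: the terminal non-zero plateau
some real blood trajectories show (never formalised in the source
methodology), item-level NMDAS correlation structure, assay-specific
pyrosequencing error profiles, and real recruitment/censoring patterns.
Passing recovery tests therefore demonstrate that the estimators invert
the stated models correctly at realistic noise levels — not that those
models capture every feature of real cohort data.

## Numerical and edge-case conventions

* Percentage/proportion detection on CSV input: values > 1 imply percent;
  a column mixing values > 1 with fractional values in (0, 1) is rejected
  as mixed-scale. Exact zeros are allowed on either scale.
* Post-transplant urine exclusion removes urine rows at ages ≥ the
  transplant age; the operation is idempotent and logs removals.
* Bootstrap replicates that fail to fit are dropped and counted; more
  than 5% dropped raises a warning.
* Degenerate inputs fail loudly: all-equal initial levels (decline
  regression), rank-deficient burden designs (collinear columns named),
  single-measurement subjects (skipped with a message), missing sex for
  urine adjustment (error — the adjustment is undefined).
* Near-singular random-effects covariances are returned with a warning
  rather than discarded, matching `nlme` practice.

## Problem sizes

The test-suite and acceptance-script simulations use cohort sizes chosen
to mirror the corresponding subsets of the reference study — 200 subjects
for the decline fit (N = 204 there), 75 for the muscle–urine models
(N = 75), 39 subjects × 3–6 repeats for urine CVs (N = 39), 35
multi-measurement subjects for the rate regression, 66 for the muscle
burden model (N = 66) — with 20–500 replicate cohorts per experiment,
enough for Monte-Carlo means to stabilise well inside the tolerances
checked.

## Known limitations

The compound-decline objective is a pragmatic reconstruction; if the
original derivation used a different scale or weighting, fitted `k` (less
well identified than `b`) is the parameter most likely to differ. The
rate-vs-initial estimator inherits the difference-quotient bias discussed
above. CV confidence intervals assume approximate normality of per-subject
CVs. The progression model's no-intercept assumption is structural — it
cannot represent congenital disease burden. None of the estimators model
measurement error in covariates; attenuation is quantified empirically in
the recovery tests rather than corrected.
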