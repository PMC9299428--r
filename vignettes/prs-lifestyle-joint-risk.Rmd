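---
title: "Joint genetic and lifestyle risk modelling with prsjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint genetic and lifestyle risk modelling with prsjoint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prsjoint estimates how polygenic and behavioural risk combine in a
complex disease, with rheumatoid arthritis (RA) in a large prospective
biobank as the motivating setting.  The package implements the full
analysis chain — polygenic risk score (PRS) construction by clumping and
thresholding, derivation of a healthy-lifestyle index, and joint,
stratified and additive-interaction risk models — together with a
synthetic cohort generator with known ground truth, so every stage can
be validated end to end before it touches real data.

```{r setup, eval = FALSE}
library(prsjoint)
library(dplyr)
```

## The model

**Polygenic score.**  For individual $i$ the score is the unnormalized
weighted allele count over the $K$ selected variants,
$\mathrm{PRS}_i = \sum_{k=1}^{K} X_{ik}\,\hat\beta_k$,
where $X_{ik} \in \{0,1,2\}$ is the dosage of the effect allele and
$\hat\beta_k$ the per-allele log odds ratio estimated in an external
discovery GWAS.  Scores are deliberately not divided by $K$ or $2K$;
standardization to mean 0, SD 1 over the *entire* cohort (training and
test together) puts every threshold's score on a common per-SD scale.

Variants enter the score through the conservative clumping +
thresholding (C+T) route: quality control (MAF $> 0.02$,
Hardy–Weinberg $p > 10^{-7}$, call rate $\ge 0.95$), greedy LD clumping
(index variant = smallest remaining $p$; neighbours within 1 Mb on the
same chromosome with dosage $r^2 \ge 0.001$ absorbed), then five
p-value cut-offs $5\times10^{-4} \dots 5\times10^{-8}$.  The cut-off
whose covariate-adjusted score shows the strongest training-set
association is fixed for all test-set analyses.  An MHC-free score
(excluding chr6:28,477,797–33,448,354) supports sensitivity analyses,
since the MHC is both the strongest RA locus cluster and the region
where LD is least trustworthy.

**Lifestyle index.**  Five binary healthy indicators are derived from
raw fields: no smoking (never-smokers, or former smokers who quit at
least 30 years ago), regular physical activity ($\ge 75$ vigorous
min/wk, or $\ge 150$ moderate min/wk, or
$2\cdot\text{vig} + \text{mod} \ge 150$, or both intensities on
$\ge 5$ days/wk), moderate BMI ($[18.5, 24)$ kg/m²), no alcohol
consumption (not a current more-than-monthly drinker), and healthy diet
(at least 4 of 6 food groups on the healthy side of the cohort
median).  The index counts the first three — smoking, activity, BMI —
because only those show a protective association with RA; categories
are favorable (3), moderate (2) and unfavorable (0–1).  Diet and
alcohol remain available for five-factor sensitivity analyses.

**Risk models.**  Case–control contrasts use multivariable logistic
regression (odds ratios), prospective contrasts use Cox proportional
hazards with the Efron tie correction (hazard ratios), both adjusted
for age, sex, deprivation index, genotyping batch, assessment centre
and 10 genetic PCs, with Wald confidence intervals throughout.
Baseline-prevalent cases are excluded from every prospective fit, and
the pipeline asserts this on each run.  Discrimination is the
Mann–Whitney AUC; dose–response uses a restricted cubic spline;
ordered-group trends use the Cochran–Armitage test.  Additive
interaction between high genetic risk and unfavorable lifestyle is
quantified by the relative excess risk due to interaction and the
attributable proportion,
$\mathrm{RERI} = e^{\beta_{gl}} - e^{\beta_g} - e^{\beta_l} + 1$ and
$\mathrm{AP} = \mathrm{RERI}/e^{\beta_{gl}}$,
from indicator coding against the doubly-unexposed reference; both are
zero when risks add.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions the package is
calibrated to: a cohort of the UK-biobank type with RA prevalence
$\approx 1.3\%$ (0.35% prevalent at baseline, the rest incident over
10–14 years of follow-up at baseline hazard $7.7\times10^{-4}$ per
person-year), healthy-indicator prevalences 0.61 (no smoking), 0.71
(regular activity), 0.781 (moderate BMI), 0.06 (no alcohol), 0.337
(healthy diet), an odds ratio of 1.4 per score SD, and protective
lifestyle odds ratios 0.70/0.75/0.72 for smoking/activity/BMI.

Genotypes come from a Gaussian copula: within each LD block a latent
AR(1) normal vector (adjacent correlation `ld_rho`) is thresholded at
the Hardy–Weinberg genotype quantiles of each variant's drawn allele
frequency.  This reproduces marginal genotype frequencies exactly and
gives smoothly tunable LD, which is all the C+T machinery consumes.
Discovery summary statistics are sampled analytically —
$\hat\beta_k \sim N(\beta^{\text{marg}}_k, se_k^2)$ with
$se_k = 1/\sqrt{2N\,p_k(1-p_k)\,\phi(1-\phi)}$ — rather than by
simulating a discovery cohort; the marginal beta of a tagged null
variant is the LD projection $\sum_j r_{kj}\beta_j$ over causal
variants in its block, using the realized dosage correlations (exact
under the copula's second-order structure).  An optional
`discovery_beta` vector decouples discovery from target effects,
emulating the winner's-curse / transferability gap that makes an
intermediate p-value threshold optimal.

Disease combines two linear predictors sharing the same effects,
mirroring parallel case–control and prospective designs: prevalent
status is Bernoulli-logistic (intercept solved by `uniroot` so the
cohort-average prevalence hits its target exactly), incident times are
exponential with rate $h_0 e^{\eta}$ under uniform administrative
censoring.  Effect sizes are rescaled on the realized panel so one SD
of the true score carries exactly $\log(1.4)$.

Deliberately *not* modelled: realistic human LD maps, imputation
uncertainty (the INFO-score filter is therefore out of scope),
relatedness, population stratification beyond pure-noise PC covariates,
age/sex effects on disease, lifestyle drift over follow-up, and
competing risks.  Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under known truth — not that any
particular real-data result is reproducible.

## Numerical and design choices

* **Quantiles and ties.**  All quantile cuts (quartile risk groups,
  deciles, spline knots) use type-7 linear interpolation; individuals
  exactly at a cut point go to the lower group; an all-tied score
  vector degenerates to "low" with a warning.  Clumping breaks p-value
  ties by (chromosome, position), making output order-deterministic.
* **BMI interval.**  Half-open $[18.5, 24)$ so adjacent categories
  never double-count; the bounds (and a closed upper bound) are
  arguments, giving the 18.5–25 sensitivity definition.
* **Smoking definition.**  The quit-30-years rule reads ambiguous
  source phrasing as "never-smokers, or former smokers quit ≥ 30
  years"; a `no_current` rule is provided as the sensitivity switch.
* **Activity days clause.**  "Both intensities at least once a week on
  at least 5 days" is implemented as vigorous > 0, moderate > 0 and
  active days ≥ 5; the equivalent-combination rule is the WHO-style
  $2\cdot\text{vig} + \text{mod} \ge 150$.
* **Missing lifestyle fields** propagate to exclusion from index
  analyses (logged), never to imputation.  Missing dosages are ignored
  pairwise in LD $r^2$ and mean-imputed as $2\,\mathrm{MAF}$ in
  scoring.
* **Allele harmonization** flips the beta sign when effect/other
  alleles are swapped relative to the panel, drops mismatched pairs
  with a warning, and assumes same-strand files (A/T and C/G pairs are
  not special-cased).
* **Model fits.**  Logistic fits run IRLS to tolerance $10^{-10}$
  (max 25 iterations) with explicit separation detection; Cox fits use
  Efron ties because simulated integer-ish follow-up times tie often
  and Breslow would bias.  RERI/AP intervals use the delta method by
  default (matching the symmetric Wald intervals used everywhere),
  with a nonparametric bootstrap option for logistic fits.
* **Spline knots** default to 4 at the 5/35/65/95th percentiles
  (3 or 5 knots available); the basis is the restricted truncated-power
  parameterization, linear beyond the boundary knots by construction.
* **Threshold selection** uses the score-term p-value as the primary
  criterion and AUC only to break exact ties, then candidate order;
  the full per-threshold table is always emitted so any alternative
  choice is auditable.  Thresholds retaining zero variants are skipped
  with a log entry.
* **Batch covariate.**  Genotyping chip/batch enters as a single
  categorical covariate.
* **Split.**  The training split is a simple random sample of size
  $\lfloor 0.2N \rfloor$ under seed 1234 (both arguments exposed; 0.4
  reproduces a 40/60 sensitivity split).  Risk-group quartiles and
  standardization use the full cohort; a reference-subset argument
  covers the train-only alternative.

## Validation problem sizes

The test suite validates each stage against independent oracles:
exhaustive greedy clumping on 50 random blocks of up to 100 variants;
exact pairwise-concordance AUC on 100 random instances up to $n=500$;
closed-form 2×2 odds ratios and a brute-force six-subject partial
likelihood; closed-form RERI/AP on saturated 2×2×2 tables.
Statistical calibration runs at moderate scale chosen to balance power
against runtime: 200 additive-null cohorts of $n=20{,}000$ for RERI
interval coverage, 50 cohorts of $n=50{,}000$ for effect-recovery
coverage and joint-grid ordering, and 50 training cohorts of
$n=20{,}000$ for threshold-selection recovery.  LD calibration checks
use $n=20{,}000$ individuals.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- sim_config(
  n_individuals = 20000, n_variants = 2000,
  baseline_prevalence = 0.02, baseline_hazard = 2e-3, seed = 2024
)
report <- run_pipeline(cfg, covariates = c("age", "sex", "tdi"))
report$selection # per-threshold OR / p / AUC table and the chosen cut-off
report$association # per-SD OR and HR with CIs in the test set
report$grid # 3x3 genetic-by-lifestyle risk grid
report$interaction # RERI / AP with delta-method CIs
autoplot(report$grid)
```

`run_pipeline()` logs the sample count at every exclusion step, stamps
every written file with the seed, and reruns byte-identically under the
same configuration.

## Limitations

Synthetic LD is block-diagonal AR(1), far simpler than real haplotype
structure, so clumping behaviour near complex loci (notably the MHC) is
not stress-tested by simulation alone.  The lifestyle generator matches
indicator prevalences, not the joint distribution of real behavioural
fields, and its BMI distribution is a calibrated log-normal, not an
empirical one.  Effect recovery is demonstrated at tens of thousands of
individuals; rare-variant and small-cell behaviour (e.g. joint-grid
cells with < 30 cases) is noisy, and the RERI delta interval is known
to be slightly anticonservative in small samples — the bootstrap option
exists for exactly that case.
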