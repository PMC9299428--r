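# prsjoint

Joint genetic and lifestyle risk modelling with polygenic risk scores,
motivated by rheumatoid arthritis (RA) in large prospective biobank
cohorts.  The package is written for genetic epidemiologists who want
the full analysis chain — score construction, lifestyle index, joint
and interaction models — as tested, reusable R functions rather than a
collection of one-off scripts, plus a synthetic cohort generator with
known ground truth for validating every stage.

## What it computes

**Clumping + thresholding PRS.**  From discovery GWAS summary
statistics and target-cohort dosages:

    PRS_i = sum_k X_ik * beta_hat_k

over variants surviving QC (MAF > 0.02, HWE p > 1e-7, call rate >=
0.95), greedy LD clumping (r² >= 0.001 within 1 Mb absorbed by the
smallest-p index variant) and one of five p-value cut-offs (5e-4 …
5e-8).  The cut-off with the strongest covariate-adjusted training-set
association is selected and held fixed; scores are standardized to
mean 0, SD 1 over the entire cohort, grouped into quartile-based
low/intermediate/high genetic risk, and optionally recomputed without
the MHC region (chr6:28,477,797–33,448,354).

**Healthy-lifestyle index.**  Binary indicators for no smoking
(never, or quit >= 30 years), regular physical activity (>= 75
vigorous or >= 150 moderate min/week, an equivalent combination, or
both intensities on >= 5 days/week), moderate BMI ([18.5, 24) kg/m²),
no alcohol consumption and healthy diet; the three-factor index
(smoking, activity, BMI) classifies lifestyles as favorable (3),
moderate (2) or unfavorable (0–1).

**Risk models.**  Covariate-adjusted logistic (OR) and Cox/Efron (HR)
fits with broom-style `tidy()`/`glance()` methods, Mann–Whitney AUC,
restricted cubic splines, Cochran–Armitage trend tests, a 3×3
genetic-by-lifestyle joint risk grid against the low-genetic/favorable
reference cell, per-variant SNP×lifestyle interaction scans, and
additive interaction via

    RERI = exp(b_gl) - exp(b_g) - exp(b_l) + 1,    AP = RERI / exp(b_gl)

with delta-method (default) or bootstrap confidence intervals.

**Synthetic cohorts.**  `sim_config()` + `simulate_cohort()` generate
LD-blocked Gaussian-copula genotypes, analytically sampled discovery
summary statistics, raw lifestyle fields whose derived indicators hit
configured prevalences, and prevalent + incident disease with known
effects (defaults: OR 1.4 per score SD, lifestyle ORs 0.70–0.75,
cohort prevalence ≈ 1.3%).

## Worked example

```r
library(prsjoint)

cfg <- sim_config(n_individuals = 20000, n_variants = 2000,
                  baseline_prevalence = 0.02, baseline_hazard = 2e-3,
                  seed = 2024)
report <- run_pipeline(cfg, covariates = c("age", "sex", "tdi"))
report
#> <prsj_report>
#>   selected threshold: 5e-08
#>   per-SD OR 1.179 / HR 1.246, AUC 0.557
#>   high-genetic x unfavorable-lifestyle OR 4.57

report$selection$table
#>   label n_variants    or conf.low conf.high p.value   auc
#> 1 5e-04         37  1.14    0.969      1.35  0.113  0.572
#> 2 5e-05         30  1.18    0.997      1.39  0.0541 0.575
#> 3 5e-06         26  1.15    0.970      1.35  0.109  0.571
#> 4 5e-07         15  1.22    1.03       1.44  0.0185 0.588
#> 5 5e-08         10  1.23    1.04       1.45  0.0158 0.589

report$interaction
#>   term  estimate conf.low conf.high method
#> 1 reri     0.890   0.0753     1.71  delta
#> 2 ap       0.326   0.0950     0.557 delta
```

Reading this: the training set picks the 5e-8 cut-off (smallest
score-term p, largest AUC; the full table keeps the choice auditable).
In the test set one standard deviation of the selected score carries an
odds ratio of 1.18 (case–control) and a hazard ratio of 1.25
(prospective, baseline cases excluded).  Individuals with high genetic
risk *and* an unfavorable lifestyle have 4.6-fold odds relative to
low-genetic-risk/favorable-lifestyle individuals, and the positive RERI
(0.89, 95% CI 0.08–1.71) says the joint risk exceeds additivity: the
two exposures amplify each other.  `autoplot(report$grid)` draws the
3×3 grid; `report$summary` is the Table-1-style cohort description.

The methods vignette (`vignettes/prs-lifestyle-joint-risk.Rmd`)
documents the model, every convention and tie rule, what the generator
does and does not emulate, and the validation problem sizes.

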