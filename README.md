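# insulinRI

Indirect (data-mining) reference intervals for fasting insulin and the
HOMA-IR insulin-resistance index, estimated from routine laboratory data
instead of recruited healthy volunteers.

## Who this is for

Clinical-chemistry and biostatistics groups who hold LIS-style records
(demographics, anthropometrics, fasting insulin and glucose, A1C, lipids,
medication flags) and want defensible reference intervals for insulin and
HOMA-IR — markers whose right-skewed distributions and strong association
with prevalent disease make naive percentiles of routine data badly biased.

## What it does

The central 95% reference interval of the *healthy* subpopulation is
estimated from a mixed patient stream by:

1. **exclusion filtering** — BMI, glucose, A1C, triglyceride, HDL-c,
   medication, visit-count and age criteria, with a per-criterion audit
   that always conserves counts;
2. **HOMA-IR arithmetic** — `glucose[mmol/L] × insulin[μU/mL] / 22.5`,
   with unit conversions under both the WHO convention
   (1 μU/mL = 6.00 pmol/L) and the legacy reciprocal rule (÷ 0.166);
3. **the statistical core** — medcouple-adjusted outlier fences, a
   skewness/kurtosis-gated Box-Cox transform (λ picked by
   Jacobian-corrected mixture BIC), Gaussian-mixture deconvolution by EM
   with BIC model selection, truncation at posterior-responsibility
   boundaries with KDE-antimode overrides, responsibility-weighted
   nonparametric percentiles with a healthy-mass adjustment, and seeded
   percentile-bootstrap 90% CIs;
4. **sex partitioning** — the Harris–Boyd z criterion
   (`z* = 3·√(n̄/120)`) plus an SD-ratio rule, and Mann-Whitney group
   comparisons;
5. **a synthetic-cohort generator** with closed-form healthy quantiles,
   so the whole pipeline is testable against known truth without any
   patient data.

See the methods vignette
(`vignettes/indirect-reference-intervals.Rmd`) for the model, the
defaults and the reasoning behind every tunable.

## Worked example

```r
library(insulinRI)

spec   <- cohort_spec(n_subjects = 20000, seed = 11)  # 86% F, 25% contaminated
cohort <- generate_cohort(spec)

ri <- run_indirect_ri(cohort$insulin, seed = 11)
ri
#> Indirect reference interval (central 95%):
#>   2.55 - 13.67   [lower 90% CI 2.50-2.58; upper 13.59-13.73]
#>   n: 20000 input, 19996 after outliers, 18365 in window [1.14, 18.4]
#>   mixture k = 2 | box_cox lambda 0 | estimator weighted

true_healthy_quantiles(spec, "all")   # generator's known healthy 2.5/97.5
#> [1]  2.53300 13.15058

estimate_percentile_ri(cohort$insulin)  # naive percentiles, for contrast
#>     lower     upper
#>  2.65837  26.32690
```

The pipeline log-transforms (λ = 0), resolves the 75/25 healthy/
pathological mixture (k = 2), truncates where the healthy component's
posterior responsibility falls below threshold, and recovers the known
healthy bounds within a few percent — while the naive percentiles of the
same contaminated sample put the upper bound at 26.3 μU/mL, double the
truth.

An end-to-end study replica — filter, HOMA-IR, RIs for women/men/all,
partitioning verdict, Table-style report in JSON/markdown/CSV — is one
call:

```r
report <- run_study(spec, seed = 11)
render_report(report, "markdown")
```

A thin CLI over the same functions lives at `inst/scripts/run_study.R`.

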