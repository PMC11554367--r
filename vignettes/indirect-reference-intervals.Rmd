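---
title: "Indirect reference intervals for fasting insulin and HOMA-IR: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect reference intervals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulinRI)
```

## The problem

A reference interval (RI) is the central 95% of an analyte's distribution in
a healthy population; its bounds are the 2.5th and 97.5th percentiles.
Direct RI studies recruit healthy volunteers — expensive, slow, and rarely
done at adequate size. The *indirect* (a posteriori) approach instead mines
routine laboratory databases: most results produced during ordinary care are
physiological, so the healthy distribution can be isolated statistically
from the mixed patient stream.

This package implements that workflow for fasting insulin (μU/mL) and the
HOMA-IR index (`glucose[mmol/L] × insulin[μU/mL] / 22.5`), two standard
noninvasive markers of insulin resistance. Both are strongly right-skewed
and both are inflated in the very conditions (obesity, diabetes, metabolic
syndrome, dyslipidemia, hypertension) that bring patients to the laboratory,
which is exactly why naive percentiles of routine data overestimate the
upper reference limit and why the statistical machinery below exists.

## The workflow

1. **Exclusion filtering** (`apply_exclusions()`). Records are removed when
   BMI < 18.5 or ≥ 25 kg/m², glucose ≥ 100 mg/dL, A1C ≥ 5.7%,
   triglycerides ≥ 150 mg/dL, HDL-c < 50 (women) / 40 (men) mg/dL, any
   antidiabetic / lipid-lowering / antihypertensive medication is reported,
   more than two yearly exams were taken, or age falls outside 20–60 years.
   Inclusion is the strict complement of each exclusion threshold (glucose
   99 is retained, HDL exactly at the minimum is retained). Each excluded
   record is attributed to the *first* failing criterion in a configurable
   order — the simplest accounting that makes the audit counts sum exactly
   to the number excluded. Missing required fields exclude a record rather
   than being imputed, mirroring mandatory-field LIS extraction. The filter
   is deliberately imperfect: thresholds on a handful of analytes cannot
   remove every unhealthy subject, which is the premise for the
   deconvolution stage.

2. **Outlier removal** (`detect_outliers()`). Medcouple-adjusted boxplot
   fences, `[Q1 − c·e^(−4·MC)·IQR, Q3 + c·e^(+3·MC)·IQR]` for medcouple
   MC ≥ 0 (exponents swap for MC < 0). The asymmetric adjustment is needed
   because symmetric Tukey fences mass-delete the long upper tail of a
   right-skewed analyte. We set the multiplier `c = 3` ("far out" fences)
   rather than the classical 1.5: upward contamination inflates the
   medcouple estimate, and with `c = 1.5` the shrunken lower fence
   `Q1 − 1.5·e^(−4·MC)·IQR` then lands *inside* the healthy lower tail. On
   the default synthetic cohort the 1.5-multiplier fences delete about 3%
   of the sample, almost all of it healthy-range data just below the lower
   reference limit — the worst possible place to delete from — and the
   truncated shapes they leave behind also derail the mixture's component
   count. With `c = 3` the stage removes gross errors (a 10⁶ entry, unit
   mix-ups) and essentially nothing else; the multiplier and both exponents
   are exposed in `ri_control()`.

3. **Transformation** (`select_transform()`). If |skewness| ≤ 0.5 and
   |excess kurtosis| ≤ 1 the data are used as-is. Otherwise a Box-Cox
   exponent is chosen from the coarse grid {−1, −0.5, 0, 0.5, 1}. The
   default selection rule fits Gaussian mixtures on each candidate scale
   and picks the λ minimizing the Jacobian-corrected BIC — i.e. the scale
   on which the data look most like a Gaussian *mixture*. The textbook
   rule (λ minimizing marginal skewness, available as
   `lambda_rule = "skewness"`) has a structural defect in exactly the
   situation this package targets: when a lognormal healthy component is
   contaminated from above, the log-scale margin is still right-skewed, so
   the skewness rule overshoots to λ = −0.5 and bends the healthy
   component *away* from normality; the downstream mixture then needs
   spurious extra components to absorb the distortion. Both rules agree on
   clean unimodal samples (a lognormal sample yields λ = 0 under either).
   The BIC scan runs on at most 4,000 evenly spaced order statistics with
   light EM settings, so it costs a fraction of the final fit.

4. **Mixture deconvolution** (`fit_mixture()`). Univariate Gaussian
   mixtures, k = 1…4, fitted by EM (relative log-likelihood tolerance
   1e−8, ≤ 1,000 iterations, 5 seeded restarts from jittered
   quantile-spread initializations), with BIC choosing k. The EM
   log-likelihood is monotone by construction and can be asserted per
   iteration (`check_monotone`). k ≤ 4 reflects what a routine cohort can
   support: one healthy component plus up to three pathological strata.

5. **Truncation** (`choose_truncation()`). The healthy component is the
   highest-weight component among those nearest the global KDE mode
   (Gaussian kernel, Silverman bandwidth, 512-point grid). The window
   grows outward from its mean while the component's posterior
   responsibility stays ≥ 0.1; a side where responsibility never drops
   below threshold ends at the data extreme, and KDE antimodes flanking
   the healthy mode override responsibility edges when they fall inside
   them (the valley between subpopulations is the natural cut). With
   k = 1 the window is the whole range. The edge provenance
   (responsibility / antimode / data extreme) is recorded per side.

6. **Percentile estimation**. The package's default estimator is the
   responsibility-weighted rank percentile: in-window values are weighted
   by their posterior probability of belonging to the healthy component,
   and the weighted rank `p(W+1)` quantile is taken at probabilities
   rescaled by the healthy-component mass the window cuts off (computed
   from the fitted component). The rescaling matters: the 97.5th
   percentile *of a truncated sample* is not the 97.5th percentile of the
   healthy component — with a window that keeps 95% of the healthy mass,
   plain truncated percentiles sit several percent below the true upper
   limit no matter how much data there is, an error the weighting and
   mass adjustment remove at the population level. The plain unweighted
   truncated percentile (`estimator = "plain"`, and always used when
   k = 1) is retained both as the classical reference behaviour and
   because with one component and a full-range window the two coincide
   exactly with `quantile(type = 6)` of the cleaned sample. A
   responsibility threshold of 0.1 (not 0.5) is the default for the same
   reason: the window must retain essentially all of the healthy tail for
   the upper limit to be estimable from within it; with heavy overlap the
   0.5-threshold window ends below the healthy 97.5th percentile, which
   no within-window estimator can repair.

7. **Confidence intervals** (`bootstrap_ci()`). 90% percentile-bootstrap
   intervals from 1,000 resamples of the in-window values (pairs of value
   and weight, for the weighted estimator). The original study cites
   adapted CI methods without formulas; the seeded percentile bootstrap
   is our declared stand-in and is labelled as such in reports.

8. **Partitioning** (`harris_boyd()`). Sex-specific intervals are
   warranted when `z = |x̄₁−x̄₂| / √(s₁²/n₁ + s₂²/n₂)` exceeds
   `z* = 3·√(n̄/120)` (n̄ the mean group size) or when the SD ratio
   reaches 1.5. The criterion assumes near-Gaussian groups, so
   `run_study()` applies it on the jointly transformed scale; a raw-scale
   call is available by passing raw values. The `z*` form is the standard
   sample-size scaling of the classical criterion and is configurable.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` creates
LIS-like cohorts in which the truth is known, so every stage can be scored.
The defaults describe the study conditions the workflow is designed for:

* 20,000 subjects, 86% women, ages 20–60 uniform — the post-filter sex
  imbalance of the motivating cohort;
* healthy fasting insulin lognormal per sex, `logmean = log(5.8)` (women)
  / `log(5.6)` (men), `logsd = 0.42` — median ≈ 5.8 μU/mL and central 95%
  ≈ 2.5–13.2 μU/mL, echoing the published healthy summaries (calibration
  targets, not asserted equalities);
* 25% pathological contamination with insulin drawn from
  `lognormal(log(14.5), 0.45)` — a 2.5× median shift, overlapping the
  healthy tail rather than cleanly separated from it;
* healthy glucose 89 ± 6 mg/dL, BMI 22.8 ± 2.6 kg/m², A1C 5.3 ± 0.25%,
  triglycerides lognormal with median 75 mg/dL, HDL-c 62 ± 10 (F) /
  52 ± 8 (M) mg/dL; pathological members have glucose and BMI ×1.25,
  A1C ×1.13, triglycerides ×1.9 and HDL ×0.85, so *most but not all*
  cross an exclusion threshold;
* medication reported by 50% of pathological and 5% of healthy subjects;
  yearly exam counts drawn 1–4 with pathology-weighted probabilities;
* healthy log-insulin and glucose share a latent Gaussian factor
  (ρ = 0.3), so HOMA-IR varies realistically rather than as a product of
  independent draws (the value is our choice; the source study does not
  report one).

The generator does **not** simulate assay analytical error, fasting
non-compliance, seasonal effects, age trends in the means, or repeated
visits with within-subject correlation. Passing recovery tests therefore
demonstrate that the statistical machinery isolates a lognormal healthy
component under overlapping contamination at realistic sample sizes — not
that it is robust to every artefact of real LIS data.

## Numerical choices and degenerate inputs

* EM: tolerance 1e−8 on relative log-likelihood change, variance floored
  at 1e−12, density floored at 1e−300 before logs; non-convergence on all
  restarts returns the best model with `converged = FALSE` and a warning.
* The medcouple uses the exact O(n²) kernel up to n = 5,000 and evenly
  spaced order statistics above that (deterministic; the thinning error is
  far below sampling noise). Pairs tied at the median contribute 0 —
  adequate for continuous analytes.
* Rank percentiles use `rank = p(n+1)` with linear interpolation, clamped
  to [1, n] (= `quantile` type 6); the weighted variant interpolates in
  cumulative weight at `rank = p(W+1)` and reduces exactly to the plain
  rule at unit weights.
* All-equal samples select the identity transform with a warning;
  `run_indirect_ri()` refuses < 20 values at the outlier stage, < 100 at
  the mixture stage, and < 120 inside the window (the conventional
  nonparametric-RI minimum), and warns below 500.
* `run_indirect_ri()` sorts its input first, making results exactly
  permutation-invariant; all randomness (EM restarts, bootstrap) flows
  through the seed argument.

## Validation scale

The shipped tests exercise recovery at the study conditions
(n = 20,000, ten seeds), bootstrap coverage on 200 replications of
n = 20,000 normal samples, partitioning behaviour across 100 cohort seeds,
and property checks (audit conservation, idempotence, permutation
invariance, affine equivariance, EM monotonicity) at n between 300 and
50,000. Those sizes were chosen as the smallest at which the Monte Carlo
noise of a 97.5th-percentile estimate (≈ 3% relative at n = 20,000 under
contamination) is clearly separated from the effects being asserted.

## Known limitations

* The healthy component must be the dominant mode. Cohorts where
  pathology is the majority, or where the healthy component is itself a
  mixture of well-separated strata, will mis-identify the component.
* The truncation-window mass adjustment uses the *fitted* healthy
  component, so a badly misspecified mixture propagates into the bounds;
  the per-side window provenance and the BIC trace in the result object
  are the diagnostic handles.
* Published intervals from the motivating study are not reproducible here
  because its record-level data are not deposited; the package validates
  against synthetic ground truth and the study's printed arithmetic
  instead.
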