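---
title: "Methods: incremental biomarker value over a baseline risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: incremental biomarker value over a baseline risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incrisk)
```

`incrisk` quantifies how much a panel of circulating biomarkers adds to an
established baseline cardiovascular risk score when predicting a dichotomized
coronary artery calcification (CAC) outcome. The statistical machinery —
logistic regression by iteratively reweighted least squares (IRLS),
Mann–Whitney AUC with DeLong variance, the paired DeLong test, two-category
net reclassification improvement (NRI), integrated discrimination improvement
(IDI), and Hosmer–Lemeshow (H–L) calibration — is implemented inside this
package; `stats::glm()` and `pROC` appear only as independent cross-checks
inside the test suite. This vignette records the methodological conventions
and the design choices behind the synthetic cohort generator.

## The synthetic cohort

Patient-level data from studies of this design are not publicly available, so
the package ships a generator whose defaults emulate the study conditions: a
rheumatoid arthritis cohort of 561 patients, split roughly 50:50 into training
and validation halves; CAC prevalences of approximately 55% (CAC > 0), 30%
(CAC > 100) and 16% (CAC > 300); a panel of 20 ELISA markers measured in
everyone plus 3 mass-spectrometric (MRM) peptides measured in a 140-patient
subset; and a baseline (ACC/AHA-style) risk score whose stand-alone AUC for
CAC > 100 is about 0.774.

### Two-part Agatston model

The Agatston score is zero-inflated and strongly right-skewed, so it is drawn
from a two-part model driven by a standardized latent liability $L$:

* $P(\mathrm{CAC} > 0) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 L)$, and
* among positives, $\log(\mathrm{CAC}) \sim N(\mu_0 + \mu_1 L, \sigma^2)$.

`calibrate_cac_intercepts()` tunes $\gamma_0$ (bisection on the zero part)
and then $\mu_0$ (root finding on the positive part) so the three prevalence
targets are met within ±1 percentage point on a large probe cohort, and it
raises a classed calibration error, reporting the achieved values, when the
targets are jointly infeasible for the remaining fixed parameters.

One consequence of prioritizing the three tail probabilities: a lognormal
positive part cannot simultaneously reproduce a very low median Agatston
score among positive patients together with 30%/16% exceedance at 100/300.
The prevalence triple is what the downstream analyses consume, so the median
is deliberately not a calibration target.

### Liability decomposition and marker loadings

The latent liability is split into a traditional-covariate component and a
biology component, $L = \sqrt{h}\,C + \sqrt{1-h}\,B$ with $h = 0.5$. The
baseline risk score is a logistic function of (noisy) $C$ only, while marker
signal loads on the full liability $L$. This is what makes *incremental*
value possible at realistic magnitudes: a score that already tracked all of
$L$ would leave markers nothing to add, and simulations with a single shared
latent variable capped the achievable IDI far below the emulated study's
reported values.

Each log-marker is built as $z = \lambda L + \sqrt{0.2(1-\lambda^2)}\,U +
\sqrt{0.8(1-\lambda^2)}\,\varepsilon$, where $U$ is a factor shared across
markers and $\lambda = 0.95\tanh(0.45\,e)$ maps a marker's `effect` size $e$
to a bounded loading. Placing the shared factor on the *residual* scale keeps
inert markers correlated at 0.2 with each other (assay batch behaviour)
without information-capping the strong markers. Effect sizes default to 3.0
for the four report-panel cytokines, 1.5 for four secondary ELISA markers,
2.8–3.4 for the three MRM peptides, and 0 for twelve inert ELISA markers.
These values were sized so that the full pipeline reproduces the qualitative
headline pattern (positive, significant validation IDI for the combined model
at CAC > 100 in a clear majority of seeds) — they are package choices, not
published quantities.

MRM missingness is missing-completely-at-random at the patient level: a fixed
fraction (140/561 by default) of patients carries all three peptides, everyone
else carries none. Real subset selection may be informative; this is a known
simplification.

## Statistical conventions

* **NRI (two categories, threshold 0.5).** The index is the *sum* of the net
  proportion of events reclassified upward and the net proportion of
  non-events reclassified downward. Published displays of this formula
  sometimes join the two brackets with a minus sign; that sign is
  inconsistent with the accompanying prose and with the reported values, and
  the sum form is implemented here. A predicted probability exactly at the
  threshold is high risk (`p >= threshold`). The standard error is the usual
  asymptotic binomial form.
* **IDI.** Difference in discrimination slopes, equivalently the integral of
  sensitivity minus the integral of one-minus-specificity over all
  thresholds (verified numerically in the tests). When the paired
  probability differences have zero sampling variance but a nonzero mean —
  which happens on constructed total-reclassification examples — the test
  degenerates; `incrisk` emits a warning and reports p = 0 rather than
  erroring, so analytic extreme cases remain computable.
* **DeLong.** AUCs are midrank Mann–Whitney statistics; variances and the
  paired test come from the structural-component (placement) covariance. A
  zero-variance difference with unequal AUCs is an error.
* **Hosmer–Lemeshow.** Cases are sorted by predicted probability into
  near-equal groups (deciles by default); tied probabilities never straddle a
  boundary (the lower group absorbs them); the statistic is referred to
  $\chi^2_{G-2}$. Groups emptied by tie handling, or groups with expected
  events equal to 0 or to the group size, raise an error suggesting fewer
  groups.
* **Selection.** Markers are log-transformed and z-standardized with
  *training-half* means and SDs throughout. The univariate screen flags
  markers at $\alpha = 0.05$; stepwise selection (forward with backward
  elimination, Wald p-values, enter 0.05 / stay 0.10, deterministic
  tie-breaking) runs separately within the significant ELISA candidates and
  within the significant MRM candidates, on the training half, at the first
  configured outcome threshold. The exact selection rules used in the
  emulated study are not fully specified publicly; these defaults are
  conventional choices and all of them are configurable.
* **Separation.** IRLS detects complete or quasi-complete separation
  (diverging coefficients with a non-vanishing gradient, or a perfect fit)
  and raises a classed error. The pipeline refits such models with a small
  ridge penalty (0.01, intercept unpenalized) and records that the fallback
  was used; MRM-subset models at study scale (n ≈ 70 per half) trigger this
  occasionally.

## A worked run

```{r run, eval = FALSE}
cfg <- analysis_config(params = default_params(), split_seed = 42)
bundle <- run_analysis(cfg)
print(bundle$comparisons[["cac100_validation_reference+cytokines+MRM"]])
render_table2(bundle, "report")
```

The bundle holds one `compare_models()` result per outcome threshold, cohort
half and extended model, reference-model AUC and calibration per threshold
and half, the screen and selection traces, and a deterministic configuration
hash; `render_table2()` writes the canonical discrimination /
reclassification / calibration table per threshold as CSV and JSON.

## Simulation sizes in the test suite

The acceptance-style tests run the documented designs at full size (1,000
oracle instances for the AUC, 1,000-rep type-I-error simulations for the
paired DeLong test and H–L, 500-rep null-marker and parameter-recovery
studies, and a 100-seed full-pipeline replication); the whole suite completes
in a few minutes on one CPU. Where exploratory work used larger probes, the
committed sizes were chosen to keep Monte-Carlo error comfortably inside the
asserted tolerances.

## Limitations

* Prevalence targets are matched; the median positive Agatston score is not
  (see above).
* MRM missingness is MCAR; informative subset selection is not modelled.
* Covariates enter the baseline score through a fixed linear index; the
  generator does not re-implement the pooled cohort equations.
* The generator's defaults are calibrated to a single study design; other
  cohorts require explicit `synthetic_params()`.
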