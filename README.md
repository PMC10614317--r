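# incrisk

Incremental value of circulating biomarkers added to a baseline
cardiovascular risk score for predicting dichotomized coronary artery
calcification (CAC).

Patients with rheumatoid arthritis carry excess cardiovascular risk that
general-population scores under-capture. A recurring study design asks
whether blood biomarkers (ELISA panels, mass-spectrometric MRM peptides)
improve on an ACC/AHA-style risk score for predicting subclinical
atherosclerosis, operationalized as CAC above 100 or 300 Agatston units.
`incrisk` implements that complete workflow:

* **Synthetic cohort generator** — a two-part (zero-inflated lognormal)
  Agatston model driven by a latent liability that is only partially tracked
  by the baseline score, with a configurable biomarker panel and
  subset-measured MRM peptides; `calibrate_cac_intercepts()` hits target
  prevalences to within ±1 percentage point.
* **Cohort I/O** — CSV plus a JSON/YAML data dictionary with strict
  validation, dichotomization, random (optionally stratified) train/validation
  splits and complete-case handling.
* **Risk models** — logistic regression by IRLS with monotone-likelihood step
  halving, separation detection, and an optional ridge fallback; univariate
  marker screening; deterministic stepwise selection; the four nested model
  specifications of the canonical report.
* **Incremental-value metrics** — Mann–Whitney AUC with DeLong variance, the
  paired DeLong test, two-category NRI at a fixed risk threshold, IDI, and
  Hosmer–Lemeshow calibration. All of these are implemented in this package;
  `glm()` and `pROC` are used only as independent cross-checks in the tests.
* **Reporting** — `run_analysis()` returns a bundle of every comparison;
  `write_bundle()` and `render_table2()` serialize it to JSON/CSV; a thin
  command-line wrapper lives at `inst/cli/incrisk.R`.

## Worked example

```r
library(incrisk)

cfg <- analysis_config(params = default_params(), split_seed = 42)
bundle <- run_analysis(cfg)
writeLines(bundle$log)
#> load: 561 patients, 20 ELISA + 3 MRM markers
#> split: 281 training / 280 validation
#> screen: 11/23 markers significant at alpha=0.05 (CAC > 100, training)
#> selection (ELISA): retained osteopontin, ccl18, cystatin_c
#> selection (MRM): retained SerD1_NFGYTLR
#> fit: reference+cytokines, CAC > 100, n=281, events=82
#> fit: reference+MRM, CAC > 100, n=65, events=21
#> fit: reference+cytokines+MRM, CAC > 100, n=65, events=21
#> fit: reference+cytokines, CAC > 300, n=281, events=45
#> fit: reference+MRM, CAC > 300, n=65, events=10
#> fit: reference+cytokines+MRM, CAC > 300, n=65, events=10

print(bundle$comparisons[["cac100_validation_reference+cytokines+MRM"]])
#> ACC/AHA + cytokines + MRM vs ACC/AHA | CAC > 100 | validation cohort (n = 75, events = 29)
#>   AUC reference: 0.728 (0.611-0.845)   AUC reference+cytokines+MRM: 0.876 (0.797-0.955)   DeLong p = 0.00284
#>   NRI 0.323 (p = 0.0122)   IDI 0.303 (p = 8.6e-07)
#>   H-L (new model) chi2 = 18.46, p = 0.018

print(bundle$reference[["cac100_training"]]$auc)
#> AUC 0.796 (95% CI 0.741-0.850), 82 events / 199 non-events

render_table2(bundle, "report")   # report/table2_cac_gt_100.{csv,json}, ..._300.{csv,json}
```

The same pipeline runs from the command line:

```sh
Rscript inst/cli/incrisk.R simulate  --seed 3 --n 561 --out cohort.csv
Rscript inst/cli/incrisk.R replicate --seed 3 --out report/
```

Lower-level pieces are exported individually — `generate_cohort()`,
`split_cohort()`, `fit_logistic()`, `univariate_screen()`,
`stepwise_select()`, `auc_mann_whitney()`, `delong_paired_test()`, `nri()`,
`idi()`, `hosmer_lemeshow()`, `compare_models()` — see the help pages and
`vignettes/incremental-value-methods.Rmd` for the methodological
conventions (NRI sum form, threshold-boundary handling, Hosmer–Lemeshow tie
rules, separation fallback, generator design).

## License

MIT (see `LICENSE`).
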