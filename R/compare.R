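#' Compare a new model against the reference on a common case set
#'
#' Evaluates discrimination (AUCs with DeLong CIs and the paired DeLong
#' test), reclassification (two-category NRI at the configured threshold and
#' IDI) and calibration (per-model Hosmer-Lemeshow) for a reference and an
#' extended model on the identical complete-case subset of `table`. Both
#' fits must have been estimated on the same cases (enforce with
#' [complete_case_subset()] on the union of the two predictor sets); when
#' `table` is a validation half, the probabilities come from the
#' training-fit coefficients applied to the validation cases.
#'
#' @param fit_ref,fit_new [fit_logistic()] results sharing a case set.
#' @param table the evaluation cohort (training or validation subset).
#' @param outcome an [dichotomize()] result aligned to `table`.
#' @param cohort_label `"training"` or `"validation"` (free text allowed).
#' @param nri_threshold risk threshold for the NRI, default 0.5.
#' @param hl_groups Hosmer-Lemeshow groups, default 10.
#' @return An object of class `incrisk_comparison`.
#' @export
compare_models <- function(fit_ref, fit_new, table, outcome,
                           cohort_label = "training",
                           nri_threshold = 0.5, hl_groups = 10) {
  if (!inherits(fit_ref, "incrisk_logit") || !inherits(fit_new, "incrisk_logit"))
    config_error("compare_models: fits must be incrisk_logit objects")
  if (!is.null(fit_ref$patient_id) && !is.null(fit_new$patient_id) &&
      !setequal(fit_ref$patient_id, fit_new$patient_id))
    data_error("compare_models: the two fits were not estimated on the same cases")
  preds <- union(fit_ref$spec$predictors, fit_new$spec$predictors)
  keep <- stats::complete.cases(as.data.frame(table)[, preds, drop = FALSE])
  if (!any(keep))
    data_error("compare_models: no complete cases in the evaluation table")
  sub <- table[keep, , drop = FALSE]
  y <- outcome_vector(outcome, nrow(table))[keep]
  if (sum(y) < 1 || sum(1 - y) < 1)
    data_error("compare_models: evaluation subset has a single outcome class")
  p_ref <- predict(fit_ref, sub)
  p_new <- predict(fit_new, sub)
  dl <- delong_paired_test(p_ref, p_new, y)
  structure(list(
    threshold = if (inherits(outcome, "incrisk_outcome")) outcome$threshold else NA_real_,
    cohort = cohort_label,
    spec_ref = fit_ref$spec, spec_new = fit_new$spec,
    auc_ref = auc_mann_whitney(p_ref, y),
    auc_new = auc_mann_whitney(p_new, y),
    delong = dl, delong_p = dl$p,
    nri = nri(p_ref, p_new, y, threshold = nri_threshold),
    idi = idi(p_ref, p_new, y),
    hl_ref = hl_or_na(p_ref, y, hl_groups),
    hl_new = hl_or_na(p_new, y, hl_groups),
    n_common_cases = nrow(sub),
    n_events = sum(y)
  ), class = "incrisk_comparison")
}

# H-L can legitimately fail on tiny/degenerate evaluation sets (a group with
# all or no expected events); report NA rather than aborting the comparison.
hl_or_na <- function(p, y, n_groups) {
  tryCatch(hosmer_lemeshow(p, y, n_groups = n_groups),
           incrisk_error = function(e) NULL)
}

#' @export
print.incrisk_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s | CAC > %g | %s cohort (n = %d, events = %d)\n",
              x$spec_new$label, x$spec_ref$label, x$threshold, x$cohort,
              x$n_common_cases, x$n_events))
  cat(sprintf("  AUC %s: %.3f (%.3f-%.3f)   AUC %s: %.3f (%.3f-%.3f)   DeLong p = %.3g\n",
              x$spec_ref$name, x$auc_ref$auc, x$auc_ref$ci95[1], x$auc_ref$ci95[2],
              x$spec_new$name, x$auc_new$auc, x$auc_new$ci95[1], x$auc_new$ci95[2],
              x$delong_p))
  cat(sprintf("  NRI %.3f (p = %.3g)   IDI %.3f (p = %.3g)\n",
              x$nri$nri, x$nri$p, x$idi$idi, x$idi$p))
  if (!is.null(x$hl_new))
    cat(sprintf("  H-L (new model) chi2 = %.2f, p = %.3g\n", x$hl_new$chi2, x$hl_new$p))
  invisible(x)
}
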