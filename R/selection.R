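#' Univariate biomarker screen against a dichotomized CAC outcome
#'
#' Each marker is log-transformed and z-standardized by default, then entered
#' alone (plus optional adjustment covariates) in a logistic regression on
#' the outcome; the odds ratio per standard deviation, its Wald 95% CI and
#' p-value are reported, and markers with `p < alpha` are flagged
#' significant. Markers that are constant, or whose fit fails (separation,
#' non-convergence), are flagged non-estimable and excluded from the
#' significance list. Each marker uses its own complete cases, so markers
#' measured only in a patient subset are screened within that subset.
#'
#' @param table cohort table.
#' @param outcome an [dichotomize()] result aligned to `table`.
#' @param markers character vector of marker columns.
#' @param alpha significance level, default 0.05.
#' @param transform `"log_z"` (default), `"z"` or `"identity"`.
#' @param adjust_for optional covariate columns added to every marker model.
#' @return An object of class `incrisk_screen`: data.frame with one row per
#'   marker (`or_per_sd`, `ci_lo`, `ci_hi`, `p`, `n`, `estimable`,
#'   `significant`).
#' @export
univariate_screen <- function(table, outcome, markers, alpha = 0.05,
                              transform = "log_z", adjust_for = character()) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    config_error("univariate_screen: 'alpha' must lie in (0,1)")
  absent <- setdiff(c(markers, adjust_for), names(table))
  if (length(absent))
    data_error(sprintf("univariate_screen: column(s) not in table: %s",
                       paste(absent, collapse = ", ")))
  y_all <- outcome_vector(outcome, nrow(table))
  rows <- lapply(markers, function(mk) {
    keep <- stats::complete.cases(table[, c(mk, adjust_for), drop = FALSE])
    sub <- table[keep, , drop = FALSE]
    y <- y_all[keep]
    base <- list(marker = mk, n = nrow(sub), or_per_sd = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                 estimable = FALSE)
    if (length(unique(sub[[mk]])) < 2L || length(unique(y)) < 2L)
      return(base)
    res <- tryCatch({
      sub <- transform_markers(sub, mk, method = transform)
      fit <- fit_logistic(sub, y, c(mk, adjust_for))
      ct <- coef_table(fit)
      i <- match(mk, ct$term)
      list(marker = mk, n = nrow(sub),
           or_per_sd = exp(ct$estimate[i]),
           ci_lo = exp(ct$estimate[i] - 1.959964 * ct$se[i]),
           ci_hi = exp(ct$estimate[i] + 1.959964 * ct$se[i]),
           p = ct$p[i], estimable = TRUE)
    }, incrisk_error = function(e) base)
    res
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$significant <- out$estimable & !is.na(out$p) & out$p < alpha
  structure(out, alpha = alpha, class = c("incrisk_screen", "data.frame"))
}

#' @export
print.incrisk_screen <- function(x, ...) {
  cat(sprintf("Univariate screen (alpha = %g): %d/%d markers significant\n",
              attr(x, "alpha"), sum(x$significant), nrow(x)))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

wald_p_for <- function(fit, term) {
  ct <- coef_table(fit)
  ct$p[match(term, ct$term)]
}

#' Stepwise logistic variable selection (forward with backward elimination)
#'
#' Iteratively adds the candidate with the smallest Wald p-value below
#' `p_enter`, then drops any included term whose Wald p-value exceeds
#' `p_remove`, until no addition or removal is possible. Ties are broken on
#' the p-value, then lexicographically on the name, so the procedure is
#' deterministic. Candidates whose addition makes the fit fail (separation,
#' collinearity) are skipped at that step.
#'
#' @param table cohort table, complete in the candidate columns.
#' @param outcome an [dichotomize()] result or 0/1 vector.
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter entry threshold (default 0.05); must be `<= p_remove`.
#' @param p_remove removal threshold (default 0.10).
#' @param forced predictors kept in every model and never dropped.
#' @return An [model_spec()] named `"stepwise"` with the selected predictors
#'   (possibly empty), with the selection trace attached as attribute
#'   `"trace"`.
#' @export
stepwise_select <- function(table, outcome, candidates, p_enter = 0.05,
                            p_remove = 0.10, forced = character()) {
  if (p_enter > p_remove)
    config_error("stepwise_select: p_enter must be <= p_remove")
  absent <- setdiff(c(candidates, forced), names(table))
  if (length(absent))
    data_error(sprintf("stepwise_select: column(s) not in table: %s",
                       paste(absent, collapse = ", ")))
  y <- outcome_vector(outcome, nrow(table))
  selected <- character()
  trace <- list()
  repeat {
    pool <- sort(setdiff(candidates, selected))
    entry_p <- vapply(pool, function(cand) {
      tryCatch(wald_p_for(fit_logistic(table, y, c(forced, selected, cand)), cand),
               incrisk_error = function(e) NA_real_)
    }, 0)
    entry_p <- entry_p[!is.na(entry_p)]
    added <- FALSE
    if (length(entry_p) && min(entry_p) < p_enter) {
      best <- names(entry_p)[order(entry_p, names(entry_p))][1]
      selected <- c(selected, best)
      trace[[length(trace) + 1L]] <- list(action = "add", term = best,
                                          p = unname(entry_p[best]))
      added <- TRUE
    }
    # backward pass
    repeat {
      if (!length(selected)) break
      fit <- tryCatch(fit_logistic(table, y, c(forced, selected)),
                      incrisk_error = function(e) NULL)
      if (is.null(fit)) { # joint fit failed: drop the most recent addition
        dropped <- selected[length(selected)]
        selected <- selected[-length(selected)]
        trace[[length(trace) + 1L]] <- list(action = "drop", term = dropped, p = NA_real_)
        next
      }
      ps <- vapply(selected, function(tm) wald_p_for(fit, tm), 0)
      if (max(ps) <= p_remove) break
      worst <- names(ps)[order(-ps, names(ps))][1]
      selected <- setdiff(selected, worst)
      trace[[length(trace) + 1L]] <- list(action = "drop", term = worst,
                                          p = unname(ps[worst]))
    }
    if (!added) break
  }
  spec <- model_spec("stepwise", c(forced, selected))
  attr(spec, "trace") <- trace
  spec
}

#' Build the four nested model specifications of the incremental-value report
#'
#' Returns the reference model (baseline risk score alone) and its three
#' extensions: plus the ELISA ("cytokine") panel, plus the MRM panel, and
#' plus both, mirroring the canonical report rows ACC/AHA,
#' ACC/AHA + cytokines, ACC/AHA + MRM, ACC/AHA + cytokines + MRM.
#'
#' @param selected_elisa character vector of ELISA panel columns.
#' @param selected_mrm character vector of MRM panel columns.
#' @param reference_col baseline score column name, default
#'   `"baseline_score"`.
#' @return list of four [model_spec()] objects.
#' @export
table2_model_specs <- function(selected_elisa, selected_mrm,
                               reference_col = "baseline_score") {
  if (length(intersect(selected_elisa, selected_mrm)))
    config_error("table2_model_specs: ELISA and MRM panels must not overlap")
  if (!length(selected_mrm))
    warning("table2_model_specs: empty MRM panel; the MRM and combined specs coincide with the ELISA spec")
  if (!length(selected_elisa))
    warning("table2_model_specs: empty ELISA panel; the cytokine and combined specs coincide")
  list(
    model_spec("reference", reference_col, label = "ACC/AHA"),
    model_spec("reference+cytokines", c(reference_col, selected_elisa),
               label = "ACC/AHA + cytokines"),
    model_spec("reference+MRM", c(reference_col, selected_mrm),
               label = "ACC/AHA + MRM"),
    model_spec("reference+cytokines+MRM",
               c(reference_col, selected_elisa, selected_mrm),
               label = "ACC/AHA + cytokines + MRM")
  )
}
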