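#' Configuration for a full incremental-value analysis
#'
#' @param params [synthetic_params()] to simulate a cohort, or `NULL` when
#'   reading from CSV.
#' @param cohort_csv,dictionary paths to a cohort CSV and its data
#'   dictionary (used when `params` is `NULL`).
#' @param split_ratio training proportion (default 0.5).
#' @param split_seed seed for the random split.
#' @param split_sizes optional explicit `c(n_training, n_validation)`.
#' @param thresholds Agatston dichotomization points, positive and
#'   increasing (default `c(100, 300)`).
#' @param alpha significance level for the univariate screen (default 0.05).
#' @param nri_threshold risk threshold for the NRI (default 0.5).
#' @param hl_groups Hosmer-Lemeshow groups (default 10).
#' @param p_enter,p_remove stepwise entry/stay thresholds (defaults
#'   0.05/0.10).
#' @param transform marker transform for screening and modelling
#'   (default `"log_z"`).
#' @param panel_elisa,panel_mrm optional fixed panels overriding the
#'   training-half selection.
#' @param refit_validation refit models on the validation half instead of
#'   applying training coefficients (default `FALSE`).
#' @param ridge_fallback ridge penalty used to refit a model whose
#'   unpenalized fit hits complete separation (default 0.01; set to 0 to
#'   propagate separation errors).
#' @param output_dir optional directory; when given, [run_analysis()] writes
#'   the bundle JSON and the per-outcome report tables there.
#' @return list of class `incrisk_config`.
#' @export
analysis_config <- function(params = NULL, cohort_csv = NULL, dictionary = NULL,
                            split_ratio = 0.5, split_seed = 1L,
                            split_sizes = NULL, thresholds = c(100, 300),
                            alpha = 0.05, nri_threshold = 0.5, hl_groups = 10,
                            p_enter = 0.05, p_remove = 0.10,
                            transform = "log_z",
                            panel_elisa = NULL, panel_mrm = NULL,
                            refit_validation = FALSE, ridge_fallback = 0.01,
                            output_dir = NULL) {
  if (is.null(params) && is.null(cohort_csv))
    config_error("analysis_config: provide either 'params' or 'cohort_csv'")
  if (!is.numeric(thresholds) || any(thresholds <= 0) ||
      any(diff(thresholds) <= 0) && length(thresholds) > 1)
    config_error("analysis_config: 'thresholds' must be positive and increasing")
  if (alpha <= 0 || alpha >= 1)
    config_error("analysis_config: 'alpha' must lie in (0,1)")
  if (nri_threshold <= 0 || nri_threshold >= 1)
    config_error("analysis_config: 'nri_threshold' must lie in (0,1)")
  structure(list(
    params = params, cohort_csv = cohort_csv, dictionary = dictionary,
    split_ratio = split_ratio, split_seed = split_seed,
    split_sizes = split_sizes, thresholds = thresholds, alpha = alpha,
    nri_threshold = nri_threshold, hl_groups = hl_groups,
    p_enter = p_enter, p_remove = p_remove, transform = transform,
    panel_elisa = panel_elisa, panel_mrm = panel_mrm,
    refit_validation = refit_validation, ridge_fallback = ridge_fallback,
    output_dir = output_dir
  ), class = "incrisk_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(unclass(config)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# Unpenalized fit, falling back to a ridge refit when the model separates
# (common for the MRM-subset models at study scale). The fallback is
# recorded in the returned object.
fit_with_fallback <- function(table, outcome, spec, ridge_fallback) {
  tryCatch(
    fit_logistic(table, outcome, spec),
    incrisk_separation_error = function(e) {
      if (ridge_fallback <= 0) stop(e)
      fit <- fit_logistic(table, outcome, spec,
                          options = list(ridge = ridge_fallback))
      fit$ridge_fallback_used <- TRUE
      fit
    }
  )
}

#' Run the full incremental-value study replica
#'
#' Pipeline: load or simulate the cohort; split it into training and
#' validation halves; on the training half, screen the markers univariately
#' and run stepwise selection within the significant ELISA and (separately)
#' MRM candidates; build the four nested model specifications; fit them on
#' the training half; and evaluate every comparison (new vs reference) on
#' the training and on the validation half (validation probabilities from
#' the training-fit coefficients unless `refit_validation`) for every
#' outcome threshold. Marker columns are log-transformed and z-standardized
#' with training-half means and SDs throughout.
#'
#' @param config an [analysis_config()].
#' @return An object of class `incrisk_bundle` with elements `comparisons`
#'   (one [compare_models()] result per outcome x half x non-reference
#'   spec), `reference` (reference-model AUC and calibration per outcome x
#'   half), `screen`, `selection`, `specs`, `meta`, and `log`.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "incrisk_config"))
    config_error("run_analysis: 'config' must be an analysis_config()")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$params)) generate_cohort(config$params)
    else read_cohort(config$cohort_csv, config$dictionary)
  })
  dict <- attr(cohort, "dictionary")
  elisa_all <- dict$column[dict$role == "marker_elisa"]
  mrm_all <- dict$column[dict$role == "marker_mrm"]
  score_col <- dict$column[dict$role == "score"]
  note("load: %d patients, %d ELISA + %d MRM markers", nrow(cohort),
       length(elisa_all), length(mrm_all))

  split <- stage("split", split_cohort(cohort, ratio = config$split_ratio,
                                       seed = config$split_seed,
                                       sizes = config$split_sizes))
  tr_idx <- split$subset == "training"
  train_raw <- cohort[tr_idx, , drop = FALSE]
  attr(train_raw, "dictionary") <- dict
  class(train_raw) <- class(cohort)
  markers <- c(elisa_all, mrm_all)
  full_t <- transform_markers(cohort, markers, method = config$transform,
                              reference = train_raw)
  attr(full_t, "dictionary") <- dict
  class(full_t) <- class(cohort)
  train <- full_t[tr_idx, , drop = FALSE]
  valid <- full_t[!tr_idx, , drop = FALSE]
  for (tb in c("train", "valid")) {
    t2 <- get(tb); attr(t2, "dictionary") <- dict
    class(t2) <- class(cohort); assign(tb, t2)
  }
  note("split: %d training / %d validation", nrow(train), nrow(valid))

  sel_thr <- config$thresholds[1]
  screen <- stage("screen", {
    out_sel <- dichotomize(train_raw, sel_thr)
    univariate_screen(train_raw, out_sel, markers, alpha = config$alpha,
                      transform = config$transform)
  })
  note("screen: %d/%d markers significant at alpha=%g (CAC > %g, training)",
       sum(screen$significant), nrow(screen), config$alpha, sel_thr)

  select_panel <- function(cands, label) {
    if (!length(cands)) {
      note("selection (%s): no significant candidates", label)
      return(list(panel = character(), trace = list()))
    }
    sub <- complete_case_subset(train, cands)
    out <- dichotomize(sub, sel_thr)
    spec <- stepwise_select(sub, out, cands, p_enter = config$p_enter,
                            p_remove = config$p_remove)
    note("selection (%s): retained %s", label,
         if (length(spec$predictors)) paste(spec$predictors, collapse = ", ") else "<none>")
    list(panel = spec$predictors, trace = attr(spec, "trace"))
  }
  selection <- stage("stepwise", {
    sig <- screen$marker[screen$significant]
    el <- if (!is.null(config$panel_elisa)) list(panel = config$panel_elisa, trace = list())
          else select_panel(intersect(sig, elisa_all), "ELISA")
    mr <- if (!is.null(config$panel_mrm)) list(panel = config$panel_mrm, trace = list())
          else select_panel(intersect(sig, mrm_all), "MRM")
    list(elisa = el, mrm = mr)
  })
  panel_elisa <- selection$elisa$panel
  panel_mrm <- selection$mrm$panel
  reference_only <- !length(panel_elisa) && !length(panel_mrm)
  if (reference_only)
    warning("run_analysis: both selected panels are empty; reference-only report")

  specs <- if (reference_only) {
    list(model_spec("reference", score_col, label = "ACC/AHA"))
  } else {
    suppressWarnings(table2_model_specs(panel_elisa, panel_mrm,
                                        reference_col = score_col))
  }
  ref_spec <- specs[[1]]

  comparisons <- list()
  reference <- list()
  for (thr in config$thresholds) {
    out_tr <- dichotomize(train, thr)
    out_va <- dichotomize(valid, thr)
    fit_ref_full <- stage("fit", fit_with_fallback(
      complete_case_subset(train, ref_spec), dichotomize(complete_case_subset(train, ref_spec), thr),
      ref_spec, config$ridge_fallback))
    for (half in c("training", "validation")) {
      tab <- if (half == "training") train else valid
      out <- if (half == "training") out_tr else out_va
      y <- outcome_vector(out, nrow(tab))
      keep <- stats::complete.cases(as.data.frame(tab)[, ref_spec$predictors, drop = FALSE])
      p <- predict(if (half == "validation" && config$refit_validation)
        fit_with_fallback(tab[keep, , drop = FALSE], y[keep], ref_spec, config$ridge_fallback)
        else fit_ref_full, tab[keep, , drop = FALSE])
      reference[[sprintf("cac%g_%s", thr, half)]] <- list(
        threshold = thr, cohort = half, n = sum(keep), n_events = sum(y[keep]),
        auc = auc_mann_whitney(p, y[keep]),
        hl = hl_or_na(p, y[keep], config$hl_groups))
    }
    for (spec in specs[-1]) {
      sub_tr <- stage("fit", complete_case_subset(train, spec))
      out_sub <- dichotomize(sub_tr, thr)
      fit_ref <- stage("fit", fit_with_fallback(sub_tr, out_sub, ref_spec, config$ridge_fallback))
      fit_new <- stage("fit", fit_with_fallback(sub_tr, out_sub, spec, config$ridge_fallback))
      note("fit: %s, CAC > %g, n=%d, events=%d%s", spec$name, thr,
           fit_new$n_cases, fit_new$n_events,
           if (isTRUE(fit_new$ridge_fallback_used)) " (ridge fallback)" else "")
      for (half in c("training", "validation")) {
        tab <- if (half == "training") train else valid
        out <- if (half == "training") out_tr else out_va
        fr <- fit_ref; fn <- fit_new
        if (half == "validation" && config$refit_validation) {
          sub_va <- complete_case_subset(valid, spec)
          out_va_sub <- dichotomize(sub_va, thr)
          fr <- fit_with_fallback(sub_va, out_va_sub, ref_spec, config$ridge_fallback)
          fn <- fit_with_fallback(sub_va, out_va_sub, spec, config$ridge_fallback)
        }
        cmp <- stage("evaluate", compare_models(
          fr, fn, tab, out, cohort_label = half,
          nri_threshold = config$nri_threshold, hl_groups = config$hl_groups))
        comparisons[[sprintf("cac%g_%s_%s", thr, half, spec$name)]] <- cmp
      }
    }
  }

  bundle <- structure(list(
    comparisons = comparisons,
    reference = reference,
    screen = screen,
    selection = selection,
    specs = specs,
    meta = list(
      seed = if (!is.null(config$params)) config$params$seed else NA_integer_,
      split_seed = config$split_seed,
      config_hash = config_hash(config),
      thresholds = config$thresholds,
      version = as.character(utils::packageVersion("incrisk")),
      n_patients = nrow(cohort)
    ),
    log = log
  ), class = "incrisk_bundle")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(bundle, file.path(config$output_dir, "bundle.json"))
    render_table2(bundle, config$output_dir)
  }
  bundle
}

#' @export
print.incrisk_bundle <- function(x, ...) {
  cat(sprintf("Incremental-value report bundle: %d comparisons, thresholds %s\n",
              length(x$comparisons), paste(x$meta$thresholds, collapse = "/")))
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

comparison_record <- function(cmp) {
  list(
    threshold = cmp$threshold, cohort = cmp$cohort,
    model = cmp$spec_new$name, label = cmp$spec_new$label,
    n = cmp$n_common_cases, n_events = cmp$n_events,
    auc_ref = cmp$auc_ref$auc, auc_ref_lo = cmp$auc_ref$ci95[1],
    auc_ref_hi = cmp$auc_ref$ci95[2],
    auc = cmp$auc_new$auc, auc_lo = cmp$auc_new$ci95[1],
    auc_hi = cmp$auc_new$ci95[2],
    delong_p = cmp$delong_p,
    hl_p = if (!is.null(cmp$hl_new)) cmp$hl_new$p else NA_real_,
    nri = cmp$nri$nri, nri_lo = cmp$nri$ci95[1], nri_hi = cmp$nri$ci95[2],
    nri_p = cmp$nri$p,
    pct_event_stratum = unname(cmp$nri$percent_reclassified_by_stratum["event"]),
    pct_nonevent_stratum = unname(cmp$nri$percent_reclassified_by_stratum["nonevent"]),
    idi = cmp$idi$idi, idi_lo = cmp$idi$ci95[1], idi_hi = cmp$idi$ci95[2],
    idi_p = cmp$idi$p
  )
}

#' Serialize a report bundle to JSON
#'
#' @param bundle an `incrisk_bundle`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  out <- list(
    meta = bundle$meta,
    comparisons = lapply(unname(bundle$comparisons), comparison_record),
    reference = lapply(unname(bundle$reference), function(r) list(
      threshold = r$threshold, cohort = r$cohort, n = r$n,
      n_events = r$n_events, auc = r$auc$auc,
      auc_lo = r$auc$ci95[1], auc_hi = r$auc$ci95[2],
      hl_p = if (!is.null(r$hl)) r$hl$p else NA_real_)),
    screen = as.data.frame(bundle$screen),
    selection = list(elisa = bundle$selection$elisa$panel,
                     mrm = bundle$selection$mrm$panel),
    log = bundle$log
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Render the bundle as per-outcome report tables
#'
#' Writes, for each outcome threshold, a CSV (and a JSON twin) with one row
#' per model and cohort half, and the columns of the canonical
#' discrimination / calibration / reclassification layout: AUC with 95% CI,
#' p versus the reference model (`Ref` for the reference row), the
#' Hosmer-Lemeshow p, NRI with CI, p and the per-stratum net percent
#' reclassified, and IDI with CI and p.
#'
#' @param bundle an `incrisk_bundle`.
#' @param dir output directory.
#' @return character vector of the files written, invisibly.
#' @export
render_table2 <- function(bundle, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (thr in bundle$meta$thresholds) {
    rows <- list()
    for (half in c("training", "validation")) {
      ref <- bundle$reference[[sprintf("cac%g_%s", thr, half)]]
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = half, model = "reference", label = "ACC/AHA",
        n = ref$n, n_events = ref$n_events,
        auc = ref$auc$auc, auc_lo = ref$auc$ci95[1], auc_hi = ref$auc$ci95[2],
        p_vs_reference = "Ref",
        hl_p = if (!is.null(ref$hl)) ref$hl$p else NA_real_,
        nri = NA_real_, nri_lo = NA_real_, nri_hi = NA_real_, nri_p = NA_real_,
        pct_event_stratum = NA_real_, pct_nonevent_stratum = NA_real_,
        idi = NA_real_, idi_lo = NA_real_, idi_hi = NA_real_, idi_p = NA_real_,
        stringsAsFactors = FALSE)
      for (cmp in bundle$comparisons) {
        if (cmp$threshold != thr || cmp$cohort != half) next
        rec <- comparison_record(cmp)
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = half, model = rec$model, label = rec$label,
          n = rec$n, n_events = rec$n_events,
          auc = rec$auc, auc_lo = rec$auc_lo, auc_hi = rec$auc_hi,
          p_vs_reference = as.character(rec$delong_p),
          hl_p = rec$hl_p,
          nri = rec$nri, nri_lo = rec$nri_lo, nri_hi = rec$nri_hi,
          nri_p = rec$nri_p,
          pct_event_stratum = rec$pct_event_stratum,
          pct_nonevent_stratum = rec$pct_nonevent_stratum,
          idi = rec$idi, idi_lo = rec$idi_lo, idi_hi = rec$idi_hi,
          idi_p = rec$idi_p,
          stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    csv <- file.path(dir, sprintf("table2_cac_gt_%g.csv", thr))
    jsn <- file.path(dir, sprintf("table2_cac_gt_%g.json", thr))
    utils::write.csv(tab, csv, row.names = FALSE, na = "")
    jsonlite::write_json(tab, jsn, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    files <- c(files, csv, jsn)
  }
  invisible(files)
}
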