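#' Declare one circulating biomarker for the synthetic cohort
#'
#' A marker is simulated on the natural-log concentration scale as a loading on
#' the shared coronary-calcification liability plus a common assay/biology
#' factor and an independent residual. `effect` expresses the strength of the
#' marker-liability association on the log-odds scale per standard deviation of
#' the (log) marker; `effect = 0` declares an inert marker.
#'
#' @param name marker identifier, unique within a panel.
#' @param assay `"ELISA"` or `"MRM"`. MRM markers are observed only in the
#'   subset of patients given by `mrm_observed_fraction` of the cohort
#'   parameters.
#' @param log_mean,log_sd location and scale of the marker on the natural-log
#'   concentration scale; `log_sd` must be positive.
#' @param effect liability association (log-odds per SD of the log marker);
#'   0 means no association with coronary calcification.
#' @return An object of class `incrisk_marker`.
#' @export
marker_spec <- function(name, assay = c("ELISA", "MRM"), log_mean = 0,
                        log_sd = 1, effect = 0) {
  assay <- match.arg(assay)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    config_error("marker_spec: 'name' must be a non-empty string")
  if (!is.numeric(log_sd) || length(log_sd) != 1L || !is.finite(log_sd) || log_sd <= 0)
    config_error(sprintf("marker_spec: 'log_sd' must be > 0 for marker '%s'", name))
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect))
    config_error(sprintf("marker_spec: 'effect' must be a finite number for marker '%s'", name))
  structure(list(name = name, assay = assay, log_mean = log_mean,
                 log_sd = log_sd, effect = effect),
            class = "incrisk_marker")
}

#' Full generative configuration for a synthetic cohort
#'
#' Bundles every parameter of the cohort generator: covariate distributions,
#' the weights mapping covariates to the latent risk linear predictor, the
#' baseline-score emission model, the marker panel, the two-part
#' (zero-inflated lognormal) Agatston score model, the fraction of patients
#' with mass-spectrometry (MRM) measurements, and the prevalence targets used
#' by [calibrate_cac_intercepts()].
#'
#' @param n_patients cohort size (>= 2).
#' @param seed integer seed; all randomness in [generate_cohort()] derives
#'   from it.
#' @param covariate_spec list with `age_mean`, `age_sd` (years), `p_female`,
#'   `p_hypertension`, `p_smoker` (proportions).
#' @param baseline_score_coefs named weights (`age`, `male`, `hypertension`,
#'   `smoker`) of the standardized covariates in the latent risk linear
#'   predictor, plus `residual_sd` for its unexplained part.
#' @param latent_spec list with `traditional_share` (proportion of the
#'   calcification liability captured by the traditional-risk component that
#'   the baseline score tracks).
#' @param score_spec list with `intercept`, `slope`, `noise_sd`: the baseline
#'   score column is `plogis(intercept + slope * (C + noise))` where `C` is the
#'   standardized traditional-risk component.
#' @param marker_panel list of [marker_spec()] objects with unique names.
#' @param marker_cor pairwise residual correlation among markers (shared
#'   Gaussian factor), in `[0, 1)`.
#' @param cac_model list with `zero_intercept`, `zero_slope` (logistic model
#'   for any calcification), `log_mean_intercept`, `log_mean_slope`, `log_sd`
#'   (lognormal model for the positive Agatston score).
#' @param mrm_observed_fraction proportion of patients with MRM measurements.
#' @param prevalence_targets named proportions `cac0`, `cac100`, `cac300` for
#'   P(CAC > 0), P(CAC > 100), P(CAC > 300).
#' @return An object of class `incrisk_params`.
#' @seealso [default_params()] for the study-scale defaults.
#' @export
synthetic_params <- function(n_patients,
                             seed,
                             covariate_spec,
                             baseline_score_coefs,
                             latent_spec,
                             score_spec,
                             marker_panel,
                             marker_cor = 0.2,
                             cac_model,
                             mrm_observed_fraction,
                             prevalence_targets) {
  p <- structure(list(
    n_patients = n_patients,
    seed = seed,
    covariate_spec = covariate_spec,
    baseline_score_coefs = baseline_score_coefs,
    latent_spec = latent_spec,
    score_spec = score_spec,
    marker_panel = marker_panel,
    marker_cor = marker_cor,
    cac_model = cac_model,
    mrm_observed_fraction = mrm_observed_fraction,
    prevalence_targets = prevalence_targets
  ), class = "incrisk_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!is_count(p$n_patients) || p$n_patients < 2)
    config_error("synthetic_params: 'n_patients' must be an integer >= 2")
  if (!is_count(p$seed))
    config_error("synthetic_params: 'seed' must be an integer")
  cs <- p$covariate_spec
  for (f in c("age_mean", "age_sd", "p_female", "p_hypertension", "p_smoker"))
    if (is.null(cs[[f]]) || !is.numeric(cs[[f]]) || !is.finite(cs[[f]]))
      config_error(sprintf("synthetic_params: covariate_spec$%s missing or non-numeric", f))
  if (cs$age_sd <= 0)
    config_error("synthetic_params: covariate_spec$age_sd must be > 0")
  for (f in c("p_female", "p_hypertension", "p_smoker"))
    if (!is_prob(cs[[f]]))
      config_error(sprintf("synthetic_params: covariate_spec$%s must lie in [0,1]", f))
  if (!is_prob(p$latent_spec$traditional_share))
    config_error("synthetic_params: latent_spec$traditional_share must lie in [0,1]")
  if (is.null(p$score_spec$noise_sd) || p$score_spec$noise_sd < 0)
    config_error("synthetic_params: score_spec$noise_sd must be >= 0")
  if (!is.numeric(p$marker_cor) || p$marker_cor < 0 || p$marker_cor >= 1)
    config_error("synthetic_params: 'marker_cor' must lie in [0,1)")
  if (!length(p$marker_panel) || !all(vapply(p$marker_panel, inherits, TRUE, "incrisk_marker")))
    config_error("synthetic_params: 'marker_panel' must be a list of marker_spec objects")
  nms <- vapply(p$marker_panel, `[[`, "", "name")
  if (anyDuplicated(nms))
    config_error(sprintf("synthetic_params: duplicated marker names: %s",
                         paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  cm <- p$cac_model
  for (f in c("zero_intercept", "zero_slope", "log_mean_intercept", "log_mean_slope", "log_sd"))
    if (is.null(cm[[f]]) || !is.numeric(cm[[f]]) || !is.finite(cm[[f]]))
      config_error(sprintf("synthetic_params: cac_model$%s missing or non-numeric", f))
  if (cm$log_sd <= 0)
    config_error("synthetic_params: cac_model$log_sd must be > 0")
  if (!is_prob(p$mrm_observed_fraction))
    config_error("synthetic_params: 'mrm_observed_fraction' must lie in [0,1]")
  tg <- p$prevalence_targets
  if (!all(c("cac0", "cac100", "cac300") %in% names(tg)) || !is_prob(unlist(tg)))
    config_error("synthetic_params: 'prevalence_targets' must name proportions cac0, cac100, cac300 in [0,1]")
  invisible(p)
}

# The named panels of the study this generator emulates: four "cytokine"
# ELISA markers retained by stepwise selection, four further ELISA markers
# significant univariately, and three MRM peptides; plus inert ELISA markers
# so screening specificity is testable.
cytokine_panel <- function() c("osteopontin", "ykl40", "cystatin_c", "ccl18")
mrm_panel <- function() c("SerD1_NFGYTLR", "PON1_IQNILTEEPK", "Clusterin_IDSLLENDR")

default_marker_panel <- function() {
  cyto <- cytokine_panel()
  other <- c("cd40_ligand", "leptin", "osteoprotegerin", "tnfr1")
  inert <- c("il6", "il8", "tnf_alpha", "mcp1", "vcam1", "icam1",
             "serum_amyloid_a", "adiponectin", "resistin", "mmp3",
             "e_selectin", "fetuin_a")
  mrm_eff <- c(SerD1_NFGYTLR = 3.4, PON1_IQNILTEEPK = 3.1, Clusterin_IDSLLENDR = 2.8)
  c(
    lapply(cyto, function(nm) marker_spec(nm, "ELISA", log_mean = 3.5, log_sd = 0.8, effect = 3.0)),
    lapply(other, function(nm) marker_spec(nm, "ELISA", log_mean = 2.0, log_sd = 0.9, effect = 1.5)),
    lapply(inert, function(nm) marker_spec(nm, "ELISA", log_mean = 1.0, log_sd = 0.7, effect = 0)),
    lapply(names(mrm_eff), function(nm) marker_spec(nm, "MRM", log_mean = 0.0, log_sd = 1.0, effect = mrm_eff[[nm]]))
  )
}

#' Default synthetic-cohort parameters at study scale
#'
#' Returns a [synthetic_params()] object emulating the pooled rheumatoid
#' arthritis cohort the analysis was designed for: 561 patients, age
#' 57.6 +/- 10.5 years, 77% female, prevalence targets 55/30/16% for
#' CAC > 0 / > 100 / > 300 Agatston units, MRM peptides measured in 140/561
#' patients, and a marker panel of 8 active ELISA markers (the four
#' "cytokines" osteopontin, YKL-40, cystatin C and CCL18 among them), 3 active
#' MRM peptides and 12 inert ELISA markers. Two-part Agatston-model intercepts
#' are pre-calibrated to the prevalence targets, and the baseline-score noise
#' is sized so the score alone discriminates CAC > 100 with AUC close to 0.774.
#'
#' @param n_patients cohort size, default 561.
#' @param seed integer seed, default 20230561.
#' @return An `incrisk_params` object.
#' @export
default_params <- function(n_patients = 561, seed = 20230561) {
  synthetic_params(
    n_patients = n_patients,
    seed = seed,
    covariate_spec = list(age_mean = 57.6, age_sd = 10.5, p_female = 0.77,
                          p_hypertension = 0.42, p_smoker = 0.14),
    baseline_score_coefs = list(age = 0.9, male = 0.5, hypertension = 0.4,
                                smoker = 0.3, residual_sd = 1.0),
    latent_spec = list(traditional_share = 0.5),
    score_spec = list(intercept = -2.2, slope = 1.0, noise_sd = 0.3),
    marker_panel = default_marker_panel(),
    marker_cor = 0.2,
    cac_model = list(zero_intercept = 0.312, zero_slope = 1.8,
                     log_mean_intercept = 3.978, log_mean_slope = 1.6,
                     log_sd = 1.0),
    mrm_observed_fraction = 140 / 561,
    prevalence_targets = c(cac0 = 0.55, cac100 = 0.30, cac300 = 0.16)
  )
}

#' @export
print.incrisk_params <- function(x, ...) {
  nms <- vapply(x$marker_panel, `[[`, "", "name")
  assay <- vapply(x$marker_panel, `[[`, "", "assay")
  eff <- vapply(x$marker_panel, `[[`, 0, "effect")
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  n_patients: %d, seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  markers: %d ELISA (%d active), %d MRM (%d active)\n",
              sum(assay == "ELISA"), sum(assay == "ELISA" & eff != 0),
              sum(assay == "MRM"), sum(assay == "MRM" & eff != 0)))
  cat(sprintf("  MRM observed fraction: %.3f\n", x$mrm_observed_fraction))
  cat(sprintf("  prevalence targets (>0/>100/>300): %.2f/%.2f/%.2f\n",
              x$prevalence_targets[["cac0"]], x$prevalence_targets[["cac100"]],
              x$prevalence_targets[["cac300"]]))
  invisible(x)
}
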