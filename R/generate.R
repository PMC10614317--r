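# Marker loading on the calcification liability implied by a liability-scale
# effect. Bounded below 1 so every marker keeps a residual; monotone in the
# effect with loading 0 at effect 0.
effect_loading <- function(effect) 0.95 * tanh(0.45 * effect)

# Draw covariates and the latent structure shared by the score, the markers
# and the Agatston model. C is the standardized traditional-risk component
# (weighted standardized covariates + residual); L is the full calcification
# liability mixing C with an orthogonal biology component.
draw_latent <- function(params, n) {
  cs <- params$covariate_spec
  bc <- params$baseline_score_coefs
  age <- stats::rnorm(n, cs$age_mean, cs$age_sd)
  female <- stats::rbinom(n, 1, cs$p_female)
  hypertension <- stats::rbinom(n, 1, cs$p_hypertension)
  smoker <- stats::rbinom(n, 1, cs$p_smoker)
  std <- function(x, m, s) if (s > 0) (x - m) / s else x * 0
  lp <- bc$age * std(age, cs$age_mean, cs$age_sd) +
    bc$male * std(1 - female, 1 - cs$p_female, sqrt(cs$p_female * (1 - cs$p_female))) +
    bc$hypertension * std(hypertension, cs$p_hypertension,
                          sqrt(cs$p_hypertension * (1 - cs$p_hypertension))) +
    bc$smoker * std(smoker, cs$p_smoker, sqrt(cs$p_smoker * (1 - cs$p_smoker))) +
    stats::rnorm(n, 0, bc$residual_sd)
  lp_sd <- sqrt(bc$age^2 + bc$male^2 + bc$hypertension^2 + bc$smoker^2 + bc$residual_sd^2)
  C <- lp / lp_sd
  h <- params$latent_spec$traditional_share
  L <- sqrt(h) * C + sqrt(1 - h) * stats::rnorm(n)
  list(age = age, female = female, hypertension = hypertension,
       smoker = smoker, C = C, L = L)
}

#' Generate a synthetic patient cohort
#'
#' Simulates a patient-level cohort with the structure the incremental-value
#' analysis assumes: demographic covariates, a baseline cardiovascular risk
#' score in (0,1), lognormal biomarker concentrations correlated with a latent
#' calcification liability, and a coronary artery calcium (Agatston) score
#' from a two-part model (a logistic zero mass and a lognormal positive part,
#' both driven by the same liability). MRM marker columns are set to missing
#' for a random subset of patients, emulating an assay run on a subsample.
#'
#' The returned table also carries the latent liability (`latent_risk`) as a
#' diagnostic column, so that the generating two-part coefficients can be
#' recovered by regression in calibration studies.
#'
#' @param params an [synthetic_params()] object.
#' @return A `data.frame` of class `incrisk_cohort` with one row per patient
#'   and a `dictionary` attribute declaring each column's role.
#' @examples
#' cohort <- generate_cohort(default_params(n_patients = 200))
#' mean(cohort$cac_agatston > 100)
#' @export
generate_cohort <- function(params) {
  validate_params(params)
  n <- params$n_patients
  with_seed(params$seed, {
    lat <- draw_latent(params, n)
    sc <- params$score_spec
    baseline_score <- stats::plogis(sc$intercept +
      sc$slope * (lat$C + stats::rnorm(n, 0, sc$noise_sd)))

    U <- stats::rnorm(n)  # shared marker factor (assay/biology common noise)
    csh <- params$marker_cor
    markers <- lapply(params$marker_panel, function(mk) {
      lam <- effect_loading(mk$effect)
      resid_var <- 1 - lam^2
      z <- lam * lat$L + sqrt(csh * resid_var) * U +
        sqrt((1 - csh) * resid_var) * stats::rnorm(n)
      exp(mk$log_mean + mk$log_sd * z)
    })
    names(markers) <- vapply(params$marker_panel, `[[`, "", "name")

    cm <- params$cac_model
    any_cac <- stats::rbinom(n, 1, stats::plogis(cm$zero_intercept + cm$zero_slope * lat$L))
    pos <- exp(stats::rnorm(n, cm$log_mean_intercept + cm$log_mean_slope * lat$L, cm$log_sd))
    cac <- ifelse(any_cac == 1, pos, 0)

    assay <- vapply(params$marker_panel, `[[`, "", "assay")
    mrm_names <- names(markers)[assay == "MRM"]
    if (length(mrm_names)) {
      n_obs <- round(params$mrm_observed_fraction * n)
      observed <- sample.int(n, n_obs)
      miss <- setdiff(seq_len(n), observed)
      for (nm in mrm_names) markers[[nm]][miss] <- NA_real_
    }

    tab <- data.frame(
      patient_id = sprintf("RA%05d", seq_len(n)),
      age = lat$age, female = lat$female,
      hypertension = lat$hypertension, smoker = lat$smoker,
      baseline_score = baseline_score,
      latent_risk = lat$L,
      stringsAsFactors = FALSE
    )
    for (nm in names(markers)) tab[[nm]] <- markers[[nm]]
    tab$cac_agatston <- cac
    attr(tab, "dictionary") <- cohort_dictionary(params)
    attr(tab, "seed") <- params$seed
    class(tab) <- c("incrisk_cohort", "data.frame")
    tab
  })
}

# Column roles for a generated table; used for CSV round-trips and validation.
cohort_dictionary <- function(params) {
  assay <- vapply(params$marker_panel, `[[`, "", "assay")
  nms <- vapply(params$marker_panel, `[[`, "", "name")
  data.frame(
    column = c("patient_id", "age", "female", "hypertension", "smoker",
               "baseline_score", "latent_risk", nms, "cac_agatston"),
    role = c("id", "covariate", "covariate", "covariate", "covariate",
             "score", "latent",
             ifelse(assay == "MRM", "marker_mrm", "marker_elisa"),
             "cac"),
    stringsAsFactors = FALSE
  )
}

# Prevalences implied by the two-part model on a probe sample of liabilities,
# with the Bernoulli/lognormal noise integrated out analytically.
probe_prevalences <- function(L, cm) {
  pz <- stats::plogis(cm$zero_intercept + cm$zero_slope * L)
  tail_p <- function(thr) mean(pz * stats::pnorm(
    (log(thr) - cm$log_mean_intercept - cm$log_mean_slope * L) / cm$log_sd,
    lower.tail = FALSE))
  c(cac0 = mean(pz), cac100 = tail_p(100), cac300 = tail_p(300))
}

#' Calibrate the two-part Agatston model intercepts to prevalence targets
#'
#' Adjusts the zero-inflation intercept so the simulated P(CAC > 0) matches
#' `prevalence_targets["cac0"]`, then the lognormal mean intercept so
#' P(CAC > 100) matches `prevalence_targets["cac100"]`, each by bisection on a
#' probe sample of latent liabilities of size `n_probe` (expectations over the
#' outcome noise are taken analytically, so the probe only carries liability
#' sampling error). The achieved P(CAC > 300) is determined by the slopes and
#' lognormal scale; if any achieved prevalence misses its target by more than
#' `tol`, a calibration-failure error reporting the best achieved values is
#' raised.
#'
#' @param params an [synthetic_params()] object with strictly decreasing
#'   prevalence targets across the 0/100/300 thresholds.
#' @param n_probe probe sample size (default 1e5).
#' @param tol maximum absolute deviation from each target (default 0.01).
#' @return `params` with `cac_model$zero_intercept` and
#'   `cac_model$log_mean_intercept` replaced by calibrated values.
#' @export
calibrate_cac_intercepts <- function(params, n_probe = 1e5, tol = 0.01) {
  validate_params(params)
  tg <- params$prevalence_targets
  if (!(tg[["cac0"]] > tg[["cac100"]] && tg[["cac100"]] > tg[["cac300"]]))
    config_error("calibrate_cac_intercepts: prevalence targets must be strictly decreasing across thresholds 0, 100, 300")
  L <- with_seed(params$seed, draw_latent(params, n_probe)$L)
  cm <- params$cac_model

  f0 <- function(zi0) mean(stats::plogis(zi0 + cm$zero_slope * L)) - tg[["cac0"]]
  lo <- -30; hi <- 30
  if (f0(lo) * f0(hi) > 0)
    incrisk_error(sprintf(
      "calibrate_cac_intercepts: P(CAC>0) target %.3f unreachable (attainable range %.3f-%.3f)",
      tg[["cac0"]], mean(stats::plogis(lo + cm$zero_slope * L)),
      mean(stats::plogis(hi + cm$zero_slope * L))), "incrisk_calibration_error")
  cm$zero_intercept <- stats::uniroot(f0, c(lo, hi), tol = 1e-8)$root

  f1 <- function(m0) {
    cm2 <- cm; cm2$log_mean_intercept <- m0
    probe_prevalences(L, cm2)[["cac100"]] - tg[["cac100"]]
  }
  if (f1(-30) * f1(30) > 0)
    incrisk_error(sprintf(
      "calibrate_cac_intercepts: P(CAC>100) target %.3f unreachable under the current zero mass",
      tg[["cac100"]]), "incrisk_calibration_error")
  cm$log_mean_intercept <- stats::uniroot(f1, c(-30, 30), tol = 1e-8)$root

  achieved <- probe_prevalences(L, cm)
  off <- abs(achieved - unlist(tg)[names(achieved)])
  if (any(off > tol))
    incrisk_error(sprintf(
      paste0("calibrate_cac_intercepts: targets not reachable within +/-%.3f ",
             "under the given slopes/scale; best achieved P(>0)=%.4f, ",
             "P(>100)=%.4f, P(>300)=%.4f"),
      tol, achieved[["cac0"]], achieved[["cac100"]], achieved[["cac300"]]),
      "incrisk_calibration_error", achieved = achieved)
  params$cac_model <- cm
  params
}
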