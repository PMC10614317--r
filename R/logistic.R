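#' Define a named nested model specification
#'
#' @param name short machine name (e.g. `"reference"`,
#'   `"reference+cytokines"`).
#' @param predictors ordered character vector of predictor columns; the
#'   Table-2-style family always includes `baseline_score`.
#' @param label optional display label for reports (defaults to `name`).
#' @return An object of class `incrisk_model_spec`.
#' @export
model_spec <- function(name, predictors, label = name) {
  if (anyDuplicated(predictors))
    config_error("model_spec: predictor names must be unique")
  structure(list(name = name, predictors = predictors, label = label),
            class = "incrisk_model_spec")
}

#' @export
print.incrisk_model_spec <- function(x, ...) {
  cat(sprintf("Model spec '%s': %s\n", x$name, paste(x$predictors, collapse = " + ")))
  invisible(x)
}

outcome_vector <- function(outcome, n) {
  y <- if (inherits(outcome, "incrisk_outcome")) outcome$indicator else outcome
  if (length(y) != n)
    data_error(sprintf("outcome length (%d) does not match table rows (%d)", length(y), n))
  if (!all(y %in% c(0, 1)))
    data_error("outcome indicator must be 0/1")
  as.numeric(y)
}

model_matrix <- function(table, predictors) {
  absent <- setdiff(predictors, names(table))
  if (length(absent))
    data_error(sprintf("fit_logistic: predictor column(s) not in table: %s",
                       paste(absent, collapse = ", ")))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(table)[, predictors, drop = FALSE]))
  if (anyNA(X))
    data_error("fit_logistic: predictors contain missing values; apply complete_case_subset first")
  X
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression with Fisher scoring and step
#' halving, standard errors from the inverse information at the optimum. The
#' log-likelihood is non-decreasing across iterations. Complete separation is
#' reported as a classed error (`incrisk_separation_error`); an optional
#' ridge penalty (excluded from the intercept) is available as a fallback.
#'
#' @param table cohort table (rows must be complete in the predictors).
#' @param outcome an [dichotomize()] result or 0/1 vector aligned to rows.
#' @param spec an [model_spec()] or character vector of predictors; an empty
#'   vector fits the intercept-only model.
#' @param options list: `max_iter` (default 100), `tol` (relative
#'   log-likelihood change, default 1e-10), `ridge` (default 0),
#'   `coef_bound` (separation detection bound on |coefficient|, default 15).
#' @return An object of class `incrisk_logit` with elements `spec`,
#'   `coefficients`, `covariance`, `fitted`, `converged`, `n_cases`,
#'   `n_events`, `loglik`, `loglik_trace`, and the `patient_id`s of the
#'   fitted cases.
#' @export
fit_logistic <- function(table, outcome, spec = character(), options = list()) {
  opt <- utils::modifyList(list(max_iter = 100L, tol = 1e-10, ridge = 0,
                                coef_bound = 15), options)
  if (inherits(spec, "incrisk_model_spec")) {
    predictors <- spec$predictors
  } else {
    predictors <- spec
    spec <- model_spec("custom", predictors)
  }
  y <- outcome_vector(outcome, nrow(table))
  if (sum(y) == 0 || sum(y) == length(y))
    data_error("fit_logistic: need at least one event and one non-event")
  X <- model_matrix(table, predictors)
  p <- ncol(X)
  pen <- c(0, rep(opt$ridge, p - 1L))  # no penalty on the intercept

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta))) - sum(pen * beta^2) / 2
  }
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-8), 1e-8))
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(opt$max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    info <- crossprod(X * sqrt(w)) + diag(pen, p)
    step <- tryCatch(solve(info, grad), error = function(e)
      incrisk_error("fit_logistic: singular information matrix (collinear or constant predictors)",
                    "incrisk_numeric_error"))
    # step halving keeps the likelihood monotone
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    beta <- cand
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < opt$tol * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  grad <- drop(crossprod(X, y - mu)) - pen * beta
  if (!converged) {
    if (max(abs(beta[-1])) > opt$coef_bound && max(abs(grad)) > 1e-3)
      incrisk_error(
        "fit_logistic: complete or quasi-complete separation detected (diverging coefficients); consider options = list(ridge = ...)",
        "incrisk_separation_error", last_coefficients = stats::setNames(beta, colnames(X)))
    incrisk_error(sprintf("fit_logistic: no convergence in %d iterations", opt$max_iter),
                  "incrisk_numeric_error", last_coefficients = stats::setNames(beta, colnames(X)))
  }
  if (opt$ridge == 0 && all(abs(y - mu) < 1e-6))
    incrisk_error(
      "fit_logistic: complete separation (fitted probabilities reproduce the outcome exactly); consider options = list(ridge = ...)",
      "incrisk_separation_error", last_coefficients = stats::setNames(beta, colnames(X)))
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X * sqrt(w)) + diag(pen, p)
  cov <- tryCatch(solve(info), error = function(e)
    incrisk_error("fit_logistic: singular information at the optimum", "incrisk_numeric_error"))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(
    spec = spec,
    coefficients = stats::setNames(beta, colnames(X)),
    covariance = cov,
    fitted = pmin(pmax(mu, 1e-12), 1 - 1e-12),
    converged = converged,
    iterations = it,
    loglik = ll,
    loglik_trace = trace,
    n_cases = length(y),
    n_events = sum(y),
    y = y,
    patient_id = if ("patient_id" %in% names(table)) table$patient_id else NULL,
    options = opt
  ), class = "incrisk_logit")
}

#' @export
print.incrisk_logit <- function(x, ...) {
  cat(sprintf("Logistic fit '%s': %d cases, %d events, logLik %.3f (%s in %d iter)\n",
              x$spec$name, x$n_cases, x$n_events, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Wald coefficient table for a logistic fit
#'
#' @param fit an `incrisk_logit`.
#' @return data.frame with estimate, SE, z, p per coefficient.
#' @export
coef_table <- function(fit) {
  se <- sqrt(diag(fit$covariance))
  z <- fit$coefficients / se
  data.frame(term = names(fit$coefficients), estimate = unname(fit$coefficients),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Predicted event probabilities for new cases
#'
#' @param object an `incrisk_logit`.
#' @param newdata table containing the fit's predictor columns (complete).
#' @param ... unused.
#' @return numeric vector of probabilities in (0,1).
#' @export
predict.incrisk_logit <- function(object, newdata, ...) {
  X <- model_matrix(newdata, object$spec$predictors)
  pmin(pmax(stats::plogis(drop(X %*% object$coefficients)), 1e-12), 1 - 1e-12)
}

#' Transform marker columns for modelling
#'
#' Natural-log + z-standardization (the default) of marker columns.
#' Centers and scales are estimated on `reference` (e.g. the training half)
#' and applied to `table`, so validation-half predictions use
#' training-frozen transforms.
#'
#' @param table table whose marker columns are transformed.
#' @param markers character vector of marker columns.
#' @param method `"log_z"`, `"z"` or `"identity"`.
#' @param reference table providing the centering/scaling statistics.
#' @return `table` with the marker columns replaced.
#' @export
transform_markers <- function(table, markers, method = c("log_z", "z", "identity"),
                              reference = table) {
  method <- match.arg(method)
  for (mk in markers) {
    if (!mk %in% names(table))
      data_error(sprintf("transform_markers: column '%s' not in table", mk))
    x <- table[[mk]]
    r <- reference[[mk]]
    if (method %in% "log_z") {
      if (any(x <= 0, na.rm = TRUE) || any(r <= 0, na.rm = TRUE))
        data_error(sprintf("transform_markers: non-positive values in '%s'; log transform undefined", mk))
      x <- log(x); r <- log(r)
    }
    if (method %in% c("log_z", "z")) {
      m <- mean(r, na.rm = TRUE)
      s <- stats::sd(r, na.rm = TRUE)
      x <- if (is.na(s) || s == 0) x - m else (x - m) / s
    }
    table[[mk]] <- x
  }
  table
}
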