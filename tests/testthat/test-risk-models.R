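test_that("logistic MLE matches closed forms on saturated designs", {
  # intercept-only: logit of the event fraction
  tab <- data.frame(x = numeric(20))
  y <- c(rep(1, 5), rep(0, 15))
  f <- fit_logistic(tab, y, character())
  expect_equal(unname(f$coefficients[1]), log(1 / 3), tolerance = 1e-8)
  # single binary predictor, 2x2 counts (x=1: 30/10, x=0: 10/30)
  tab <- data.frame(x = c(rep(1, 40), rep(0, 40)))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  f <- fit_logistic(tab, y, "x")
  expect_equal(unname(f$coefficients["x"]), log(9), tolerance = 1e-8)
  expect_equal(unname(f$coefficients["(Intercept)"]), log(1 / 3), tolerance = 1e-8)
})

test_that("IRLS agrees with glm on coefficients and standard errors", {
  set.seed(31)
  n <- 400
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * tab$a - 0.4 * tab$b + 0.6 * tab$c))
  f <- fit_logistic(tab, y, c("a", "b", "c"))
  g <- glm(y ~ a + b + c, binomial, data = cbind(tab, y = y))
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$covariance))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(unname(f$fitted), unname(fitted(g)), tolerance = 1e-6)
  # score equations hold at the optimum
  X <- cbind(1, as.matrix(tab))
  expect_lt(max(abs(crossprod(X, y - f$fitted))), 1e-6)
})

test_that("the IRLS log-likelihood never decreases", {
  set.seed(32)
  for (r in 1:10) {
    n <- 150
    tab <- data.frame(a = rnorm(n), b = exp(rnorm(n)))
    y <- rbinom(n, 1, plogis(2 * tab$a))
    f <- fit_logistic(tab, y, c("a", "b"))
    expect_true(all(diff(f$loglik_trace) >= -1e-10))
  }
})

test_that("affine predictor rescaling leaves fitted probabilities unchanged", {
  set.seed(33)
  n <- 200
  tab <- data.frame(a = rnorm(n, 50, 10))
  y <- rbinom(n, 1, plogis(-2 + 0.04 * tab$a))
  f1 <- fit_logistic(tab, y, "a")
  tab2 <- data.frame(a = (tab$a - 50) / 10)
  f2 <- fit_logistic(tab2, y, "a")
  expect_equal(unname(f1$coefficients["a"]) * 10,
               unname(f2$coefficients["a"]), tolerance = 1e-8)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("complete separation raises a classed error and ridge recovers", {
  tab <- data.frame(x = c(1:10, 21:30))
  y <- rep(c(0, 1), each = 10)
  expect_error(fit_logistic(tab, y, "x"), class = "incrisk_separation_error")
  f <- fit_logistic(tab, y, "x", options = list(ridge = 0.1))
  expect_true(f$converged)
  expect_gt(unname(f$coefficients["x"]), 0)
  # degenerate outcomes are rejected up front
  expect_error(fit_logistic(tab, rep(1, 20), "x"), class = "incrisk_data_error")
})

test_that("the univariate screen separates active from inert markers", {
  co <- generate_cohort(default_params(n_patients = 4000, seed = 41))
  out <- dichotomize(co, 100)
  dict <- attr(co, "dictionary")
  markers <- dict$column[grepl("marker", dict$role)]
  sc <- univariate_screen(co, out, markers)
  active <- c("osteopontin", "ykl40", "cystatin_c", "ccl18", "cd40_ligand",
              "leptin", "osteoprotegerin", "tnfr1",
              "SerD1_NFGYTLR", "PON1_IQNILTEEPK", "Clusterin_IDSLLENDR")
  expect_true(all(sc$significant[sc$marker %in% active]))
  inert_flags <- sc$significant[!sc$marker %in% active]
  expect_lte(sum(inert_flags), 3)
  expect_true(all(sc$or_per_sd[sc$marker %in% active] > 1))
  # CI contains the point estimate
  est <- sc[sc$estimable, ]
  expect_true(all(est$ci_lo <= est$or_per_sd & est$or_per_sd <= est$ci_hi))
})

test_that("screen flags constant and near-perfect markers appropriately", {
  set.seed(42)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  tab <- as_cohort(data.frame(patient_id = as.character(1:n),
                              baseline_score = rep(0.3, n),
                              flat = rep(2, n),
                              strong = exp(y + rnorm(n, 0, 0.5)),
                              cac_agatston = y * 200),
                   tiny_dictionary(markers = c("flat", "strong")))
  sc <- univariate_screen(tab, dichotomize(tab, 100), c("flat", "strong"))
  expect_false(sc$estimable[sc$marker == "flat"])
  expect_false(sc$significant[sc$marker == "flat"])
  expect_true(sc$or_per_sd[sc$marker == "strong"] > 1)
  expect_lt(sc$p[sc$marker == "strong"], 1e-6)
})

test_that("stepwise selection recovers a single strong predictor", {
  # v1 must always enter; noise entries occur at roughly the alpha rate
  # (P(any of 9 noise vars enters) ~ 1 - 0.95^9 ~ 0.37), so bound the total.
  noise_total <- 0
  for (r in 1:25) {
    set.seed(500 + r)
    n <- 2000
    tab <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(tab) <- paste0("v", 1:10)
    y <- rbinom(n, 1, plogis(-0.5 + 1.0 * tab$v1))
    spec <- stepwise_select(tab, y, names(tab))
    expect_true("v1" %in% spec$predictors)
    noise_total <- noise_total + length(setdiff(spec$predictors, "v1"))
  }
  expect_lte(noise_total, 25)
})

test_that("stepwise honors its thresholds and degenerate cases", {
  set.seed(51)
  n <- 300
  tab <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(tab) <- paste0("v", 1:5)
  y <- rbinom(n, 1, 0.3)  # no predictor is real
  spec <- stepwise_select(tab, y, names(tab), p_enter = 1e-6)
  expect_length(spec$predictors, 0)
  expect_error(stepwise_select(tab, y, names(tab), p_enter = 0.2, p_remove = 0.1),
               class = "incrisk_config_error")
  # contract: selection is a subset of candidates and every term stays under p_remove
  co <- generate_cohort(default_params(n_patients = 2000, seed = 52))
  cands <- c("osteopontin", "ykl40", "cystatin_c", "ccl18")
  cot <- transform_markers(co, cands, "log_z")
  out <- dichotomize(co, 100)
  spec <- stepwise_select(cot, out, cands)
  expect_true(all(spec$predictors %in% cands))
  expect_gt(length(spec$predictors), 0)
  fit <- fit_logistic(cot, out, spec)
  ct <- coef_table(fit)
  expect_true(all(ct$p[match(spec$predictors, ct$term)] < 0.10))
})

test_that("the four nested specifications mirror the report rows", {
  specs <- table2_model_specs(c("osteopontin", "ykl40"), c("SerD1_NFGYTLR"))
  expect_length(specs, 4)
  expect_equal(vapply(specs, `[[`, "", "label"),
               c("ACC/AHA", "ACC/AHA + cytokines", "ACC/AHA + MRM",
                 "ACC/AHA + cytokines + MRM"))
  expect_equal(specs[[1]]$predictors, "baseline_score")
  expect_error(table2_model_specs(c("a", "b"), c("b")),
               class = "incrisk_config_error")
  expect_warning(table2_model_specs(c("a"), character()), "empty MRM panel")
})
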