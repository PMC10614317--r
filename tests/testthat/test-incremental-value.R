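test_that("the Mann-Whitney AUC reproduces hand-computable cases", {
  y <- c(1, 1, 0, 0)
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), y)$auc, 1.0)
  expect_equal(auc_mann_whitney(rep(0.5, 4), y)$auc, 0.5)
  # one discordant pair out of four: 3/4
  expect_equal(auc_mann_whitney(c(0.9, 0.3, 0.4, 0.1), y)$auc, 0.75)
  # invariant under strictly monotone rescaling of the scores
  set.seed(60)
  s <- rnorm(80); lab <- rbinom(80, 1, 0.5)
  expect_equal(auc_mann_whitney(s, lab)$auc,
               auc_mann_whitney(plogis(3 * s), lab)$auc)
  expect_error(auc_mann_whitney(s, rep(1, 80)), class = "incrisk_data_error")
})

test_that("midrank AUC equals the pair-enumeration oracle under heavy ties", {
  set.seed(61)
  for (r in 1:5) {
    s <- sample(1:6, 120, replace = TRUE)  # many ties
    lab <- rbinom(120, 1, 0.4)
    expect_equal(auc_mann_whitney(s, lab)$auc, brute_force_auc(s, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC, DeLong variance and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(62)
  n <- 300
  lab <- rbinom(n, 1, 0.4)
  s1 <- rnorm(n, mean = lab)
  s2 <- 0.6 * s1 + rnorm(n, mean = 0.5 * lab)
  a <- auc_mann_whitney(s1, lab)
  r1 <- pROC::roc(lab, s1, quiet = TRUE, direction = "<")
  expect_equal(a$auc, as.numeric(pROC::auc(r1)), tolerance = 1e-12)
  expect_equal(a$variance, as.numeric(pROC::var(r1, method = "delong")),
               tolerance = 1e-10)
  r2 <- pROC::roc(lab, s2, quiet = TRUE, direction = "<")
  dl <- delong_paired_test(s1, s2, lab)
  pt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(dl$p, pt$p.value, tolerance = 1e-10)
  expect_equal(abs(dl$z), abs(as.numeric(pt$statistic)), tolerance = 1e-10)
})

test_that("the paired DeLong test is exact under identity and degeneracy", {
  set.seed(63)
  s <- rnorm(60); lab <- rbinom(60, 1, 0.5)
  dl <- delong_paired_test(s, s, lab)
  expect_equal(dl$delta_auc, 0)
  expect_equal(dl$p, 1)
  # zero variance with a genuinely different AUC cannot be tested
  expect_error(delong_paired_test(lab, rep(0.5, 60), lab),
               class = "incrisk_numeric_error")
})

test_that("NRI reproduces the worked example and its conventions", {
  # events: one up, one down (net 0); non-events: one down of two (net +0.5)
  p_ref <- c(0.3, 0.4, 0.6, 0.7, 0.6, 0.3)
  p_new <- c(0.6, 0.4, 0.6, 0.4, 0.4, 0.3)
  lab <- c(1, 1, 1, 1, 0, 0)
  r <- nri(p_ref, p_new, lab)
  expect_equal(r$nri, 0.5)
  expect_equal(r$event_net, 0)
  expect_equal(r$nonevent_net, 0.5)
  expect_equal(unname(r$counts[c("up_event", "down_event",
                                 "up_nonevent", "down_nonevent")]),
               c(1, 1, 0, 1))
  expect_equal(r$se, sqrt(2 / 16 + 1 / 4))
  # a probability exactly at the threshold is high risk
  b <- nri(c(0.49, 0.5), c(0.5, 0.49), c(1, 0))
  expect_equal(b$nri, 2)
  # antisymmetry under swapping the models
  expect_equal(nri(p_new, p_ref, lab)$nri, -r$nri)
})

test_that("IDI reproduces the worked example and the difference of slopes", {
  p_ref <- c(0.2, 0.4, 0.5, 0.3)
  p_new <- c(0.5, 0.5, 0.2, 0.2)
  lab <- c(1, 1, 0, 0)
  r <- idi(p_ref, p_new, lab)
  expect_equal(r$idi, 0.4)
  expect_equal(r$delta_event_mean, 0.2)
  expect_equal(r$delta_nonevent_mean, -0.2)
  expect_equal(idi(p_new, p_ref, lab)$idi, -0.4)
  # equals the change in discrimination slope
  slope <- function(p) mean(p[lab == 1]) - mean(p[lab == 0])
  expect_equal(r$idi, slope(p_new) - slope(p_ref))
  # maximal improvement is +2; NRI shares the bound
  expect_warning(r2 <- idi(c(0, 1), c(1, 0), c(1, 0)), "zero sampling variance")
  expect_equal(r2$idi, 2)
  expect_equal(nri(c(0.1, 0.9), c(0.9, 0.1), c(1, 0))$nri, 2)
})

test_that("IDI equals the integrated sensitivity/specificity difference", {
  set.seed(64)
  n <- 500
  lab <- rbinom(n, 1, 0.35)
  p_ref <- plogis(rnorm(n, lab - 0.5))
  p_new <- plogis(rnorm(n, 1.5 * (lab - 0.5)))
  grid <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  integ <- function(p) {
    sens <- vapply(grid, function(t) mean(p[lab == 1] >= t), 0)
    fpr <- vapply(grid, function(t) mean(p[lab == 0] >= t), 0)
    mean(sens) - mean(fpr)
  }
  expect_equal(idi(p_ref, p_new, lab)$idi, integ(p_new) - integ(p_ref),
               tolerance = 1e-3)
})

test_that("degenerate zero-variance improvements warn and report p = 0", {
  lab <- rep(c(1, 0), each = 5)
  p_ref <- rep(c(0.1, 0.9), each = 5)
  p_new <- rep(c(0.9, 0.1), each = 5)
  expect_warning(r <- idi(p_ref, p_new, lab), "zero sampling variance")
  expect_equal(r$idi, 1.6)
  expect_equal(r$p, 0)
  expect_warning(r2 <- nri(p_ref, p_new, lab), regexp = NA)  # counts vary, SE > 0
  expect_equal(r2$nri, 2)
})

test_that("Hosmer-Lemeshow is zero for an exactly calibrated table", {
  p <- rep(c(0.2, 0.4, 0.6, 0.8), each = 5)
  y <- unlist(lapply(1:4, function(k) rep(c(1, 0), c(k, 5 - k))))
  h <- hosmer_lemeshow(p, y, n_groups = 4)
  expect_equal(h$chi2, 0, tolerance = 1e-12)
  expect_equal(h$df, 2L)
  expect_equal(h$p, 1)
  expect_equal(h$groups$expected, c(1, 2, 3, 4))
})

test_that("Hosmer-Lemeshow matches a hand-computed statistic", {
  p <- rep(c(0.2, 0.8), each = 5)
  y <- c(1, 1, 0, 0, 0, 1, 1, 1, 0, 0)
  h <- hosmer_lemeshow(p, y, n_groups = 2)
  # group 1: O=2 E=1 -> 1/1 + 1/4; group 2: O=3 E=4 -> 1/4 + 1/1
  expect_equal(h$chi2, 2.5, tolerance = 1e-12)
  expect_error(hosmer_lemeshow(rep(0.3, 10), y, n_groups = 2),
               "fewer groups", class = "incrisk_numeric_error")
  expect_error(hosmer_lemeshow(c(0, p[-1]), y, n_groups = 2),
               class = "incrisk_data_error")
})

test_that("Hosmer-Lemeshow deciles keep ties together and fill all groups", {
  set.seed(65)
  p <- round(runif(400, 0.05, 0.95), 2)  # heavy ties
  y <- rbinom(400, 1, p)
  h <- hosmer_lemeshow(p, y, n_groups = 10)
  expect_equal(sum(h$groups$n), 400)
  expect_true(all(h$groups$n > 0))
  # no probability value straddles two groups
  grp_of <- rep(h$groups$group, h$groups$n)
  ps <- sort(p)
  straddle <- tapply(grp_of, ps, function(g) length(unique(g)))
  expect_true(all(straddle == 1))
  expect_gte(h$p, 0.0)
})

test_that("compare_models bundles all metric families coherently", {
  co <- generate_cohort(default_params(n_patients = 800, seed = 66))
  out <- dichotomize(co, 100)
  cot <- transform_markers(co, c("osteopontin", "ykl40"), "log_z")
  f0 <- fit_logistic(cot, out, model_spec("reference", "baseline_score"))
  f1 <- fit_logistic(cot, out, model_spec("reference+cytokines",
                                          c("baseline_score", "osteopontin", "ykl40")))
  cmp <- compare_models(f0, f1, cot, out, "training")
  expect_s3_class(cmp, "incrisk_comparison")
  expect_equal(cmp$n_common_cases, 800)
  expect_equal(cmp$threshold, 100)
  expect_s3_class(cmp$auc_ref, "incrisk_auc")
  expect_s3_class(cmp$nri, "incrisk_nri")
  expect_s3_class(cmp$idi, "incrisk_idi")
  expect_equal(cmp$delong$delta_auc, cmp$auc_new$auc - cmp$auc_ref$auc)
  # comparing a model against itself gives exact null results
  same <- compare_models(f0, f0, cot, out, "training")
  expect_equal(same$delong$delta_auc, 0)
  expect_equal(same$delong_p, 1)
  expect_equal(same$nri$nri, 0)
  expect_equal(same$idi$idi, 0)
  # fits on different case sets are rejected
  f2 <- fit_logistic(cohort_subset(cot, 1:400), dichotomize(cohort_subset(co, 1:400), 100),
                     model_spec("reference", "baseline_score"))
  expect_error(compare_models(f2, f1, cot, out, "training"),
               "same cases", class = "incrisk_data_error")
})
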