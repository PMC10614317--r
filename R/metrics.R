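check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    data_error("labels must be a 0/1 event indicator")
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    data_error("need at least one event and one non-event")
  as.integer(labels)
}

# DeLong structural components via midranks, O(n log n).
# V10[i] (events) and V01[j] (non-events) are the placement values whose
# means both equal the Mann-Whitney AUC.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Mann-Whitney AUC with DeLong variance
#'
#' The area under the ROC curve computed as the Mann-Whitney two-sample
#' statistic (ties count 1/2), using midranks so the computation is
#' O(n log n). The variance is the DeLong structural-component estimator and
#' the 95% CI is Wald on the AUC scale, clipped to \[0, 1\].
#'
#' @param scores numeric risk scores (any monotone scale).
#' @param labels 0/1 event indicator aligned to `scores`.
#' @return An object of class `incrisk_auc`: list with `auc`, `variance`,
#'   `ci95`, `n_events`, `n_nonevents`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels))
    data_error("auc_mann_whitney: scores and labels must have equal length")
  pl <- delong_placements(scores, labels)
  v10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  v01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  variance <- v10 / pl$m + v01 / pl$n
  half <- 1.959964 * sqrt(variance)
  structure(list(auc = pl$auc, variance = variance,
                 ci95 = c(max(0, pl$auc - half), min(1, pl$auc + half)),
                 n_events = pl$m, n_nonevents = pl$n),
            class = "incrisk_auc")
}

#' @export
print.incrisk_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d events / %d non-events\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_events, x$n_nonevents))
  invisible(x)
}

#' DeLong test for two correlated (paired) ROC curves
#'
#' Tests the difference between the AUCs of two risk scores measured on the
#' same cases. The variance of the AUC difference is obtained from the 2x2
#' covariance of the structural components shared across models; the p-value
#' is two-sided normal.
#'
#' @param scores_ref,scores_new paired score vectors on the identical cases.
#' @param labels 0/1 event indicator.
#' @return list with `auc_ref`, `auc_new`, `delta_auc`, `variance`, `z`, `p`.
#' @export
delong_paired_test <- function(scores_ref, scores_new, labels) {
  labels <- check_labels(labels)
  if (length(scores_ref) != length(labels) || length(scores_new) != length(labels))
    data_error("delong_paired_test: score vectors must align with labels")
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    data_error("delong_paired_test: need at least 2 events and 2 non-events")
  a <- delong_placements(scores_ref, labels)
  b <- delong_placements(scores_new, labels)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  variance <- (s10[1, 1] - 2 * s10[1, 2] + s10[2, 2]) / a$m +
    (s01[1, 1] - 2 * s01[1, 2] + s01[2, 2]) / a$n
  delta <- b$auc - a$auc
  if (variance <= .Machine$double.eps) {
    if (abs(delta) <= sqrt(.Machine$double.eps)) {
      z <- 0; p <- 1
    } else {
      incrisk_error("delong_paired_test: zero variance with a nonzero AUC difference",
                    "incrisk_numeric_error")
    }
  } else {
    z <- delta / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_ref = a$auc, auc_new = b$auc, delta_auc = delta,
       variance = variance, z = z, p = p)
}

degenerate_test <- function(estimate, se, what) {
  if (is.na(se) || se <= 0) {
    if (abs(estimate) <= sqrt(.Machine$double.eps)) return(list(z = 0, p = 1, se = 0))
    warning(sprintf("%s: zero sampling variance with a nonzero estimate; p set to 0", what))
    return(list(z = sign(estimate) * Inf, p = 0, se = 0))
  }
  z <- estimate / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se = se)
}

#' Two-category net reclassification improvement (NRI)
#'
#' Risk categories are `low` (< threshold) and `high` (>= threshold; a
#' probability exactly at the threshold is high risk). The NRI is the sum of
#' the net proportion of events reclassified upward and the net proportion
#' of non-events reclassified downward, ranging from -2 to +2. The standard
#' error is the asymptotic binomial form
#' `sqrt((Pup_e + Pdown_e)/n_e + (Pup_ne + Pdown_ne)/n_ne)`.
#'
#' @param p_ref,p_new predicted event probabilities from the reference and
#'   new model, aligned to the same cases.
#' @param labels 0/1 event indicator.
#' @param threshold risk threshold in (0,1), default 0.5.
#' @return An object of class `incrisk_nri`: list with `nri`, `event_net`,
#'   `nonevent_net`, `se`, `z`, `p`, `ci95`,
#'   `percent_reclassified_by_stratum`, and the crossing counts.
#' @export
nri <- function(p_ref, p_new, labels, threshold = 0.5) {
  labels <- check_labels(labels)
  if (!is_prob(p_ref) || !is_prob(p_new))
    data_error("nri: probabilities must lie in [0,1]")
  if (length(p_ref) != length(labels) || length(p_new) != length(labels))
    data_error("nri: probability vectors must align with labels")
  if (threshold <= 0 || threshold >= 1)
    config_error("nri: 'threshold' must lie strictly between 0 and 1")
  high_ref <- p_ref >= threshold
  high_new <- p_new >= threshold
  up <- !high_ref & high_new
  down <- high_ref & !high_new
  e <- labels == 1
  n_e <- sum(e); n_ne <- sum(!e)
  up_e <- sum(up & e); down_e <- sum(down & e)
  up_ne <- sum(up & !e); down_ne <- sum(down & !e)
  event_net <- (up_e - down_e) / n_e
  nonevent_net <- (down_ne - up_ne) / n_ne
  est <- event_net + nonevent_net
  se <- sqrt((up_e + down_e) / n_e^2 + (up_ne + down_ne) / n_ne^2)
  tst <- degenerate_test(est, se, "nri")
  structure(list(
    threshold = threshold, nri = est,
    event_net = event_net, nonevent_net = nonevent_net,
    se = tst$se, z = tst$z, p = tst$p,
    ci95 = c(est - 1.959964 * tst$se, est + 1.959964 * tst$se),
    percent_reclassified_by_stratum = c(event = 100 * event_net,
                                        nonevent = 100 * nonevent_net),
    counts = c(up_event = up_e, down_event = down_e,
               up_nonevent = up_ne, down_nonevent = down_ne,
               n_events = n_e, n_nonevents = n_ne)
  ), class = "incrisk_nri")
}

#' @export
print.incrisk_nri <- function(x, ...) {
  cat(sprintf("NRI %.3f (95%% CI %.3f-%.3f), p = %.3g at threshold %g\n",
              x$nri, x$ci95[1], x$ci95[2], x$p, x$threshold))
  cat(sprintf("  net %% reclassified: events %.1f%%, non-events %.1f%%\n",
              x$percent_reclassified_by_stratum[["event"]],
              x$percent_reclassified_by_stratum[["nonevent"]]))
  invisible(x)
}

#' Integrated discrimination improvement (IDI)
#'
#' The cutoff-free reclassification measure: the change (new minus reference)
#' in mean predicted probability among events, minus the same change among
#' non-events. Equivalent to the difference of the integrals of sensitivity
#' and of one-minus-specificity over all thresholds, and to the difference in
#' discrimination slopes; ranges from -2 to +2. The standard error combines
#' the within-group standard deviations of the paired probability
#' differences.
#'
#' @inheritParams nri
#' @return An object of class `incrisk_idi`: list with `idi`,
#'   `delta_event_mean`, `delta_nonevent_mean`, `se`, `z`, `p`, `ci95`.
#' @export
idi <- function(p_ref, p_new, labels) {
  labels <- check_labels(labels)
  if (!is_prob(p_ref) || !is_prob(p_new))
    data_error("idi: probabilities must lie in [0,1]")
  if (length(p_ref) != length(labels) || length(p_new) != length(labels))
    data_error("idi: probability vectors must align with labels")
  d <- p_new - p_ref
  e <- labels == 1
  de <- mean(d[e]); dne <- mean(d[!e])
  est <- de - dne
  v_e <- if (sum(e) > 1) stats::var(d[e]) else 0
  v_ne <- if (sum(!e) > 1) stats::var(d[!e]) else 0
  se <- sqrt(v_e / sum(e) + v_ne / sum(!e))
  tst <- degenerate_test(est, se, "idi")
  structure(list(
    idi = est, delta_event_mean = de, delta_nonevent_mean = dne,
    se = tst$se, z = tst$z, p = tst$p,
    ci95 = c(est - 1.959964 * tst$se, est + 1.959964 * tst$se),
    n_events = sum(e), n_nonevents = sum(!e)
  ), class = "incrisk_idi")
}

#' @export
print.incrisk_idi <- function(x, ...) {
  cat(sprintf("IDI %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$idi, x$ci95[1], x$ci95[2], x$p))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Cases are sorted by predicted probability and partitioned into
#' `n_groups` near-equal groups (deciles by default); tied probabilities are
#' kept together in the lower group. The statistic sums
#' `(O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E)` over groups and is
#' referred to a chi-square distribution with `n_groups - 2` degrees of
#' freedom.
#'
#' @param p predicted probabilities in (0,1).
#' @param labels 0/1 observed event indicator.
#' @param n_groups number of groups, default 10.
#' @return An object of class `incrisk_hl`: list with `chi2`, `df`, `p`,
#'   `n_groups` and the per-group table.
#' @export
hosmer_lemeshow <- function(p, labels, n_groups = 10) {
  labels <- check_labels(labels)
  if (length(p) != length(labels))
    data_error("hosmer_lemeshow: p and labels must align")
  if (any(p <= 0 | p >= 1))
    data_error("hosmer_lemeshow: probabilities must lie strictly in (0,1)")
  n <- length(p)
  if (n < n_groups)
    config_error("hosmer_lemeshow: fewer cases than groups")
  ord <- order(p)
  ps <- p[ord]; ys <- labels[ord]
  bounds <- floor(seq_len(n_groups - 1L) * n / n_groups)
  for (k in seq_along(bounds)) {
    b <- max(bounds[k], if (k > 1) bounds[k - 1] else 0L)
    while (b > 0 && b < n && ps[b + 1] == ps[b]) b <- b + 1L  # ties stay in the lower group
    bounds[k] <- b
  }
  grp <- findInterval(seq_len(n), bounds + 1L) + 1L
  sizes <- tabulate(grp, nbins = n_groups)
  if (any(sizes == 0))
    incrisk_error("hosmer_lemeshow: empty group after tie handling; use fewer groups",
                  "incrisk_numeric_error")
  O <- tapply(ys, grp, sum)
  E <- tapply(ps, grp, sum)
  ng <- as.numeric(sizes)
  if (any(E <= 0) || any(E >= ng))
    incrisk_error("hosmer_lemeshow: a group has expected events equal to 0 or its size; use fewer groups",
                  "incrisk_numeric_error")
  chi2 <- sum((O - E)^2 / E + ((ng - O) - (ng - E))^2 / (ng - E))
  df <- n_groups - 2L
  structure(list(
    chi2 = chi2, n_groups = n_groups, df = df,
    p = stats::pchisq(chi2, df, lower.tail = FALSE),
    groups = data.frame(group = seq_len(n_groups), n = ng,
                        observed = as.numeric(O), expected = as.numeric(E))
  ), class = "incrisk_hl")
}

#' @export
print.incrisk_hl <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi2 = %.3f on %d df (groups = %d), p = %.3g\n",
              x$chi2, x$df, x$n_groups, x$p))
  invisible(x)
}
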