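# Independent O(m*n) pair-enumeration AUC (oracle for the midrank version).
brute_force_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  tot <- 0
  for (xi in x) tot <- tot + sum(xi > y) + 0.5 * sum(xi == y)
  tot / (length(x) * length(y))
}

# Leave-one-out jackknife variance of the AUC.
jackknife_auc_var <- function(scores, labels) {
  n <- length(labels)
  th <- vapply(seq_len(n), function(i)
    auc_mann_whitney(scores[-i], labels[-i])$auc, 0)
  (n - 1) / n * sum((th - mean(th))^2)
}

# Attach a dictionary and the cohort class to a plain data.frame.
as_cohort <- function(df, dict) {
  attr(df, "dictionary") <- dict
  class(df) <- c("incrisk_cohort", "data.frame")
  df
}

# Minimal three-column dictionary for hand-built tables.
tiny_dictionary <- function(markers = character(), mrm = character()) {
  data.frame(
    column = c("patient_id", "baseline_score", markers, mrm, "cac_agatston"),
    role = c("id", "score", rep("marker_elisa", length(markers)),
             rep("marker_mrm", length(mrm)), "cac"),
    stringsAsFactors = FALSE
  )
}

# Subset a cohort, keeping dictionary and class (base [ drops attributes).
cohort_subset <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  attr(out, "dictionary") <- attr(table, "dictionary")
  class(out) <- class(table)
  out
}
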