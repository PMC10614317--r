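valid_roles <- c("id", "covariate", "score", "marker_elisa", "marker_mrm",
                 "cac", "latent")

#' Write a cohort table to CSV with a parameter sidecar
#'
#' Writes one row per patient with missing values as empty fields, a JSON
#' data dictionary next to it (`<path>.dict.json`), and, when `params` is
#' given, a JSON sidecar (`<path>.params.json`) recording the exact generator
#' configuration and seed.
#'
#' @param table an `incrisk_cohort` data.frame.
#' @param path output CSV path.
#' @param params optional [synthetic_params()] that produced the table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, params = NULL) {
  dict <- attr(table, "dictionary")
  if (is.null(dict)) data_error("write_cohort: table has no data dictionary")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  jsonlite::write_json(dict, paste0(path, ".dict.json"), dataframe = "rows")
  if (!is.null(params)) {
    ser <- unclass(params)
    ser$marker_panel <- lapply(ser$marker_panel, unclass)
    jsonlite::write_json(ser, paste0(path, ".params.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

read_dictionary <- function(dictionary_path) {
  if (!file.exists(dictionary_path))
    config_error(sprintf("read_cohort: dictionary file '%s' not found", dictionary_path))
  ext <- tolower(tools::file_ext(dictionary_path))
  dict <- if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(dictionary_path)
    if (!is.null(raw$columns)) raw <- raw$columns
    data.frame(column = vapply(raw, `[[`, "", "column"),
               role = vapply(raw, `[[`, "", "role"),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(dictionary_path, simplifyVector = TRUE))
  }
  if (!all(c("column", "role") %in% names(dict)))
    config_error("read_cohort: dictionary must declare 'column' and 'role' for every column")
  bad <- setdiff(dict$role, valid_roles)
  if (length(bad))
    config_error(sprintf("read_cohort: unknown dictionary roles: %s",
                         paste(unique(bad), collapse = ", ")))
  dict
}

#' Read a cohort table from CSV against a data dictionary
#'
#' The dictionary (JSON or YAML) declares each column's role: `id`,
#' `covariate`, `score` (the baseline risk score in (0,1)), `marker_elisa`,
#' `marker_mrm`, `cac` (the Agatston score) or `latent`. Every non-id column
#' is parsed as numeric; out-of-range or non-numeric cells are reported with
#' their row and column.
#'
#' @param path CSV path.
#' @param dictionary_path JSON/YAML dictionary path.
#' @return An `incrisk_cohort` data.frame.
#' @export
read_cohort <- function(path, dictionary_path) {
  if (!file.exists(path))
    config_error(sprintf("read_cohort: cohort file '%s' not found", path))
  dict <- read_dictionary(dictionary_path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(dict$column, names(raw))
  if (length(missing_cols))
    data_error(sprintf("read_cohort: mandatory column(s) missing from CSV: %s",
                       paste(missing_cols, collapse = ", ")))
  for (role in c("id", "score", "cac"))
    if (sum(dict$role == role) != 1L)
      config_error(sprintf("read_cohort: dictionary must declare exactly one '%s' column", role))

  id_col <- dict$column[dict$role == "id"]
  ids <- raw[[id_col]]
  if (anyDuplicated(ids))
    data_error(sprintf("read_cohort: duplicate patient_id: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))

  cols <- list()
  cols[[id_col]] <- ids
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (dict$role[i] == "id") next
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad))
      data_error(sprintf("read_cohort: non-numeric value '%s' in column '%s', row %d",
                         raw[[col]][bad[1]], col, bad[1]))
    cols[[col]] <- vals
  }
  tab <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  score_col <- dict$column[dict$role == "score"]
  sc <- tab[[score_col]]
  bad <- which(is.na(sc) | sc <= 0 | sc >= 1)
  if (length(bad))
    data_error(sprintf("read_cohort: baseline score outside (0,1) in column '%s', row %d",
                       score_col, bad[1]))
  cac_col <- dict$column[dict$role == "cac"]
  bad <- which(is.na(tab[[cac_col]]) | tab[[cac_col]] < 0)
  if (length(bad))
    data_error(sprintf("read_cohort: negative or missing Agatston score in row %d", bad[1]))

  tab <- tab[, dict$column, drop = FALSE]
  attr(tab, "dictionary") <- dict
  class(tab) <- c("incrisk_cohort", "data.frame")
  tab
}

#' Dichotomize the Agatston score at a threshold
#'
#' The event indicator is 1 when the Agatston score strictly exceeds the
#' threshold (a value exactly at the threshold is not an event).
#'
#' @param table an `incrisk_cohort` data.frame with a `cac_agatston` column
#'   (or the single column of role `cac` in its dictionary).
#' @param threshold Agatston units, >= 0 (the canonical analyses use 100
#'   and 300).
#' @return An object of class `incrisk_outcome`: the 0/1 indicator aligned to
#'   the table rows, with the threshold and event counts attached.
#' @export
dichotomize <- function(table, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    config_error("dichotomize: 'threshold' must be a single number >= 0")
  cac <- cac_column(table)
  ind <- as.integer(cac > threshold)
  structure(list(threshold = threshold, indicator = ind,
                 n = length(ind), n_events = sum(ind)),
            class = "incrisk_outcome")
}

cac_column <- function(table) {
  dict <- attr(table, "dictionary")
  col <- if (!is.null(dict)) dict$column[dict$role == "cac"] else "cac_agatston"
  if (!length(col) || !col[1] %in% names(table))
    data_error("dichotomize: no Agatston score column found")
  table[[col[1]]]
}

#' @export
print.incrisk_outcome <- function(x, ...) {
  cat(sprintf("CAC > %g outcome: %d events / %d patients (%.1f%%)\n",
              x$threshold, x$n_events, x$n, 100 * x$n_events / x$n))
  invisible(x)
}

#' Randomly split a cohort into training and validation halves
#'
#' Simple random split without replacement: `ceiling(ratio * n)` patients are
#' labelled `training`, the rest `validation`. Explicit sizes can be supplied
#' instead of a ratio, and the split can optionally be stratified on a binary
#' outcome so event fractions are balanced across halves.
#'
#' @param table cohort table.
#' @param ratio training proportion in (0,1), default 0.5.
#' @param seed integer seed.
#' @param sizes optional integer vector `c(n_training, n_validation)` summing
#'   to the cohort size; overrides `ratio`.
#' @param stratify optional `incrisk_outcome` to stratify on.
#' @return An object of class `incrisk_split`: data.frame with `patient_id`
#'   and `subset` (`"training"`/`"validation"`).
#' @export
split_cohort <- function(table, ratio = 0.5, seed, sizes = NULL, stratify = NULL) {
  n <- nrow(table)
  if (n < 2) data_error("split_cohort: need at least 2 patients")
  if (is.null(sizes)) {
    if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
      config_error("split_cohort: 'ratio' must lie strictly between 0 and 1")
    n_train <- ceiling(ratio * n)
  } else {
    if (length(sizes) != 2L || sum(sizes) != n)
      config_error(sprintf("split_cohort: explicit sizes must sum to the cohort size (%d)", n))
    n_train <- sizes[1]
  }
  lab <- rep("validation", n)
  with_seed(seed, {
    if (is.null(stratify)) {
      lab[sample.int(n, n_train)] <- "training"
    } else {
      y <- stratify$indicator
      idx1 <- which(y == 1); idx0 <- which(y == 0)
      k1 <- round(n_train * length(idx1) / n)
      lab[sample(idx1, k1)] <- "training"
      lab[sample(idx0, n_train - k1)] <- "training"
    }
  })
  structure(data.frame(patient_id = table$patient_id, subset = lab,
                       stringsAsFactors = FALSE),
            seed = seed, class = c("incrisk_split", "data.frame"))
}

#' Retain rows complete in every predictor of a model specification
#'
#' For a fair paired comparison of two models, apply this to the union of
#' both predictor sets so both are fitted and evaluated on the identical
#' case set.
#'
#' @param table cohort table.
#' @param spec an [model_spec()] or character vector of predictor columns.
#' @return The subset of `table` with no missing value in any predictor.
#' @export
complete_case_subset <- function(table, spec) {
  preds <- if (inherits(spec, "incrisk_model_spec")) spec$predictors else spec
  absent <- setdiff(preds, names(table))
  if (length(absent))
    data_error(sprintf("complete_case_subset: column(s) not in table: %s",
                       paste(absent, collapse = ", ")))
  keep <- stats::complete.cases(table[, preds, drop = FALSE])
  if (!any(keep))
    data_error("complete_case_subset: no complete cases for the requested predictors")
  out <- table[keep, , drop = FALSE]
  attr(out, "dictionary") <- attr(table, "dictionary")
  class(out) <- class(table)
  out
}
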