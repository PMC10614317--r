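write_tiny_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  csv <- file.path(dir, "cohort.csv")
  writeLines(lines, csv)
  dict <- file.path(dir, "dict.json")
  jsonlite::write_json(tiny_dictionary(markers = "m1"), dict, dataframe = "rows")
  list(csv = csv, dict = dict)
}

test_that("a well-formed CSV reads into a typed table", {
  f <- write_tiny_csv(c("patient_id,baseline_score,m1,cac_agatston",
                        "a,0.1,5,0", "b,0.5,,120", "c,0.9,2,400"))
  tab <- read_cohort(f$csv, f$dict)
  expect_s3_class(tab, "incrisk_cohort")
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$m1[2]))
  expect_type(tab$cac_agatston, "double")
})

test_that("malformed cohort files are rejected with informative errors", {
  f <- write_tiny_csv(c("patient_id,baseline_score,m1,cac_agatston",
                        "a,0.1,5,0", "a,0.5,1,120"))
  expect_error(read_cohort(f$csv, f$dict), "duplicate patient_id: a",
               class = "incrisk_data_error")
  f <- write_tiny_csv(c("patient_id,baseline_score,m1,cac_agatston",
                        "a,0.1,five,0"))
  expect_error(read_cohort(f$csv, f$dict), "'m1', row 1",
               class = "incrisk_data_error")
  f <- write_tiny_csv(c("patient_id,baseline_score,m1,cac_agatston",
                        "a,1.4,5,0"))
  expect_error(read_cohort(f$csv, f$dict), "baseline score outside",
               class = "incrisk_data_error")
  f <- write_tiny_csv(c("patient_id,baseline_score,cac_agatston", "a,0.1,0"))
  expect_error(read_cohort(f$csv, f$dict), "missing from CSV",
               class = "incrisk_data_error")
})

test_that("generated cohorts round-trip through CSV", {
  co <- generate_cohort(default_params(n_patients = 60, seed = 8))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cohort.csv")
  write_cohort(co, csv, params = default_params(n_patients = 60, seed = 8))
  expect_true(file.exists(paste0(csv, ".params.json")))
  back <- read_cohort(csv, paste0(csv, ".dict.json"))
  expect_equal(back$patient_id, co$patient_id)
  num <- names(co)[vapply(co, is.numeric, TRUE)]
  for (cl in num) expect_equal(back[[cl]], co[[cl]], tolerance = 1e-12)
})

test_that("dichotomization uses a strict threshold and nests across cutoffs", {
  tab <- as_cohort(data.frame(patient_id = letters[1:4],
                              baseline_score = rep(0.5, 4),
                              cac_agatston = c(0, 100, 100.1, 350)),
                   tiny_dictionary())
  expect_equal(dichotomize(tab, 100)$indicator, c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize(tab, 300)$indicator, c(0L, 0L, 0L, 1L))
  co <- generate_cohort(default_params(n_patients = 800, seed = 13))
  expect_true(all(dichotomize(co, 100)$indicator >= dichotomize(co, 300)$indicator))
  expect_error(dichotomize(tab, -1), class = "incrisk_config_error")
})

test_that("default cohorts carry roughly the calibrated CAC>100 prevalence", {
  co <- generate_cohort(default_params(n_patients = 5000, seed = 14))
  expect_equal(mean(co$cac_agatston > 100), 0.30, tolerance = 0.15)
})

test_that("splitting partitions the cohort reproducibly", {
  co <- generate_cohort(default_params(seed = 9))
  sp <- split_cohort(co, ratio = 0.5, seed = 7)
  expect_equal(sum(sp$subset == "training"), 281)
  expect_equal(sum(sp$subset == "validation"), 280)
  expect_setequal(sp$patient_id, co$patient_id)
  expect_identical(sp, split_cohort(co, ratio = 0.5, seed = 7))
  expect_false(identical(sp$subset, split_cohort(co, 0.5, seed = 8)$subset))
  # the published cohort sizes are honored when passed explicitly
  sp2 <- split_cohort(co, seed = 7, sizes = c(284, 277))
  expect_equal(sum(sp2$subset == "training"), 284)
  expect_error(split_cohort(co, seed = 1, sizes = c(300, 300)),
               class = "incrisk_config_error")
  expect_error(split_cohort(co, ratio = 1.2, seed = 1),
               class = "incrisk_config_error")
})

test_that("stratified splits balance the event fraction", {
  co <- generate_cohort(default_params(seed = 10))
  out <- dichotomize(co, 100)
  sp <- split_cohort(co, 0.5, seed = 3, stratify = out)
  tr <- out$indicator[sp$subset == "training"]
  va <- out$indicator[sp$subset == "validation"]
  expect_lt(abs(mean(tr) - mean(va)), 0.01)
})

test_that("complete-case subsetting matches the measured-marker pattern", {
  co <- generate_cohort(default_params(seed = 16))
  expect_equal(nrow(complete_case_subset(co, "baseline_score")), 561)
  sub <- complete_case_subset(co, c("baseline_score", mrm_cols <- c(
    "SerD1_NFGYTLR", "PON1_IQNILTEEPK", "Clusterin_IDSLLENDR")))
  expect_equal(nrow(sub), 140)
  # idempotent
  expect_identical(nrow(complete_case_subset(sub, mrm_cols)), nrow(sub))
  expect_error(complete_case_subset(co, "no_such_marker"), "no_such_marker",
               class = "incrisk_data_error")
  co$all_na <- NA_real_
  expect_error(complete_case_subset(co, "all_na"), "no complete cases",
               class = "incrisk_data_error")
})
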