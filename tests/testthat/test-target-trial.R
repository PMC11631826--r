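mini_cohort <- function() {
  d0 <- as.Date("2013-06-01")
  data.frame(
    patient_id = 1:6,
    age = c(45, 80, 17, 60, NA, 70),
    hba1c = c(75, 90, 60, NA, 55, 44),
    bmi = c(24.9, 31, 14, 36, 27, 25),
    female = c(1, 0, 1, 0, 1, 0),
    ethnicity = c("white", "south_asian", "black_mixed_other", "white",
                  "white", "white"),
    index_date = rep(d0, 6),
    baseline_hba1c_date = d0 - c(10, 200, 30, 30, 30, 180),
    stringsAsFactors = FALSE)
}

test_that("eligibility predicates remove the hand-counted rows", {
  ch <- mini_cohort()
  res <- apply_eligibility(ch, eligibility_criteria())
  # adult removes the 17-year-old and the NA age (NA fails)
  expect_identical(res$flow$rule,
                   c("adult", "hba1c_recorded", "hba1c_recent"))
  expect_identical(res$flow$n_removed, c(2L, 1L, 1L))
  expect_identical(res$flow$n_remaining, c(4L, 3L, 2L))
  # survivors: patient 1 (recent HbA1c) and patient 6 (exactly 180 days)
  expect_identical(res$cohort$patient_id, c(1L, 6L))
})

test_that("the recency window bound is inclusive and configurable", {
  ch <- mini_cohort()
  strict <- apply_eligibility(
    ch, eligibility_criteria(hba1c_recency_days = 179))
  expect_false(6L %in% strict$cohort$patient_id)
  expect_true(1L %in% strict$cohort$patient_id)
})

test_that("extra predicates must be named and are applied in order", {
  ch <- mini_cohort()
  expect_error(eligibility_criteria(function(df) df$bmi > 20), "named")
  crit <- eligibility_criteria(bmi_in_range = function(df) df$bmi >= 15)
  res <- apply_eligibility(ch, crit)
  expect_identical(tail(res$flow$rule, 1), "bmi_in_range")
  expect_false(3L %in% res$cohort$patient_id)
})

test_that("predicates returning the wrong shape are rejected", {
  ch <- mini_cohort()
  bad <- eligibility_criteria(broken = function(df) TRUE, .defaults = FALSE)
  expect_error(apply_eligibility(ch, bad), "one logical per row")
})

test_that("RCT eligibility bounds are inclusive; age 80 or HbA1c 90 fail", {
  ch <- data.frame(age = c(78, 79, 80, 18, 17, 50, 50, 50, 50),
                   hba1c = c(60, 60, 60, 60, 60, 44, 43, 87, 90))
  out <- split_rct_eligibility(ch)
  expect_identical(out$rct_eligible,
                   c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE,
                     FALSE))
})

test_that("missing age or HbA1c gives an indeterminate flag and warning", {
  ch <- data.frame(age = c(50, NA), hba1c = c(NA, 60))
  expect_warning(out <- split_rct_eligibility(ch), "indeterminate")
  expect_identical(out$rct_eligible, c(NA, NA))
})

test_that("subgroup bands follow the half-open convention exactly", {
  ch <- data.frame(
    age = c(49.9, 50, 59.9, 60, 69.9, 70, 78.9, 79, 95),
    hba1c = c(43.9, 44, 63.9, 64, 74.9, 75, 87.9, 88, 140),
    bmi = c(14.9, 15, 24.9, 25, 29.9, 30, 34.9, 35, 60),
    female = c(1, 0, 1, 0, 1, 0, 1, 0, 1),
    ethnicity = c("white", "south_asian", "black_mixed_other",
                  "white", "white", "white", "white", "white", "white"),
    stringsAsFactors = FALSE)
  out <- assign_subgroups(ch, subgroup_scheme())
  expect_identical(as.character(out$age_group),
                   c("Younger than 50", "50-59", "50-59", "60-69", "60-69",
                     "70-78", "70-78", "79 or older", "79 or older"))
  expect_identical(as.character(out$hba1c_group),
                   c("HbA1c < 44", "HbA1c 44-<64", "HbA1c 44-<64",
                     "HbA1c 64-<75", "HbA1c 64-<75", "HbA1c 75-<88",
                     "HbA1c 75-<88", "HbA1c >= 88", "HbA1c >= 88"))
  expect_identical(as.character(out$bmi_group),
                   c("bmi out of range", "Under/normal weight (15-24.9)",
                     "Under/normal weight (15-24.9)", "Overweight (25-29.9)",
                     "Overweight (25-29.9)", "Obese (class 1) (30-34.9)",
                     "Obese (class 1) (30-34.9)", "Obese (class 2 & 3) (35+)",
                     "Obese (class 2 & 3) (35+)"))
  expect_identical(as.character(out$sex_group),
                   rep(c("Female", "Male"), length.out = 9)[c(1:9)])
  expect_identical(as.character(out$ethnicity_group)[1:3],
                   c("White", "South Asian", "Black/mixed/other"))
})

test_that("every non-missing value maps to exactly one subgroup", {
  out <- assign_subgroups(fx_cohort, subgroup_scheme())
  for (col in c("age_group", "hba1c_group", "bmi_group", "ethnicity_group",
                "sex_group"))
    expect_false(anyNA(out[[col]]))
})

test_that("complete_case_filter windows the follow-up and recomputes y", {
  d0 <- as.Date("2013-01-01")
  ch <- data.frame(
    patient_id = 1:4,
    age = 60, female = 1, ethnicity = "white", hba1c = c(70, 70, 70, NA),
    bmi = 30, egfr = 80, sbp = 130, dbp = 80, duration = 5,
    index_date = rep(d0, 4),
    followup_hba1c = c(65, 64, 63, 62),
    followup_date = d0 + 364 + c(0, 90, 91, 0),
    stringsAsFactors = FALSE)
  res <- complete_case_filter(ch)
  # row 3 is out of window (91 > 90); row 4 has missing baseline HbA1c
  expect_identical(res$cohort$patient_id, c(1L, 2L))
  expect_equal(res$cohort$y, c(65 - 70, 64 - 70))
  miss <- setNames(res$missingness$n_missing, res$missingness$column)
  expect_identical(unname(miss["y"]), 2L)     # windowed-out + NA baseline
  expect_identical(unname(miss["hba1c"]), 1L)
})

test_that("complete_case_filter demands the covariate columns", {
  expect_error(complete_case_filter(data.frame(y = 1)), "absent")
})
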