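#' Eligibility criteria for target-trial cohort construction
#'
#' A named, ordered set of row-wise predicates applied by
#' [apply_eligibility()]. Each predicate is a pure function of the cohort
#' data.frame returning a logical vector (TRUE = keep); rows with NA are
#' treated as failing the predicate. The defaults encode adult age, a
#' recorded baseline HbA1c, and HbA1c measurement recency within 180 days of
#' day zero; covariate recency rules (e.g. 540 days for blood pressure or
#' eGFR measurement dates) can be added as extra predicates when those date
#' columns exist.
#'
#' @param ... named predicate functions `function(df) logical`.
#' @param .defaults include the default predicate set.
#' @param hba1c_recency_days maximum age in days of the baseline HbA1c
#'   measurement at day zero.
#' @return An object of class `eligibility_criteria` (named list of
#'   functions).
#' @export
eligibility_criteria <- function(..., .defaults = TRUE,
                                 hba1c_recency_days = 180) {
  preds <- list()
  if (.defaults) {
    preds <- list(
      adult = function(df) !is.na(df$age) & df$age >= 18,
      hba1c_recorded = function(df) !is.na(df$hba1c),
      hba1c_recent = function(df) {
        !is.na(df$baseline_hba1c_date) &
          as.numeric(df$index_date - df$baseline_hba1c_date) <=
            hba1c_recency_days
      }
    )
  }
  extra <- list(...)
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("all extra predicates must be named", call. = FALSE)
    preds <- c(preds, extra)
  }
  structure(preds, class = "eligibility_criteria")
}

#' Apply eligibility criteria with a flow-count report
#'
#' Applies each predicate in order and removes failing rows, recording how
#' many rows each rule removed (attribution follows application order, so the
#' counts depend on the ordering even though the surviving set does not).
#'
#' @param cohort cohort data.frame.
#' @param criteria an [eligibility_criteria()] object.
#' @return list with `cohort` (surviving rows) and `flow` (data.frame of
#'   `rule`, `n_removed`, `n_remaining`).
#' @export
apply_eligibility <- function(cohort, criteria) {
  stopifnot(inherits(criteria, "eligibility_criteria"))
  keep <- rep(TRUE, nrow(cohort))
  flow <- data.frame(rule = character(), n_removed = integer(),
                     n_remaining = integer(), stringsAsFactors = FALSE)
  for (nm in names(criteria)) {
    ok <- tryCatch(criteria[[nm]](cohort),
                   error = function(e)
                     stop("eligibility predicate '", nm, "' failed: ",
                          conditionMessage(e), call. = FALSE))
    if (!is.logical(ok) || length(ok) != nrow(cohort))
      stop("predicate '", nm, "' must return one logical per row",
           call. = FALSE)
    ok[is.na(ok)] <- FALSE
    removed <- sum(keep & !ok)
    keep <- keep & ok
    flow <- rbind(flow, data.frame(rule = nm, n_removed = removed,
                                   n_remaining = sum(keep),
                                   stringsAsFactors = FALSE))
  }
  list(cohort = cohort[keep, , drop = FALSE], flow = flow)
}

#' Flag the RCT-eligible subpopulation
#'
#' Flags patients meeting the benchmark trial's inclusion criteria: age 18-78
#' years and baseline HbA1c 44-87 mmol/mol (both bounds inclusive; the trial
#' excluded patients aged over 78 and with HbA1c above 87). No rows are
#' dropped; rows with missing age or HbA1c are flagged indeterminate (NA)
#' and a warning reports their count.
#'
#' @param cohort cohort data.frame with `age` and `hba1c`.
#' @param age_range inclusive age bounds.
#' @param hba1c_range inclusive baseline HbA1c bounds (mmol/mol).
#' @return the cohort with a logical `rct_eligible` column (NA =
#'   indeterminate).
#' @export
split_rct_eligibility <- function(cohort, age_range = c(18, 78),
                                  hba1c_range = c(44, 87)) {
  indet <- is.na(cohort$age) | is.na(cohort$hba1c)
  flag <- cohort$age >= age_range[1] & cohort$age <= age_range[2] &
    cohort$hba1c >= hba1c_range[1] & cohort$hba1c <= hba1c_range[2]
  flag[indet] <- NA
  if (any(indet))
    warning(sum(indet), " rows with missing age or baseline HbA1c flagged ",
            "indeterminate and excluded from both strata", call. = FALSE)
  cohort$rct_eligible <- flag
  cohort
}

#' Pre-specified subgroup scheme
#'
#' Bands for the subgroup CATEs: age (<50, 50-59, 60-69, 70-78, >=79 years),
#' baseline HbA1c (<44, 44-<64, 64-<75, 75-<88, >=88 mmol/mol), BMI by WHO
#' category (15-24.9 under/normal, 25-29.9 overweight, 30-34.9 obese class
#' 1, >=35 obese class 2 & 3), ethnicity (white, South Asian,
#' black/mixed/other) and sex. Continuous bands are half-open (lower bound
#' inclusive, upper exclusive) except the terminal bands.
#'
#' @param age_breaks,hba1c_breaks,bmi_breaks interior band boundaries.
#' @return An object of class `subgroup_scheme`.
#' @export
subgroup_scheme <- function(age_breaks = c(50, 60, 70, 79),
                            hba1c_breaks = c(44, 64, 75, 88),
                            bmi_breaks = c(25, 30, 35)) {
  sch <- list(
    age_group = list(var = "age", breaks = c(-Inf, age_breaks, Inf),
                     lower_limit = NA,
                     labels = c("Younger than 50", "50-59", "60-69", "70-78",
                                "79 or older")),
    hba1c_group = list(var = "hba1c", breaks = c(-Inf, hba1c_breaks, Inf),
                       lower_limit = NA,
                       labels = c("HbA1c < 44", "HbA1c 44-<64",
                                  "HbA1c 64-<75", "HbA1c 75-<88",
                                  "HbA1c >= 88")),
    bmi_group = list(var = "bmi", breaks = c(15, bmi_breaks, Inf),
                     lower_limit = 15,
                     labels = c("Under/normal weight (15-24.9)",
                                "Overweight (25-29.9)",
                                "Obese (class 1) (30-34.9)",
                                "Obese (class 2 & 3) (35+)")),
    ethnicity_group = list(var = "ethnicity", breaks = NULL,
                           labels = c(white = "White",
                                      south_asian = "South Asian",
                                      black_mixed_other = "Black/mixed/other")),
    sex_group = list(var = "female", breaks = NULL,
                     labels = c(`1` = "Female", `0` = "Male"))
  )
  structure(sch, columns = names(sch), class = "subgroup_scheme")
}

#' Assign subgroup labels
#'
#' Adds one factor column per scheme to the cohort. Every non-missing value
#' maps to exactly one band (half-open convention, terminal bands closed);
#' values below an explicit lower limit (e.g. BMI < 15) get an explicit
#' "out of range" level rather than a silent NA.
#'
#' @param cohort cohort data.frame.
#' @param scheme a [subgroup_scheme()].
#' @return the cohort with added factor columns named after the schemes.
#' @export
assign_subgroups <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "subgroup_scheme"))
  for (nm in names(scheme)) {
    sp <- scheme[[nm]]
    val <- cohort[[sp$var]]
    if (is.null(sp$breaks)) {
      lab <- sp$labels[as.character(val)]
      col <- factor(lab, levels = unique(unname(sp$labels)))
    } else {
      breaks <- sp$breaks
      levs <- sp$labels
      oor_label <- paste0(sp$var, " out of range")
      if (!is.na(sp$lower_limit)) levs <- c(levs, oor_label)
      band <- findInterval(val, breaks, rightmost.closed = TRUE,
                           left.open = FALSE)
      lab <- rep(NA_character_, length(val))
      inside <- !is.na(val) & band >= 1 & band <= length(sp$labels)
      lab[inside] <- sp$labels[band[inside]]
      if (!is.na(sp$lower_limit))
        lab[!is.na(val) & val < sp$lower_limit] <- oor_label
      col <- factor(lab, levels = levs)
    }
    cohort[[nm]] <- col
  }
  cohort
}

#' Outcome windowing and complete-case filtering
#'
#' Sets the follow-up HbA1c (and hence the outcome change score) missing when
#' the follow-up measurement falls outside +/- `window_days` of the week-52
#' anchor (day zero + `anchor_days`), then drops rows with a missing outcome
#' or any missing model covariate, reporting per-column missingness.
#'
#' @param cohort cohort data.frame.
#' @param covariates model covariate columns required complete.
#' @param anchor_days day-count anchor for week 52 (364 by default).
#' @param window_days tolerance around the anchor in days.
#' @return list with `cohort` (complete cases; `y` recomputed as follow-up
#'   minus baseline HbA1c) and `missingness` (data.frame of per-column
#'   missing counts among the input rows).
#' @export
complete_case_filter <- function(cohort,
                                 covariates = c("age", "female", "ethnicity",
                                                "hba1c", "bmi", "egfr",
                                                "sbp", "dbp", "duration"),
                                 anchor_days = 364, window_days = 90) {
  miss_cols <- setdiff(covariates, names(cohort))
  if (length(miss_cols))
    stop("covariate column(s) absent from cohort: ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  off <- as.numeric(cohort$followup_date -
                      (cohort$index_date + anchor_days))
  out_of_window <- !is.na(off) & abs(off) > window_days
  cohort$followup_hba1c[out_of_window] <- NA
  cohort$followup_date[out_of_window] <- NA
  cohort$y <- cohort$followup_hba1c - cohort$hba1c

  check_cols <- c("y", covariates)
  missingness <- data.frame(
    column = check_cols,
    n_missing = vapply(check_cols, function(cl) sum(is.na(cohort[[cl]])),
                       integer(1)),
    stringsAsFactors = FALSE)
  missingness$fraction <- missingness$n_missing / max(1L, nrow(cohort))

  keep <- !Reduce(`|`, lapply(check_cols, function(cl) is.na(cohort[[cl]])))
  if (!any(keep))
    warning("complete-case filter removed every row", call. = FALSE)
  list(cohort = cohort[keep, , drop = FALSE], missingness = missingness)
}
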