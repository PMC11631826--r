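# Shared fixtures, built once per test run.

# Small default-parameter cohort for structural unit tests.
fx_config <- dgp_config(n_patients = 2000L, n_clusters = 40L,
                        n_regions = 8L, seed = 42L)
fx_sim <- generate_cohort(fx_config)
fx_cohort <- fx_sim$cohort
fx_truth <- fx_sim$truth
fx_cc <- complete_case_filter(fx_cohort)$cohort

# A lean, correctly specified term set used when speed matters: the
# default generator's selection index and baseline mean only involve the
# instrument, HbA1c and BMI, so this propensity model is exact.
lean_terms <- function(degree = 3L) {
  liv_terms(covariates = c("hba1c", "bmi", "age"),
            quadratic = character(0), interactions = list(),
            iv_interactions = "hba1c", pscore_poly_degree = degree)
}

# Simulate -> complete-case analysis set together with the true mean
# individual effect over the retained rows.
simulate_analysis_set <- function(config) {
  sc <- generate_cohort(config)
  cc <- complete_case_filter(sc$cohort)$cohort
  truth <- sc$truth$individual_effect[match(cc$patient_id,
                                            sc$truth$patient_id)]
  list(cohort = cc, true_ate = mean(truth), truth = sc$truth)
}

# Naive OLS ATE (treatment coefficient, covariate-adjusted).
ols_ate <- function(data, covariates = c("hba1c", "bmi", "age")) {
  fml <- stats::reformulate(c("d", covariates), response = "y")
  unname(stats::coef(stats::lm(fml, data = data))["d"])
}

# Wald-LATE between the outer instrument quartiles.
wald_quartile_late <- function(data) {
  qs <- stats::quantile(data$ttp, c(0.25, 0.75))
  wald_late(data, z_low = qs[1], z_high = qs[2])$late
}
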