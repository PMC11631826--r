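test_that("dgp_config validates its arguments", {
  expect_error(dgp_config(n_patients = 0), "n_patients")
  expect_error(dgp_config(n_clusters = 0), "n_clusters")
  expect_error(dgp_config(n_patients = 10, n_clusters = 20), "n_clusters")
  expect_error(dgp_config(n_regions = 0), "n_regions")
  expect_error(dgp_config(base_ttp = 1.5), "base_ttp")
  expect_error(dgp_config(rho_ess = 1.2), "rho_ess")
  expect_error(dgp_config(rho_conf = -2), "rho_conf")
  expect_error(dgp_config(sigma_y = -1), "sigma_y")
  expect_error(dgp_config(missing_outcome_prob = 2), "missing_outcome_prob")
})

test_that("generate_cohort is seed-reproducible and seed-sensitive", {
  a <- generate_cohort(dgp_config(n_patients = 500, n_clusters = 20,
                                  seed = 11))
  b <- generate_cohort(dgp_config(n_patients = 500, n_clusters = 20,
                                  seed = 11))
  c <- generate_cohort(dgp_config(n_patients = 500, n_clusters = 20,
                                  seed = 12))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$cohort$y, c$cohort$y))
})

test_that("cohort and truth tables have the expected structure", {
  expect_identical(nrow(fx_cohort), 2000L)
  expect_true(all(c("patient_id", "cluster_id", "region_id", "index_date",
                    "d", "ttp", "ttp_events", "age", "female", "ethnicity",
                    "hba1c", "bmi", "egfr", "sbp", "dbp", "duration",
                    "baseline_hba1c_date", "followup_hba1c",
                    "followup_date", "y") %in% names(fx_cohort)))
  expect_true(all(c("patient_id", "v", "y0", "y1", "individual_effect",
                    "eta", "eps0") %in% names(fx_truth)))
  expect_identical(fx_cohort$patient_id, fx_truth$patient_id)
  expect_true(all(fx_cohort$d %in% c(0, 1)))
  expect_true(all(fx_cohort$ttp >= 0 & fx_cohort$ttp <= 1))
  expect_lte(max(fx_cohort$cluster_id), 40L)
  expect_lte(max(fx_cohort$region_id), 8L)
  # each cluster maps to exactly one region
  expect_true(all(tapply(fx_cohort$region_id, fx_cohort$cluster_id,
                         function(r) length(unique(r))) == 1L))
})

test_that("potential outcomes, observed outcome and truth are consistent", {
  expect_equal(fx_truth$individual_effect, fx_truth$y1 - fx_truth$y0)
  y_expected <- ifelse(fx_cohort$d == 1, fx_truth$y1, fx_truth$y0)
  obs <- !is.na(fx_cohort$followup_hba1c)
  expect_equal(fx_cohort$y[obs],
               (fx_cohort$hba1c + y_expected)[obs] - fx_cohort$hba1c[obs])
  expect_true(all(is.na(fx_cohort$y[!obs])))
})

test_that("missing outcomes match the configured fraction", {
  frac <- mean(is.na(fx_cohort$followup_hba1c))
  expect_gt(frac, fx_config$missing_outcome_prob - 0.05)
  expect_lt(frac, fx_config$missing_outcome_prob + 0.05)
  none <- generate_cohort(dgp_config(n_patients = 300, n_clusters = 10,
                                     missing_outcome_prob = 0, seed = 5))
  expect_false(anyNA(none$cohort$followup_hba1c))
})

test_that("closed_form_mte matches its defining formula", {
  cfg <- dgp_config(tau0 = -1.3, tau_x = c(hba1c = -0.1),
                    rho_ess = 0.5, sigma_gain = 4)
  x <- data.frame(hba1c = 80)
  v <- c(0.2, 0.5, 0.8)
  hb_c <- 80 - default_covariate_params()$hba1c$mean
  expect_equal(closed_form_mte(cfg, x, v),
               -1.3 - 0.1 * hb_c + 0.5 * 4 * qnorm(v))
  # no essential heterogeneity -> flat in v
  cfg0 <- dgp_config(tau0 = 2, tau_x = numeric(0), rho_ess = 0)
  expect_equal(closed_form_mte(cfg0, NULL, v), rep(2, 3))
})

test_that("the essential-heterogeneity structure holds in the truth table", {
  cfg <- dgp_config(n_patients = 20000, n_clusters = 50, seed = 9,
                    rho_ess = 0.6, rho_conf = 0.4)
  sc <- generate_cohort(cfg)
  # eta = rho_ess * sigma_gain * qnorm(V) + independent noise
  r <- cor(sc$truth$eta, qnorm(sc$truth$v))
  expect_gt(r, cfg$rho_ess - 0.03)
  expect_lt(r, cfg$rho_ess + 0.03)
  r0 <- cor(sc$truth$eps0, qnorm(sc$truth$v))
  expect_gt(r0, cfg$rho_conf - 0.03)
  expect_lt(r0, cfg$rho_conf + 0.03)
  expect_lt(abs(sd(sc$truth$eta) - cfg$sigma_gain), 0.1)
  expect_lt(abs(sd(sc$truth$eps0) - cfg$sigma_y), 0.2)
})

test_that("treatment follows the latent-index selection rule", {
  # D = 1{Phi(mu_D(x, z)) > V}: reconstruct the index from config and data
  cfg <- fx_config
  centers <- livhte:::index_centers(cfg$covariate_params)
  idx <- livhte:::eval_index(cfg$selection_coefs, fx_cohort,
                             z = fx_cohort$ttp, centers = centers)
  expect_identical(fx_cohort$d, as.integer(pnorm(idx) > fx_truth$v))
})

test_that("oracle_config overrides propagate and keep other defaults", {
  oc <- oracle_config(seed = 3, tau0 = -2)
  expect_identical(oc$tau0, -2)
  expect_identical(oc$rho_ess, 0.5)
  expect_identical(oc$sigma_gain, 4)
  expect_identical(oc$tau_x, numeric(0))
  expect_identical(oc$missing_outcome_prob, 0)
  expect_identical(oc$n_patients, 50000L)
})

test_that("degenerate configurations fail loudly", {
  expect_error(
    generate_cohort(dgp_config(n_patients = 50, n_clusters = 5,
                               n_regions = 5,
                               selection_coefs = c(intercept = -8, z = 3.5),
                               seed = 1)),
    "degenerate treatment")
  expect_error(dgp_config(selection_coefs = c(intercept = 0, z = -1)),
               "monotonicity")
})
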