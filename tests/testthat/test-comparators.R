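test_that("recycled predictions equal an independent weighted g-computation", {
  ch <- fx_cc
  fit <- iptw_ra(ch)
  # independent implementation: refit the weighted outcome model from the
  # returned weights with model.matrix, then average predicted contrasts
  covs <- c("age", "female", "ethnicity", "hba1c", "bmi", "egfr", "sbp",
            "dbp", "duration")
  fml <- as.formula(paste("y ~ d * (", paste(covs, collapse = "+"), ")"))
  om <- lm(fml, data = ch, weights = fit$weight)
  d1 <- ch; d1$d <- 1
  d0 <- ch; d0$d <- 0
  gcomp <- predict(om, d1) - predict(om, d0)
  expect_lt(max(abs(fit$effect - gcomp)), 1e-8)
  expect_equal(fit$ate, mean(gcomp), tolerance = 1e-10)
})

test_that("stabilized weights are computed and capped as documented", {
  ch <- fx_cc
  free <- iptw_ra(ch, weight_cap = Inf)
  raw <- free$weight
  ps <- pmin(pmax(fitted(free$ps_model), 1e-6), 1 - 1e-6)
  expect_equal(raw, ifelse(ch$d == 1, mean(ch$d) / ps,
                           (1 - mean(ch$d)) / (1 - ps)))
  cap <- unname(quantile(raw, 0.9))
  fit <- iptw_ra(ch, weight_cap = cap)
  expect_equal(fit$weight, pmin(raw, cap))
  expect_identical(fit$n_truncated, sum(raw > cap))
  expect_gt(fit$n_truncated, 0L)
  expect_error(iptw_ra(transform(ch, d = d + 0.5)), "binary")
  expect_output(print(fit), "IPTW-RA")
})

test_that("the instrument is excluded from the default treatment model", {
  fit <- iptw_ra(fx_cc)
  expect_false("ttp" %in% names(coef(fit$ps_model)))
})

test_that("2SLS with a binary instrument equals the Wald ratio", {
  set.seed(15)
  n <- 5000
  z <- rbinom(n, 1, 0.5)
  d <- rbinom(n, 1, 0.2 + 0.4 * z)
  y <- 2 + 3 * d + rnorm(n)
  df <- data.frame(y = y, d = d, ttp = z, region_id = rep(1:10, n / 10))
  ts <- two_stage_least_squares(df, covariates = character(0))
  wald <- (mean(y[z == 1]) - mean(y[z == 0])) /
    (mean(d[z == 1]) - mean(d[z == 0]))
  expect_equal(unname(ts$ate), wald, tolerance = 1e-10)
  # and the generic two-step projection gives the same coefficient
  dhat <- fitted(lm(d ~ z))
  expect_equal(unname(ts$ate), unname(coef(lm(y ~ dhat))["dhat"]),
               tolerance = 1e-8)
})

test_that("2SLS covariate adjustment matches an explicit projection", {
  ch <- fx_cc
  ts <- two_stage_least_squares(ch)
  covs <- c("age", "female", "ethnicity", "hba1c", "bmi", "egfr", "sbp",
            "dbp", "duration")
  X <- model.matrix(reformulate(covs), ch)[, -1]
  dhat <- fitted(lm(ch$d ~ ch$ttp + X))
  b <- coef(lm(ch$y ~ dhat + X))["dhat"]
  expect_equal(unname(ts$ate), unname(b), tolerance = 1e-8)
  expect_true(is.finite(ts$f_first_stage))
  expect_output(print(ts), "first-stage F")
})

test_that("weak instruments trigger a warning", {
  set.seed(2)
  n <- 800
  df <- data.frame(y = rnorm(n), d = rbinom(n, 1, 0.5),
                   ttp = runif(n), region_id = rep(1:8, n / 8))
  expect_warning(two_stage_least_squares(df, covariates = character(0)),
                 "weak first stage")
})

test_that("Wald LATE equals 5.0 on the printed-style fixture", {
  # low group: treatment rate 0.2, mean outcome 10
  # high group: treatment rate 0.6, mean outcome 12
  # LATE = (12 - 10) / (0.6 - 0.2) = 5 exactly
  fx <- data.frame(
    ttp = rep(c(0.1, 0.9), each = 10),
    d = c(rep(c(1, 0), times = c(2, 8)), rep(c(1, 0), times = c(6, 4))),
    y = c(rep(c(14, 9), times = c(2, 8)), rep(c(14, 9), times = c(6, 4))))
  # group means: low 0.2*14+0.8*9 = 10; high 0.6*14+0.4*9 = 12
  w <- wald_late(fx, z_low = 0.1, z_high = 0.9)
  expect_identical(w$late, 5)
  expect_identical(w$n_low, 10L)
  expect_identical(w$n_high, 10L)
  expect_equal(c(w$ey_low, w$ey_high), c(10, 12))
  expect_equal(c(w$ed_low, w$ed_high), c(0.2, 0.6))
})

test_that("Wald LATE validates its groups", {
  fx <- data.frame(ttp = c(0.1, 0.9), d = c(0, 0), y = c(1, 2))
  expect_error(wald_late(fx, 0.1, 0.9), "zero denominator")
  expect_error(wald_late(fx, -1, 2), "empty instrument group")
  # cell restriction
  fx2 <- data.frame(ttp = rep(c(0, 1), 50),
                    d = rep(c(0, 1), 50), y = rep(c(0, 3), 50),
                    g = rep(c(1, 1, 2, 2), 25))
  w <- wald_late(fx2, 0, 1, cell = fx2$g == 1)
  expect_equal(w$late, 3)
  expect_identical(w$n_low + w$n_high, 50L)
})

test_that("double robustness: one correct model is enough", {
  # DGP with a quadratic term; constant effect tau = 2
  gen <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n)
    p <- pnorm(-0.3 + 0.5 * x + 0.3 * x^2)
    d <- rbinom(n, 1, p)
    y <- 1 + x + 1.5 * x^2 + 2 * d + rnorm(n)
    data.frame(x = x, x2 = x^2, d = d, y = y)
  }
  df <- gen(40000, 99)
  # (a) treatment model correct, outcome model misses x^2
  a <- iptw_ra(df, covariates = "x",
               ps_formula = d ~ x + x2,
               outcome_formula = y ~ d * x)
  # (b) outcome model correct, treatment model misses x^2
  b <- iptw_ra(df, covariates = "x",
               ps_formula = d ~ x,
               outcome_formula = y ~ d * (x + x2))
  # (c) both models miss x^2: inconsistent
  c_ <- iptw_ra(df, covariates = "x",
                ps_formula = d ~ x,
                outcome_formula = y ~ d * x)
  expect_lt(abs(a$ate - 2), 0.1)
  expect_lt(abs(b$ate - 2), 0.1)
  expect_gt(abs(c_$ate - 2), 0.5)
})
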