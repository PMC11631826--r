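test_that("the probit first stage recovers known coefficients", {
  set.seed(21)
  n <- 20000
  df <- data.frame(ttp = runif(n), hba1c = rnorm(n, 0, 17),
                   bmi = rnorm(n, 0, 6), age = rnorm(n, 0, 12))
  eta <- -1 + 2.5 * df$ttp - 0.02 * df$hba1c
  df$d <- rbinom(n, 1, pnorm(eta))
  tm <- liv_terms(covariates = c("hba1c", "bmi", "age"),
                  quadratic = character(0), interactions = list(),
                  iv_interactions = character(0))
  pf <- fit_propensity(df, tm)
  expect_s3_class(pf, "liv_propensity")
  b <- pf$coefficients
  expect_lt(abs(b["(Intercept)"] - (-1)), 0.1)
  expect_lt(abs(b["iv"] - 2.5), 0.15)
  expect_lt(abs(b["hba1c"] - (-0.02)), 0.005)
  expect_lt(abs(b["bmi"]), 0.01)
  expect_true(all(pf$p_hat >= pf$clip & pf$p_hat <= 1 - pf$clip))
})

test_that("a warm start changes nothing but the iteration path", {
  tm <- lean_terms()
  pf1 <- fit_propensity(fx_cc, tm)
  pf2 <- fit_propensity(fx_cc, tm, start = pf1$coefficients)
  expect_equal(pf1$coefficients, pf2$coefficients, tolerance = 1e-4)
})

test_that("degenerate treatment or separation is an error", {
  df <- data.frame(ttp = runif(50), hba1c = rnorm(50), bmi = rnorm(50),
                   age = rnorm(50), d = 1)
  tm <- lean_terms()
  expect_error(fit_propensity(df, tm), "degenerate")
  df$d <- c(0.5, rep(1, 49))
  expect_error(fit_propensity(df, tm), "binary")
  # perfectly separated treatment
  sep <- data.frame(ttp = seq(0, 1, length.out = 400),
                    hba1c = rnorm(400), bmi = rnorm(400),
                    age = rnorm(400))
  sep$d <- as.integer(sep$ttp > 0.5)
  expect_error(fit_propensity(sep, tm), "separation")
})

test_that("the outcome-model derivative reproduces a known polynomial", {
  # Y constructed with known dependence on p: g(p) = 1 + 2p - 3p^2 + p^3
  # so dg/dp = 2 - 6p + 3p^2; no covariate terms, no noise.
  set.seed(12)
  n <- 4000
  df <- data.frame(hba1c = rnorm(n), bmi = rnorm(n), age = rnorm(n))
  p <- runif(n, 0.05, 0.95)
  df$y <- 1 + 2 * p - 3 * p^2 + p^3 + 0.5 * df$hba1c
  tm <- liv_terms(covariates = c("hba1c", "bmi", "age"),
                  quadratic = character(0), interactions = list(),
                  iv_interactions = character(0), pscore_poly_degree = 3L)
  of <- fit_outcome(df, p, tm)
  ps <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(mte(of, NULL, ps), 2 - 6 * ps + 3 * ps^2, tolerance = 1e-6)
})

test_that("the analytic MTE matches a numerical derivative of the fit", {
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none")
  of <- fit$outcome
  prof <- data.frame(hba1c = 70)
  h <- 1e-5
  for (p0 in c(0.3, 0.5, 0.7)) {
    g <- function(p) {
      pb <- predict(of$poly, p)
      unname(sum(of$coefficients[paste0("pscore^", 1:of$degree)] * pb) +
               of$coefficients["pscore:hba1c"] * p * prof$hba1c)
    }
    expect_equal(mte(of, prof, p0), (g(p0 + h) - g(p0 - h)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("MTE evaluation respects the fitted support", {
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none")
  lo <- fit$support[1]
  expect_error(mte(fit$outcome, data.frame(hba1c = 70), lo - 0.01),
               "support")
  expect_silent(mte(fit$outcome, data.frame(hba1c = 70), lo - 0.01,
                    extrapolate = TRUE))
  expect_error(mte(fit$outcome, NULL, 0.5), "covariate profile")
})

test_that("PeT effects use the correct draw branches", {
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none",
             n_draws = 500, seed = 9)
  pe <- fit$pet
  eff <- pe$effects
  expect_identical(nrow(eff), nrow(fx_cc))
  # treated patients average the MTE over draws below their propensity
  u <- pe$u_draws
  i_t <- which(fx_cc$d == 1 & eff$w > 0)[1]
  draws <- u[u < eff$p_hat[i_t]]
  prof <- fx_cc[i_t, , drop = FALSE]
  expect_equal(eff$pet_effect[i_t], mean(mte(fit$outcome, prof, draws)),
               tolerance = 1e-10)
  i_u <- which(fx_cc$d == 0 & eff$w < 1)[1]
  draws_u <- u[u >= eff$p_hat[i_u]]
  expect_equal(eff$pet_effect[i_u],
               mean(mte(fit$outcome, fx_cc[i_u, , drop = FALSE], draws_u)),
               tolerance = 1e-10)
  # w is the fraction of draws below the propensity
  expect_equal(eff$w, findInterval(eff$p_hat, sort(u)) / 500)
})

test_that("PeT draws are seed-reproducible", {
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none")
  a <- pet_effects(fit$propensity, fit$outcome, fx_cc, seed = 4)
  b <- pet_effects(fit$propensity, fit$outcome, fx_cc, seed = 4)
  c <- pet_effects(fit$propensity, fit$outcome, fx_cc, seed = 5)
  expect_identical(a$effects, b$effects)
  expect_false(identical(a$u_draws, c$u_draws))
})

test_that("liv() parses its two-part formula and validates inputs", {
  expect_error(liv(y ~ d, fx_cc), "treatment \\| instrument")
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none")
  expect_s3_class(fit, "liv")
  expect_identical(fit$vars,
                   list(outcome = "y", treatment = "d", instrument = "ttp"))
  expect_equal(fit$ate, mean(fit$pet$effects$pet_effect))
  expect_identical(fit$n, nrow(fx_cc))
})

test_that("plugin selection produces a sub-model of the candidate set", {
  fit <- liv(y ~ d | ttp, fx_cc, select = "plugin")
  cand <- liv_terms()
  expect_true(all(fit$terms$quadratic %in% cand$quadratic))
  expect_true(all(fit$terms$iv_interactions %in% cand$iv_interactions))
  expect_true(length(fit$terms$covariates) > 0)
})

test_that("liv methods work end to end", {
  fit <- liv(y ~ d | ttp, fx_cc, terms = lean_terms(), select = "none")
  expect_output(print(fit), "ATE")
  s <- summary(fit)
  expect_s3_class(s, "summary.liv")
  expect_output(print(s), "quantiles")
  expect_named(coef(fit, "propensity")[1], "(Intercept)")
  expect_identical(length(residuals(fit)), nrow(fx_cc))
  expect_identical(predict(fit, type = "pet"),
                   fit$pet$effects$pet_effect)
  expect_equal(predict(fit, type = "propensity"), fit$propensity$p_hat)
  # propensity prediction on new rows reproduces in-sample values
  nd <- fx_cc[3:7, ]
  expect_equal(unname(predict(fit, nd, type = "propensity")),
               unname(fit$propensity$p_hat[3:7]), tolerance = 1e-10)
  mid <- mean(fit$support)
  expect_equal(predict(fit, fx_cc[1, ], type = "mte", p = mid),
               mte(fit$outcome, fx_cc[1, ], mid))
  tf <- tempfile(fileext = ".pdf")
  pdf(tf)
  expect_silent(plot(fit, data = fx_cc))
  dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
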