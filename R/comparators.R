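#' IPTW with regression adjustment and recycled predictions
#'
#' The selection-on-observables comparator: a probit treatment model on the
#' observed covariates only (the instrument is deliberately excluded; this
#' analysis represents the "no unobserved confounding" assumption) yields
#' stabilized inverse-probability weights; a weighted gaussian-identity
#' outcome regression with treatment-by-covariate terms is then used to
#' predict each patient's potential outcomes under both treatments
#' (recycled predictions), whose difference is the individual effect. The
#' estimator is doubly robust: consistent if either the treatment or the
#' outcome model is correctly specified. Equivalent to weighted
#' g-computation regression adjustment.
#'
#' @param data complete-case cohort data.frame.
#' @param covariates covariate columns for both models (defaults to the
#'   standard baseline set present in `data`).
#' @param treatment,outcome column names.
#' @param ps_formula optional one-sided formula overriding the treatment
#'   model design (e.g. to study misspecification).
#' @param outcome_formula optional formula overriding the outcome model
#'   (must contain the treatment).
#' @param weight_cap weights above this are truncated (and counted).
#' @return Object of class `iptw_ra`: per-patient `y1_hat`, `y0_hat`,
#'   `effect`, `weight`; `ate`; `n_truncated`; both fitted models.
#' @export
iptw_ra <- function(data, covariates = c("age", "female", "ethnicity",
                                         "hba1c", "bmi", "egfr", "sbp",
                                         "dbp", "duration"),
                    treatment = "d", outcome = "y", ps_formula = NULL,
                    outcome_formula = NULL, weight_cap = 50) {
  covariates <- intersect(covariates, names(data))
  d <- data[[treatment]]
  if (!all(d %in% c(0, 1))) stop("treatment must be binary", call. = FALSE)
  if (is.null(ps_formula))
    ps_formula <- stats::reformulate(covariates, response = treatment)
  ps_fit <- stats::glm(ps_formula, data = data,
                       family = stats::binomial(link = "probit"))
  ps <- pmin(pmax(stats::fitted(ps_fit), 1e-6), 1 - 1e-6)
  sw <- ifelse(d == 1, mean(d) / ps, (1 - mean(d)) / (1 - ps))
  n_trunc <- sum(sw > weight_cap)
  sw <- pmin(sw, weight_cap)

  if (is.null(outcome_formula))
    outcome_formula <- stats::as.formula(paste(
      outcome, "~", treatment, "* (", paste(covariates, collapse = " + "),
      ")"))
  data$.stabilized_weight <- sw
  om <- stats::lm(outcome_formula, data = data,
                  weights = .stabilized_weight)
  d1 <- data; d1[[treatment]] <- 1
  d0 <- data; d0[[treatment]] <- 0
  y1 <- stats::predict(om, newdata = d1)
  y0 <- stats::predict(om, newdata = d0)

  structure(list(y1_hat = y1, y0_hat = y0, effect = y1 - y0,
                 weight = sw, ate = mean(y1 - y0),
                 n_truncated = n_trunc, ps_model = ps_fit,
                 outcome_model = om, treatment = treatment,
                 outcome = outcome),
            class = "iptw_ra")
}

#' @export
print.iptw_ra <- function(x, ...) {
  cat("IPTW-RA (doubly robust, recycled predictions)\n")
  cat(sprintf("  ATE: %.3f mmol/mol over %d patients", x$ate,
              length(x$effect)))
  if (x$n_truncated > 0) cat(" (", x$n_truncated, "weights truncated )")
  cat("\n")
  invisible(x)
}

#' Two-stage least squares with region-clustered errors
#'
#' The linear-IV comparator: 2SLS of the outcome on treatment (instrumented
#' by the tendency-to-prescribe) and covariates, with CR1 cluster-robust
#' standard errors. Under essential heterogeneity this identifies an
#' instrument-weighted average of marginal effects rather than the ATE; it
#' is reported as the conventional benchmark against the LIV estimates.
#'
#' @param data complete-case cohort data.frame.
#' @param covariates adjustment covariates.
#' @param treatment,outcome,instrument,cluster column names.
#' @param weak_f_threshold first-stage F below this triggers a weak-IV
#'   warning on the estimate.
#' @return Object of class `tsls`: `ate` (treatment coefficient), `se`,
#'   `ci`, full `coefficients`, `f_first_stage`, `weak_iv` flag.
#' @export
two_stage_least_squares <- function(data,
                                    covariates = c("age", "female",
                                                   "ethnicity", "hba1c",
                                                   "bmi", "egfr", "sbp",
                                                   "dbp", "duration"),
                                    treatment = "d", outcome = "y",
                                    instrument = "ttp",
                                    cluster = "region_id",
                                    weak_f_threshold = 10) {
  covariates <- intersect(covariates, names(data))
  z <- numeric_column(data, instrument)
  if (length(unique(z)) < 2L)
    stop("no instrument variation", call. = FALSE)
  C <- if (length(covariates)) main_effect_matrix(data, covariates) else
    matrix(numeric(0), nrow(data), 0)
  y <- data[[outcome]]
  Xm <- cbind(`(Intercept)` = 1, d = data[[treatment]], C)
  W <- cbind(`(Intercept)` = 1, iv = z, C)
  A <- crossprod(W, Xm)
  beta <- solve(A, crossprod(W, y))
  e <- as.numeric(y - Xm %*% beta)

  cl <- as.factor(data[[cluster]])
  G <- nlevels(cl)
  scores <- rowsum(W * e, cl)
  meat <- crossprod(scores)
  n <- nrow(Xm); k <- ncol(Xm)
  adj <- if (G > 1) (G / (G - 1)) * ((n - 1) / (n - k)) else 1
  Ainv <- solve(A)
  V <- adj * Ainv %*% meat %*% t(Ainv)
  se <- sqrt(diag(V))

  fstat <- tryCatch(
    weak_iv_test(data, instrument, treatment, cluster,
                 covariates)$f_statistic,
    error = function(e) NA_real_)
  weak <- is.finite(fstat) && fstat < weak_f_threshold
  if (weak)
    warning("weak first stage: F = ", round(fstat, 1), " < ",
            weak_f_threshold, call. = FALSE)
  i <- match("d", rownames(beta))
  structure(list(ate = beta[i], se = se[i],
                 ci = beta[i] + c(-1, 1) * stats::qnorm(0.975) * se[i],
                 coefficients = stats::setNames(as.numeric(beta),
                                                rownames(beta)),
                 se_all = se, f_first_stage = fstat, weak_iv = weak,
                 n = n), class = "tsls")
}

#' @export
print.tsls <- function(x, ...) {
  cat("Two-stage least squares (region-clustered CR1 errors)\n")
  cat(sprintf("  ATE: %.3f (SE %.3f, 95%% CI %.3f to %.3f)\n",
              x$ate, x$se, x$ci[1], x$ci[2]))
  cat(sprintf("  first-stage F: %.1f%s\n", x$f_first_stage,
              if (x$weak_iv) "  [WEAK INSTRUMENT]" else ""))
  invisible(x)
}

#' Wald (grouped-IV) estimator of the local average treatment effect
#'
#' Compares mean outcomes and treatment rates between low- and
#' high-instrument groups, optionally within a covariate cell:
#' \eqn{[E(Y|hi) - E(Y|lo)] / [E(D|hi) - E(D|lo)]}. Identifies the LATE of
#' the compliers between the two instrument levels.
#'
#' @param data cohort data.frame.
#' @param z_low observations with instrument `<= z_low` form the low group.
#' @param z_high observations with instrument `>= z_high` form the high
#'   group.
#' @param cell optional logical mask restricting to a covariate cell.
#' @param instrument,treatment,outcome column names.
#' @return list with `late`, group means, and group sizes.
#' @export
wald_late <- function(data, z_low, z_high, cell = NULL,
                      instrument = "ttp", treatment = "d", outcome = "y") {
  z <- numeric_column(data, instrument)
  m <- if (is.null(cell)) rep(TRUE, nrow(data)) else cell
  lo <- m & z <= z_low
  hi <- m & z >= z_high
  if (!any(lo) || !any(hi))
    stop("empty instrument group within the covariate cell", call. = FALSE)
  ey <- c(mean(data[[outcome]][lo]), mean(data[[outcome]][hi]))
  ed <- c(mean(data[[treatment]][lo]), mean(data[[treatment]][hi]))
  denom <- ed[2] - ed[1]
  if (abs(denom) < .Machine$double.eps^0.5)
    stop("no compliers at these instrument levels (zero denominator)",
         call. = FALSE)
  list(late = (ey[2] - ey[1]) / denom,
       ey_low = ey[1], ey_high = ey[2], ed_low = ed[1], ed_high = ed[2],
       n_low = sum(lo), n_high = sum(hi))
}
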