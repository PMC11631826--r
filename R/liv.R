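#' Probit treatment-propensity model (first stage)
#'
#' Fits the first-stage probit of treatment on the instrument, main
#' covariate effects and the selected quadratic/interaction terms, and
#' returns clipped fitted propensities with their empirical support.
#'
#' @param data complete-case cohort data.frame.
#' @param terms a (selected) [liv_terms()] object.
#' @param instrument,treatment column names.
#' @param clip propensities are clipped to `[clip, 1 - clip]`.
#' @param start optional starting coefficient vector (intercept first), e.g.
#'   the full-sample coefficients when refitting on bootstrap resamples.
#' @return Object of class `liv_propensity`: coefficients, `p_hat`,
#'   `support` (range of clipped propensities), and the design description.
#' @export
fit_propensity <- function(data, terms, instrument = "ttp", treatment = "d",
                           clip = 1e-3, start = NULL) {
  d <- data[[treatment]]
  if (!all(d %in% c(0, 1)))
    stop("treatment must be binary 0/1", call. = FALSE)
  if (length(unique(d)) < 2L)
    stop("degenerate treatment: all observations have D = ", d[1],
         call. = FALSE)
  z <- numeric_column(data, instrument)
  X <- stage1_design(data, terms, z)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), d,
                   family = stats::binomial(link = "probit"),
                   start = start))
  if (!fit$converged || any(!is.finite(fit$coefficients)) ||
      max(abs(fit$coefficients[-1] *
                apply(X, 2, stats::sd))) > 15)
    stop("probit first stage shows signs of separation (diverging ",
         "coefficients); review the specification or the data-generating ",
         "configuration", call. = FALSE)
  p <- pmin(pmax(fit$fitted.values, clip), 1 - clip)
  structure(list(coefficients = fit$coefficients, p_hat = p,
                 support = range(p), clip = clip, terms = terms,
                 instrument = instrument, treatment = treatment,
                 columns = colnames(X)),
            class = "liv_propensity")
}

stage1_design <- function(data, terms, z) {
  cbind(structure(matrix(z, ncol = 1), dimnames = list(NULL, "iv")),
        main_effect_matrix(data, terms$covariates),
        candidate_x_matrix(data, terms),
        iv_interaction_matrix(data, terms, z, "iv"))
}

#' Outcome model in covariates and the estimated propensity (second stage)
#'
#' Fits the gaussian-identity outcome regression on the main covariate
#' effects, selected quadratic/interaction terms, an orthogonal polynomial
#' basis in the estimated propensity, and the selected propensity-covariate
#' interactions. The polynomial + linear-interaction structure makes the
#' derivative with respect to the propensity (the MTE) available
#' analytically; the raw-coefficient representation of the orthogonal basis
#' is recovered exactly and stored for that purpose.
#'
#' @param data complete-case cohort data.frame.
#' @param p_hat estimated propensities (from [fit_propensity()]).
#' @param terms a (selected) [liv_terms()] object; `pscore_poly_degree`
#'   controls the polynomial basis.
#' @param outcome outcome column name.
#' @return Object of class `liv_outcome` with coefficients, residuals, the
#'   derivative polynomial, interaction coefficients and the propensity
#'   support.
#' @export
fit_outcome <- function(data, p_hat, terms, outcome = "y") {
  y <- data[[outcome]]
  if (any(!is.finite(y)))
    stop("outcome contains non-finite values; apply the complete-case ",
         "filter first", call. = FALSE)
  degree <- terms$pscore_poly_degree
  pb <- stats::poly(p_hat, degree)
  pbasis <- unclass(pb)[, , drop = FALSE]
  colnames(pbasis) <- paste0("pscore^", seq_len(degree))
  Xx <- cbind(main_effect_matrix(data, terms$covariates),
              candidate_x_matrix(data, terms))
  Xi <- iv_interaction_matrix(data, terms, p_hat, "pscore")
  X <- cbind(`(Intercept)` = 1, Xx, pbasis, Xi)
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients))) {
    bad <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient outcome design; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- fit$coefficients

  # exact raw-power representation of the orthogonal basis columns
  pts <- seq(0.05, 0.95, length.out = degree + 1L)
  B <- stats::predict(pb, pts)
  Vand <- outer(pts, 0:degree, `^`)
  A <- solve(Vand, cbind(0, B))[, -1, drop = FALSE]  # (degree+1) x degree
  rawp <- as.numeric(A %*% beta[colnames(pbasis)])   # powers 0..degree
  deriv_poly <- rawp[-1] * seq_len(degree)           # powers 0..degree-1

  inter_vars <- terms$iv_interactions
  inter_coefs <- if (length(inter_vars))
    beta[paste("pscore", inter_vars, sep = ":")] else numeric(0)

  structure(list(coefficients = beta, residuals = fit$residuals,
                 fitted.values = y - fit$residuals,
                 sigma = sqrt(sum(fit$residuals^2) /
                                max(1, length(y) - ncol(X))),
                 deriv_poly = deriv_poly, poly = pb,
                 inter_vars = inter_vars,
                 inter_coefs = unname(inter_coefs),
                 support = range(p_hat), degree = degree, terms = terms,
                 outcome = outcome),
            class = "liv_outcome")
}

polyval_asc <- function(coefs, x) {
  # ascending powers: coefs[1] + coefs[2] x + ...
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

#' Marginal treatment effect from a fitted outcome model
#'
#' Evaluates the analytic derivative of the outcome model with respect to
#' the propensity at a covariate profile and propensity value:
#' the derivative of the propensity polynomial plus the sum of
#' propensity-covariate interaction coefficients times the profile's
#' covariate values.
#'
#' @param outcome_fit a `liv_outcome` object.
#' @param x one-row data.frame (or named list) with the covariates entering
#'   propensity interactions; may be NULL when there are none.
#' @param p propensity value(s) at which to evaluate.
#' @param extrapolate allow `p` outside the fitted support.
#' @return MTE value(s) in outcome units (mmol/mol), vectorised over `p`.
#' @export
mte <- function(outcome_fit, x = NULL, p, extrapolate = FALSE) {
  stopifnot(inherits(outcome_fit, "liv_outcome"))
  if (!extrapolate &&
      any(p < outcome_fit$support[1] - 1e-12 |
            p > outcome_fit$support[2] + 1e-12))
    stop("p outside the fitted propensity support [",
         signif(outcome_fit$support[1], 4), ", ",
         signif(outcome_fit$support[2], 4),
         "]; set extrapolate = TRUE to override", call. = FALSE)
  cx <- 0
  if (length(outcome_fit$inter_vars)) {
    if (is.null(x))
      stop("covariate profile x required: the fitted MTE depends on ",
           paste(outcome_fit$inter_vars, collapse = ", "), call. = FALSE)
    x <- as.data.frame(x)
    cx <- sum(outcome_fit$inter_coefs *
                vapply(outcome_fit$inter_vars,
                       function(v) numeric_column(x, v), numeric(1)))
  }
  polyval_asc(outcome_fit$deriv_poly, p) + cx
}

#' Personalised treatment effects by conditional integration of the MTE
#'
#' Draws one shared vector of `n_draws` values
#' \eqn{u \sim U(\min\hat p, \max\hat p)} and, for each patient, averages
#' the fitted MTE at their covariates over the draws compatible with their
#' observed treatment: draws with \eqn{u < \hat p_i} for treated patients
#' (the latent-index rule \eqn{D^* = \Phi^{-1}(\hat p) + \Phi^{-1}(1-u) > 0}
#' is algebraically the same event) and \eqn{u \ge \hat p_i} otherwise.
#' Patients whose propensity sits at the support edge and have no
#' qualifying draw fall back to the nearest single draw; the count is
#' recorded.
#'
#' @param prop_fit a `liv_propensity`.
#' @param outcome_fit a `liv_outcome` fitted on the same data.
#' @param data the same complete-case cohort.
#' @param n_draws number of shared uniform draws (default 1000).
#' @param seed seed for the draw vector.
#' @return Object of class `pet_result`: a list with `effects` (data.frame
#'   of `patient_id`, `p_hat`, `w` = fraction of draws below the patient's
#'   propensity, both branch means, `pet_effect`, `side`, `n_draws_used`),
#'   the shared `u_draws`, `support`, `n_fallback` and `seed`.
#' @export
pet_effects <- function(prop_fit, outcome_fit, data, n_draws = 1000L,
                        seed = 1L) {
  stopifnot(inherits(prop_fit, "liv_propensity"),
            inherits(outcome_fit, "liv_outcome"))
  p <- prop_fit$p_hat
  if (length(p) != nrow(data))
    stop("propensity fit and cohort are not aligned", call. = FALSE)
  d <- data[[prop_fit$treatment]]
  set.seed(seed)
  u <- stats::runif(n_draws, prop_fit$support[1], prop_fit$support[2])
  ord <- order(u)
  us <- u[ord]
  fs <- polyval_asc(outcome_fit$deriv_poly, us)
  pref <- c(0, cumsum(fs))
  cnt <- findInterval(p, us)
  n_fb <- sum(cnt == 0L & d == 1) + sum(cnt == n_draws & d == 0)
  below <- ifelse(cnt > 0L, pref[cnt + 1L] / pmax(cnt, 1L), fs[1])
  above <- ifelse(cnt < n_draws,
                  (pref[n_draws + 1L] - pref[cnt + 1L]) /
                    pmax(n_draws - cnt, 1L),
                  fs[n_draws])
  cx <- rep(0, nrow(data))
  if (length(outcome_fit$inter_vars))
    cx <- as.numeric(
      do.call(cbind, lapply(outcome_fit$inter_vars,
                            function(v) numeric_column(data, v))) %*%
        outcome_fit$inter_coefs)
  pet_t <- below + cx
  pet_u <- above + cx
  eff <- data.frame(
    patient_id = if ("patient_id" %in% names(data)) data$patient_id else
      seq_len(nrow(data)),
    p_hat = p, w = cnt / n_draws,
    pet_treated_branch = pet_t, pet_untreated_branch = pet_u,
    pet_effect = ifelse(d == 1, pet_t, pet_u),
    side = ifelse(d == 1, "treated", "untreated"),
    n_draws_used = ifelse(d == 1, pmax(cnt, 1L),
                          pmax(n_draws - cnt, 1L)))
  structure(list(effects = eff, u_draws = u, support = prop_fit$support,
                 n_draws = n_draws, n_fallback = n_fb, seed = seed),
            class = "pet_result")
}

#' @export
print.pet_result <- function(x, ...) {
  cat("Personalised treatment effects for", nrow(x$effects), "patients\n")
  cat(sprintf("  shared draws: %d on support [%.3f, %.3f]; %d fallback\n",
              x$n_draws, x$support[1], x$support[2], x$n_fallback))
  cat(sprintf("  mean PeT: %.3f mmol/mol\n", mean(x$effects$pet_effect)))
  invisible(x)
}

#' Fit the local-instrumental-variable treatment-effect model
#'
#' The main fitting function. Given a cohort with a binary treatment, a
#' continuous instrument and baseline covariates, it (optionally) selects
#' quadratic and interaction terms by plugin-penalty lasso in each stage and
#' takes the union across stages, fits the probit propensity first stage and
#' the gaussian-identity outcome model in the estimated propensity, and
#' integrates the analytic MTE over shared uniform draws to produce
#' personalised treatment effects (PeT) for every patient. The average of
#' the PeT effects is the (support-restricted) ATE.
#'
#' @param formula `outcome ~ treatment | instrument` (two-part right-hand
#'   side separated by `|`).
#' @param data complete-case cohort data.frame.
#' @param terms candidate [liv_terms()]; its `covariates` are intersected
#'   with the columns of `data`.
#' @param select `"plugin"` for rigorous-lasso selection with
#'   union-across-stages, `"none"` to use the candidate set as given.
#' @param n_draws shared uniform draws for the PeT integration.
#' @param clip propensity clipping bound.
#' @param seed seed for the PeT draws (and nothing else; the fit itself is
#'   deterministic given the data).
#' @return Object of class `liv` with components `propensity`, `outcome`,
#'   `pet`, `terms` (the final selection), `ate`, `support`, `call`.
#' @examples
#' sc <- generate_cohort(dgp_config(n_patients = 2000, seed = 7,
#'                                  missing_outcome_prob = 0))
#' cc <- complete_case_filter(sc$cohort)$cohort
#' fit <- liv(y ~ d | ttp, cc, select = "none")
#' fit
#' @export
liv <- function(formula, data, terms = liv_terms(), select = c("plugin",
                                                               "none"),
                n_draws = 1000L, clip = 1e-3, seed = 1L) {
  select <- match.arg(select)
  vars <- parse_liv_formula(formula)
  terms$covariates <- intersect(terms$covariates, names(data))
  keep_num <- function(v) v[v %in% terms$covariates &
                              vapply(v, function(nm)
                                is.numeric(data[[nm]]), TRUE)]
  terms$quadratic <- keep_num(terms$quadratic)
  terms$interactions <- Filter(function(pr)
    all(pr %in% terms$covariates), terms$interactions)
  terms$iv_interactions <- keep_num(terms$iv_interactions)

  d <- data[[vars$treatment]]
  z <- numeric_column(data, vars$instrument)
  y <- data[[vars$outcome]]

  if (select == "plugin") {
    sel1 <- select_terms_lasso(data, terms, 1L, iv = z, response = d)
    prelim <- fit_propensity(data, sel1, vars$instrument, vars$treatment,
                             clip)
    sel2 <- select_terms_lasso(data, terms, 2L, iv = prelim$p_hat,
                               response = y)
    final_terms <- union_terms(terms, sel1, sel2)
  } else {
    final_terms <- terms
  }

  prop <- fit_propensity(data, final_terms, vars$instrument,
                         vars$treatment, clip)
  outc <- fit_outcome(data, prop$p_hat, final_terms, vars$outcome)
  pet <- pet_effects(prop, outc, data, n_draws = n_draws, seed = seed)

  structure(list(call = match.call(), formula = formula, vars = vars,
                 terms = final_terms, propensity = prop, outcome = outc,
                 pet = pet, ate = mean(pet$effects$pet_effect),
                 support = prop$support, n = nrow(data),
                 select = select, n_draws = n_draws, clip = clip,
                 seed = seed),
            class = "liv")
}

parse_liv_formula <- function(formula) {
  if (length(formula) != 3L)
    stop("formula must have the form outcome ~ treatment | instrument",
         call. = FALSE)
  rhs <- formula[[3]]
  if (!(is.call(rhs) && identical(rhs[[1]], as.name("|"))))
    stop("right-hand side must be `treatment | instrument`", call. = FALSE)
  list(outcome = deparse(formula[[2]]),
       treatment = deparse(rhs[[2]]),
       instrument = deparse(rhs[[3]]))
}

#' @export
print.liv <- function(x, ...) {
  cat("Local-IV treatment effect model\n")
  cat("  ", deparse(x$formula), "  (n =", x$n, ")\n")
  cat(sprintf("  propensity support: [%.3f, %.3f]\n", x$support[1],
              x$support[2]))
  cat(sprintf("  ATE (mean PeT): %.3f mmol/mol\n", x$ate))
  invisible(x)
}

#' @export
summary.liv <- function(object, ...) {
  eff <- object$pet$effects
  structure(list(
    call = object$call, n = object$n, ate = object$ate,
    support = object$support,
    ate_treated = mean(eff$pet_effect[eff$side == "treated"]),
    ate_untreated = mean(eff$pet_effect[eff$side == "untreated"]),
    pet_quantiles = stats::quantile(eff$pet_effect,
                                    c(0.05, 0.25, 0.5, 0.75, 0.95)),
    selected = attr(object$terms, "selected"),
    degree = object$terms$pscore_poly_degree,
    sigma = object$outcome$sigma,
    n_fallback = object$pet$n_fallback), class = "summary.liv")
}

#' @export
print.summary.liv <- function(x, ...) {
  cat("Local-IV treatment effect model (n =", x$n, ")\n\n")
  cat(sprintf("ATE (mean PeT):       %8.3f mmol/mol\n", x$ate))
  cat(sprintf("  among treated:      %8.3f\n", x$ate_treated))
  cat(sprintf("  among untreated:    %8.3f\n", x$ate_untreated))
  cat(sprintf("Propensity support:   [%.3f, %.3f]\n", x$support[1],
              x$support[2]))
  cat("PeT effect quantiles:\n")
  print(round(x$pet_quantiles, 3))
  if (length(x$selected))
    cat("Lasso-selected terms:", paste(x$selected, collapse = ", "), "\n")
  else
    cat("Lasso-selected terms: none beyond forced terms\n")
  cat(sprintf("Outcome residual SD:  %.3f; pscore polynomial degree %d\n",
              x$sigma, x$degree))
  if (x$n_fallback > 0)
    cat("Support-edge fallback draws used for", x$n_fallback, "patients\n")
  invisible(x)
}

#' @export
coef.liv <- function(object, stage = c("outcome", "propensity"), ...) {
  stage <- match.arg(stage)
  if (stage == "outcome") object$outcome$coefficients else
    object$propensity$coefficients
}

#' @export
residuals.liv <- function(object, ...) object$outcome$residuals

#' Predictions from a fitted LIV model
#'
#' @param object a fitted [liv()] model.
#' @param newdata optional data.frame. For `type = "pet"` only the fitted
#'   cohort's effects are available; for `type = "mte"` supply `newdata`
#'   (covariate profiles) and `p`; for `type = "propensity"` supply rows
#'   with the instrument and covariates.
#' @param type prediction type.
#' @param p propensity values for `type = "mte"`.
#' @param ... unused.
#' @export
predict.liv <- function(object, newdata = NULL,
                        type = c("pet", "mte", "propensity"), p = NULL,
                        ...) {
  type <- match.arg(type)
  if (type == "pet") {
    if (!is.null(newdata))
      stop("PeT effects are defined for the fitted cohort; refit on new ",
           "data", call. = FALSE)
    return(object$pet$effects$pet_effect)
  }
  if (type == "mte") {
    if (is.null(p)) stop("supply propensity values p", call. = FALSE)
    return(mte(object$outcome, x = newdata, p = p))
  }
  if (is.null(newdata)) return(object$propensity$p_hat)
  z <- numeric_column(newdata, object$vars$instrument)
  X <- stage1_design(newdata, object$terms, z)
  eta <- as.numeric(cbind(1, X) %*% object$propensity$coefficients)
  pmin(pmax(stats::pnorm(eta), object$clip), 1 - object$clip)
}

#' Plot the fitted MTE curve
#'
#' Draws the marginal treatment effect over the fitted propensity support at
#' a reference covariate profile (cohort means of the interacting
#' covariates), with a rug of estimated propensities.
#'
#' @param x a fitted [liv()] model.
#' @param data the fitting cohort (used for the reference profile and rug);
#'   optional.
#' @param ... passed to [graphics::plot()].
#' @export
plot.liv <- function(x, data = NULL, ...) {
  ps <- seq(x$support[1], x$support[2], length.out = 200)
  prof <- NULL
  if (length(x$outcome$inter_vars)) {
    if (is.null(data))
      stop("supply the fitting data to form the reference covariate ",
           "profile", call. = FALSE)
    prof <- as.data.frame(lapply(data[x$outcome$inter_vars], mean))
  }
  m <- mte(x$outcome, prof, ps)
  graphics::plot(ps, m, type = "l", xlab = "propensity p",
                 ylab = "MTE (mmol/mol)", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::rug(x$propensity$p_hat)
  invisible(x)
}
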