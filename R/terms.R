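#' Candidate term set for the two-stage LIV models
#'
#' Defines the model terms considered in both stages: main covariate
#' effects (always included), candidate quadratic terms, candidate
#' covariate-covariate interactions, and candidate interactions of the
#' instrument (stage 1) or the estimated propensity (stage 2) with selected
#' covariates. The instrument in stage 1 and the propensity-score polynomial
#' basis in stage 2 are forced terms and never penalized. The defaults
#' mirror the standard specification for this analysis: quadratics in age
#' and baseline HbA1c; HbA1c interacted with age, sex and BMI; the
#' instrument/propensity interacted with HbA1c, eGFR, BMI, SBP and age.
#'
#' @param covariates main-effect covariate columns.
#' @param quadratic covariates given candidate quadratic terms.
#' @param interactions list of 2-vectors of covariate names (candidate
#'   covariate-covariate interactions).
#' @param iv_interactions covariates given candidate interactions with the
#'   instrument (stage 1) / propensity score (stage 2).
#' @param pscore_poly_degree degree of the (forced, orthogonal) polynomial
#'   basis in the estimated propensity in the outcome model.
#' @return An object of class `liv_terms`.
#' @export
liv_terms <- function(covariates = c("age", "female", "ethnicity", "hba1c",
                                     "bmi", "egfr", "sbp", "dbp",
                                     "duration"),
                      quadratic = c("age", "hba1c"),
                      interactions = list(c("hba1c", "age"),
                                          c("hba1c", "female"),
                                          c("hba1c", "bmi")),
                      iv_interactions = c("hba1c", "egfr", "bmi", "sbp",
                                          "age"),
                      pscore_poly_degree = 3L) {
  stopifnot(pscore_poly_degree >= 1L)
  structure(list(covariates = covariates,
                 quadratic = quadratic,
                 interactions = interactions,
                 iv_interactions = iv_interactions,
                 pscore_poly_degree = as.integer(pscore_poly_degree)),
            class = "liv_terms")
}

#' @export
print.liv_terms <- function(x, ...) {
  cat("LIV term set\n")
  cat("  main:        ", paste(x$covariates, collapse = ", "), "\n")
  cat("  quadratic:   ", paste(x$quadratic, collapse = ", "), "\n")
  cat("  interactions:",
      paste(vapply(x$interactions, paste, "", collapse = ":"),
            collapse = ", "), "\n")
  cat("  iv/pscore x: ", paste(x$iv_interactions, collapse = ", "), "\n")
  cat("  pscore polynomial degree:", x$pscore_poly_degree, "\n")
  invisible(x)
}

# Numeric main-effect matrix: factors expanded to treatment-coded dummies.
main_effect_matrix <- function(data, covariates) {
  missing <- setdiff(covariates, names(data))
  if (length(missing))
    stop("covariate column(s) absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mm <- stats::model.matrix(stats::reformulate(covariates),
                            data = data)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

numeric_column <- function(data, nm) {
  v <- data[[nm]]
  if (!is.numeric(v))
    stop("term '", nm, "' requires a numeric column", call. = FALSE)
  v
}

# Candidate columns shared by both stages (quadratics + covariate
# interactions); returned as a named matrix, possibly with zero columns.
candidate_x_matrix <- function(data, terms) {
  cols <- list()
  for (q in terms$quadratic)
    cols[[paste0(q, "^2")]] <- numeric_column(data, q)^2
  for (pr in terms$interactions)
    cols[[paste(pr, collapse = ":")]] <-
      numeric_column(data, pr[1]) * numeric_column(data, pr[2])
  if (!length(cols)) return(matrix(numeric(0), nrow(data), 0))
  do.call(cbind, cols)
}

# Instrument/propensity interaction columns; `iv` is the stage-specific
# running variable (Z in stage 1, p-hat in stage 2), `prefix` labels it.
iv_interaction_matrix <- function(data, terms, iv, prefix) {
  if (!length(terms$iv_interactions))
    return(matrix(numeric(0), nrow(data), 0))
  cols <- lapply(terms$iv_interactions, function(v)
    iv * numeric_column(data, v))
  m <- do.call(cbind, cols)
  colnames(m) <- paste(prefix, terms$iv_interactions, sep = ":")
  m
}

# Plugin-penalty ("rigorous") lasso with heteroscedasticity-robust penalty
# loadings (Belloni-Chernozhukov-Hansen). Unpenalized (forced) columns and
# the intercept are partialled out of the response and the candidate columns
# first -- selection is unchanged by Frisch-Waugh when those columns carry no
# penalty, and the loadings are then computed on the partialled columns as in
# the standard rigorous-lasso implementations. Returns the names of the
# penalized columns with nonzero coefficients.
plugin_lasso <- function(X, y, penalize, c0 = 1.1, gamma = NULL,
                         n_iter = 2L) {
  p_pen <- sum(penalize)
  if (p_pen == 0L) return(character(0))
  n <- nrow(X)
  if (is.null(gamma)) gamma <- 0.1 / log(max(n, 3))
  lam <- 2 * c0 * sqrt(n) * stats::qnorm(1 - gamma / (2 * p_pen))
  lam_unit <- lam / (2 * n)   # per-unit-loading penalty on the 1/(2n)
                              # RSS scale glmnet uses

  qf <- qr(cbind(`(Intercept)` = 1, X[, !penalize, drop = FALSE]))
  yt <- qr.resid(qf, y)
  Xt <- qr.resid(qf, X[, penalize, drop = FALSE])
  cand <- colnames(X)[penalize]
  e <- yt
  sel <- character(0)
  for (it in seq_len(n_iter)) {
    psi <- sqrt(colMeans(Xt^2 * e^2))
    psi[psi < 1e-12] <- 1e-12
    if (p_pen == 1L) {
      # univariate lasso: closed-form soft threshold
      b <- soft_threshold(mean(Xt[, 1] * yt), lam_unit * psi) /
        mean(Xt[, 1]^2)
    } else {
      # glmnet rescales penalty.factor to mean 1; compensate in lambda
      lam_g <- lam_unit * mean(psi)
      fit <- glmnet::glmnet(Xt, yt, lambda = lam_g, penalty.factor = psi,
                            standardize = FALSE, intercept = FALSE)
      b <- as.numeric(fit$beta)
    }
    sel <- cand[abs(b) > 1e-10]
    e <- yt - as.numeric(Xt %*% b)
  }
  sel
}

soft_threshold <- function(x, t) sign(x) * max(abs(x) - t, 0)

#' Stage-wise plugin-lasso term selection
#'
#' Runs the plugin-penalty lasso on one stage's candidate terms. In stage 1
#' the response is the treatment indicator regressed on the instrument
#' (forced), main covariate effects (forced), and the candidate quadratic,
#' covariate-interaction and instrument-interaction columns; in stage 2 the
#' response is the outcome regressed on the propensity basis (forced), main
#' effects (forced) and the analogous candidates with the propensity as the
#' running variable. Candidate names are stage-agnostic so selections can be
#' unioned across stages ([liv()] uses the union in both stages).
#'
#' @param data cohort data.frame (complete cases).
#' @param terms a [liv_terms()] candidate set.
#' @param stage 1 or 2.
#' @param iv the stage's running variable: the instrument column values
#'   (stage 1) or the estimated propensity (stage 2).
#' @param response the stage's response values (treatment for stage 1,
#'   outcome for stage 2).
#' @return A `liv_terms` object whose candidate slots are reduced to the
#'   selected terms (main effects and forced terms unchanged), with a
#'   `selected` attribute listing the stage-agnostic selected names.
#' @export
select_terms_lasso <- function(data, terms, stage, iv, response) {
  stopifnot(inherits(terms, "liv_terms"), stage %in% c(1L, 2L))
  Xmain <- main_effect_matrix(data, terms$covariates)
  Xcand <- candidate_x_matrix(data, terms)
  prefix <- if (stage == 1L) "iv" else "pscore"
  Xiv <- iv_interaction_matrix(data, terms, iv, prefix)
  forced_iv <- matrix(iv, ncol = 1,
                      dimnames = list(NULL, if (stage == 1L) "iv" else
                        "pscore"))
  X <- cbind(forced_iv, Xmain, Xcand, Xiv)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("singular candidate design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  penalize <- c(FALSE, rep(FALSE, ncol(Xmain)),
                rep(TRUE, ncol(Xcand)), rep(TRUE, ncol(Xiv)))
  sel <- plugin_lasso(X, response, penalize)
  # strip the stage prefix so iv:x (stage 1) and pscore:x (stage 2) match
  sel_canon <- sub(paste0("^", prefix, ":"), "iv:", sel)
  restrict_terms(terms, sel_canon)
}

# Reduce a candidate liv_terms object to a set of selected canonical names.
restrict_terms <- function(terms, selected) {
  out <- terms
  out$quadratic <- terms$quadratic[paste0(terms$quadratic, "^2") %in%
                                     selected]
  out$interactions <- Filter(function(pr)
    paste(pr, collapse = ":") %in% selected, terms$interactions)
  out$iv_interactions <- terms$iv_interactions[
    paste0("iv:", terms$iv_interactions) %in% selected]
  attr(out, "selected") <- selected
  out
}

# Union of two selected liv_terms objects (stage-agnostic candidates).
union_terms <- function(candidate, a, b) {
  restrict_terms(candidate,
                 union(attr(a, "selected") %||% character(0),
                       attr(b, "selected") %||% character(0)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
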