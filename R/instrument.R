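#' Tendency-to-prescribe from a prescription history
#'
#' Computes the preference-based instrument for one patient: the fraction of
#' the cluster's prescription events falling in the `window_days` preceding
#' the patient's index date that were for the index drug class. The window
#' is the half-open interval `[index_date - window_days, index_date)`, so
#' the patient's own day-zero prescription is excluded.
#'
#' @param history data.frame with columns `cluster_id`, `event_date` (Date
#'   or numeric day), `drug_class` (1 = index drug class, 0 = comparator).
#' @param cluster_id cluster whose history to use.
#' @param index_date the patient's day zero.
#' @param window_days length of the preceding window (default 365).
#' @param min_events minimum event count below which the value is flagged
#'   low-support.
#' @return list with `ttp` (proportion in \[0,1\]), `n_events`, and logical
#'   `low_support`. Zero qualifying events is an error.
#' @export
compute_ttp <- function(history, cluster_id, index_date, window_days = 365,
                        min_events = 5L) {
  if (window_days <= 0) stop("window_days must be positive", call. = FALSE)
  h <- history[history$cluster_id == cluster_id, , drop = FALSE]
  dd <- as.numeric(h$event_date)
  t0 <- as.numeric(index_date)
  in_win <- dd >= t0 - window_days & dd < t0
  n <- sum(in_win)
  if (n == 0L)
    stop("no prescription events in the preceding ", window_days,
         "-day window for cluster ", cluster_id, call. = FALSE)
  list(ttp = mean(h$drug_class[in_win]), n_events = n,
       low_support = n < min_events)
}

# CR1 cluster-robust covariance for an lm fit.
cluster_vcov_cr1 <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  e <- stats::resid(fit)
  n <- nrow(X); k <- ncol(X)
  cl <- as.factor(cluster)
  G <- nlevels(cl)
  Xe <- X * e
  scores <- rowsum(Xe, cl)
  meat <- crossprod(scores)
  bread <- chol2inv(chol(crossprod(X)))
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  adj * bread %*% meat %*% bread
}

#' Weak-instrument test with region-clustered errors
#'
#' First-stage linear regression of treatment on the instrument and the
#' observed covariates; the reported F statistic is the squared t statistic
#' of the instrument coefficient using a CR1 region-clustered
#' (heteroscedasticity- and cluster-robust) variance. The conventional
#' strength benchmark for preference-based instruments in this setting is
#' F > 100.
#'
#' @param cohort cohort data.frame.
#' @param instrument,treatment,cluster column names.
#' @param covariates covariate columns adjusted for.
#' @return list of class `iv_diagnostics` with `f_statistic`, `f_benchmark`
#'   (100), `coef_z` (first-stage instrument coefficient), `se_z`,
#'   `n_clusters`, and `cluster_var` (variance of cluster-mean instrument
#'   values).
#' @export
weak_iv_test <- function(cohort, instrument = "ttp", treatment = "d",
                         cluster = "region_id",
                         covariates = c("age", "female", "ethnicity",
                                        "hba1c", "bmi", "egfr", "sbp",
                                        "dbp", "duration")) {
  z <- cohort[[instrument]]
  if (length(unique(z)) < 2L)
    stop("no instrument variation", call. = FALSE)
  if (length(unique(cohort[[cluster]])) < 2L)
    stop("at least 2 clusters (regions) required for the cluster-robust ",
         "weak-instrument test", call. = FALSE)
  covariates <- intersect(covariates, names(cohort))
  fml <- stats::reformulate(c(instrument, covariates), response = treatment)
  fit <- stats::lm(fml, data = cohort)
  V <- cluster_vcov_cr1(fit, cohort[[cluster]])
  i <- match(instrument, names(stats::coef(fit)))
  se <- sqrt(V[i, i])
  f <- (stats::coef(fit)[i] / se)^2
  cl_col <- if (!is.null(cohort$cluster_id)) cohort$cluster_id else
    cohort[[cluster]]
  cm <- tapply(z, cl_col, mean)
  structure(list(f_statistic = unname(f), f_benchmark = 100,
                 coef_z = unname(stats::coef(fit)[i]), se_z = unname(se),
                 n_clusters = length(unique(cohort[[cluster]])),
                 cluster_var = stats::var(as.numeric(cm))),
            class = "iv_diagnostics")
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat(sprintf("Weak-instrument test (CR1 cluster-robust): F = %.1f ",
              x$f_statistic))
  cat(sprintf("(benchmark %g)\n", x$f_benchmark))
  cat(sprintf("  first-stage coefficient %.4f (SE %.4f), %d clusters\n",
              x$coef_z, x$se_z, x$n_clusters))
  invisible(x)
}

#' Covariate balance across instrument levels
#'
#' Splits the cohort into `n_bins` instrument bins (quantile cut points) and
#' reports the standardized mean difference of each observed covariate
#' between the top and bottom bins. |SMD| <= 0.1 is marked balanced; factor
#' covariates are expanded into level indicators.
#'
#' @param cohort cohort data.frame.
#' @param instrument instrument column.
#' @param covariates covariate columns to check.
#' @param n_bins number of instrument bins (>= 2).
#' @return data.frame with `covariate`, `mean_low`, `mean_high`, `smd`,
#'   `balanced`.
#' @export
balance_by_iv <- function(cohort, instrument = "ttp",
                          covariates = c("age", "female", "ethnicity",
                                         "hba1c", "bmi", "egfr", "sbp",
                                         "dbp", "duration"),
                          n_bins = 3L) {
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  z <- cohort[[instrument]]
  qs <- stats::quantile(z, probs = seq(0, 1, length.out = n_bins + 1L))
  bin <- cut(z, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  lo <- bin == 1L
  hi <- bin == max(bin)
  if (!any(lo) || !any(hi)) stop("empty instrument bin", call. = FALSE)

  cols <- list()
  for (cv in intersect(covariates, names(cohort))) {
    val <- cohort[[cv]]
    if (is.numeric(val) || is.logical(val)) {
      cols[[cv]] <- as.numeric(val)
    } else {
      f <- as.factor(val)
      for (lv in levels(f)) cols[[paste(cv, lv, sep = ":")]] <-
          as.numeric(f == lv)
    }
  }
  res <- lapply(names(cols), function(nm) {
    v <- cols[[nm]]
    m0 <- mean(v[lo]); m1 <- mean(v[hi])
    s <- sqrt((stats::var(v[lo]) + stats::var(v[hi])) / 2)
    smd <- if (isTRUE(all.equal(m0, m1))) 0 else (m1 - m0) / s
    data.frame(covariate = nm, mean_low = m0, mean_high = m1, smd = smd,
               balanced = abs(smd) <= 0.1, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
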