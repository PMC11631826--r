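#' Aggregate individual effects to ATE and subgroup CATEs
#'
#' Averages per-patient effect estimates (PeT effects from [liv()], or
#' recycled-prediction effects from [iptw_ra()]) overall and within each
#' stratum of a subgroup scheme, for one or more target populations defined
#' by row masks (e.g. the full target population and the RCT-eligible /
#' RCT-ineligible subpopulations).
#'
#' @param effects a `pet_result`, or a numeric vector of per-patient effect
#'   estimates aligned with `cohort`.
#' @param cohort the cohort the effects belong to.
#' @param scheme optional [subgroup_scheme()] for CATEs.
#' @param populations named list of logical masks over `cohort` rows;
#'   defaults to the full cohort as population "target".
#' @param min_n strata smaller than this are flagged `small_sample` (still
#'   reported).
#' @param method method label attached to the rows.
#' @return data.frame with columns `method`, `population`, `scheme`,
#'   `subgroup`, `n`, `estimate`, `small_sample`.
#' @export
aggregate_effects <- function(effects, cohort, scheme = NULL,
                              populations = NULL, min_n = 10L,
                              method = "LIV") {
  eff <- if (inherits(effects, "pet_result")) effects$effects$pet_effect
         else as.numeric(effects)
  if (length(eff) != nrow(cohort))
    stop("effects and cohort are not aligned", call. = FALSE)
  if (is.null(populations))
    populations <- list(target = rep(TRUE, nrow(cohort)))

  lab <- if (!is.null(scheme)) assign_subgroups(cohort, scheme) else NULL
  rows <- list()
  for (pop in names(populations)) {
    m <- populations[[pop]] & !is.na(populations[[pop]])
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, population = pop, scheme = "overall",
      subgroup = "overall", n = sum(m),
      estimate = if (any(m)) mean(eff[m]) else NA_real_,
      small_sample = sum(m) < min_n, stringsAsFactors = FALSE)
    if (!is.null(scheme)) {
      for (sc in attr(scheme, "columns")) {
        col <- lab[[sc]]
        for (lv in levels(col)) {
          mm <- m & !is.na(col) & col == lv
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, population = pop, scheme = sc, subgroup = lv,
            n = sum(mm),
            estimate = if (any(mm)) mean(eff[mm]) else NA_real_,
            small_sample = sum(mm) < min_n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

# Stratified resampling of row indices with replacement, preserving stratum
# sizes. `strata` is a factor/interaction over rows (NULL = whole sample).
resample_indices <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n, n, replace = TRUE))
  idx <- integer(n)
  pos <- split(seq_len(n), strata, drop = TRUE)
  at <- 1L
  for (g in pos) {
    k <- length(g)
    idx[at:(at + k - 1L)] <- g[sample.int(k, k, replace = TRUE)]
    at <- at + k
  }
  idx
}

#' Stratified nonparametric bootstrap confidence intervals
#'
#' Resamples patients with replacement within each stratum (by default
#' region x treatment, mirroring the study design), re-runs a user-supplied
#' pipeline closure on each resample, and attaches t-distribution intervals
#' `point +/- t(1 - alpha/2, B - 1) * SD(bootstrap estimates)` centred at
#' the full-sample estimate. Per-replicate seeds are derived from the master
#' seed and recorded; failed replicates are skipped and counted, and the run
#' aborts if more than 5% fail.
#'
#' @param statistic function `(data, seed) -> named numeric vector` that
#'   re-runs the full estimation (with a frozen model specification) on a
#'   resampled cohort.
#' @param data the cohort to resample.
#' @param B number of bootstrap replicates (>= 2).
#' @param alpha two-sided level (default 0.05 for 95% intervals).
#' @param strata character vector of stratification columns, or NULL for an
#'   ordinary nonparametric bootstrap.
#' @param seed master seed.
#' @return list with `point`, `ci_low`, `ci_high` (named vectors), `B_used`,
#'   `n_failed`, `replicates` (B x k matrix), `seeds`.
#' @export
bootstrap_ci <- function(statistic, data, B = 500L, alpha = 0.05,
                         strata = c("region_id", "d"), seed = 1L) {
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  strat_f <- if (is.null(strata)) NULL else
    interaction(data[strata], drop = TRUE)
  point <- statistic(data, seed)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, B)
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- resample_indices(nrow(data), strat_f)
    est <- tryCatch(statistic(data[idx, , drop = FALSE], rep_seeds[b]),
                    error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else reps[b, ] <- est
  }
  if (n_failed > 0.05 * B)
    stop(n_failed, " of ", B, " bootstrap replicates failed (more than ",
         "5%); aborting", call. = FALSE)
  sds <- apply(reps, 2, stats::sd, na.rm = TRUE)
  half <- stats::qt(1 - alpha / 2, df = B - 1L) * sds
  list(point = point, ci_low = point - half, ci_high = point + half,
       B_used = B - n_failed, n_failed = n_failed, replicates = reps,
       seeds = rep_seeds, alpha = alpha)
}

#' Bootstrap confidence intervals for a fitted LIV model
#'
#' Re-runs the two-stage LIV estimation (propensity, outcome, PeT,
#' aggregation) on stratified resamples of the cohort, holding the selected
#' term specification fixed, and returns the effect table with t-interval
#' confidence bounds. Lasso selection is performed once on the full sample;
#' replicates reuse that specification.
#'
#' @param object a fitted [liv()] model.
#' @param data the cohort the model was fitted on.
#' @param B,alpha,strata,seed see [bootstrap_ci()].
#' @param scheme optional [subgroup_scheme()] for subgroup CATEs.
#' @param populations optional named list of row masks (see
#'   [aggregate_effects()]).
#' @return The [aggregate_effects()] table with `ci_low`, `ci_high` and `B`
#'   columns appended.
#' @export
liv_boot <- function(object, data, B = 500L, alpha = 0.05,
                     strata = c("region_id", "d"), seed = 1L,
                     scheme = NULL, populations = NULL) {
  stopifnot(inherits(object, "liv"))
  frozen <- object$terms
  vars <- object$vars
  masks_of <- function(d) {
    if (is.null(populations)) return(NULL)
    lapply(populations, function(msk) {
      if (is.logical(msk)) stop("populations for liv_boot must be ",
                                "functions of the resampled cohort",
                                call. = FALSE)
      msk(d)
    })
  }
  statistic <- function(d, s) {
    fit <- liv(object$formula, d, terms = frozen, select = "none",
               n_draws = object$n_draws, clip = object$clip,
               seed = (s %% 2147483L) + 1L)
    tab <- aggregate_effects(fit$pet, d, scheme, masks_of(d))
    stats::setNames(tab$estimate,
                    paste(tab$population, tab$scheme, tab$subgroup,
                          sep = "|"))
  }
  bs <- bootstrap_ci(statistic, data, B = B, alpha = alpha,
                     strata = strata, seed = seed)
  tab <- aggregate_effects(object$pet, data, scheme, masks_of(data))
  key <- paste(tab$population, tab$scheme, tab$subgroup, sep = "|")
  tab$ci_low <- unname(bs$ci_low[key])
  tab$ci_high <- unname(bs$ci_high[key])
  tab$B <- bs$B_used
  attr(tab, "bootstrap") <- bs
  tab
}

#' Estimate agreement with a benchmark trial
#'
#' The binary benchmark metric: the emulation's point estimate agrees with
#' the benchmark RCT if it lies inside the RCT's 95% confidence interval
#' (closed at the endpoints).
#'
#' @param target_point the emulation's point estimate (mmol/mol).
#' @param benchmark_point the benchmark RCT point estimate (reported for
#'   context, not used in the criterion).
#' @param benchmark_ci length-2 numeric, the benchmark 95% CI.
#' @return list with `agree` (logical), `target_point`, `benchmark_point`,
#'   `benchmark_ci`.
#' @export
estimate_agreement <- function(target_point, benchmark_point = NA_real_,
                               benchmark_ci) {
  if (is.null(benchmark_ci) || length(benchmark_ci) != 2L ||
      any(is.na(benchmark_ci)))
    stop("a benchmark confidence interval is required", call. = FALSE)
  if (benchmark_ci[1] > benchmark_ci[2])
    stop("benchmark CI bounds are reversed", call. = FALSE)
  list(agree = target_point >= benchmark_ci[1] &
         target_point <= benchmark_ci[2],
       target_point = target_point, benchmark_point = benchmark_point,
       benchmark_ci = benchmark_ci)
}
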