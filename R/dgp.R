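#' Configuration of the synthetic cohort generator
#'
#' Builds the full parameter set of the data-generating process used to
#' emulate a primary-care cohort of second-line antidiabetic initiators:
#' prescribing clusters with heterogeneous tendency-to-prescribe (the
#' instrument), latent-index treatment selection, overt effect modification
#' through observed covariates, essential heterogeneity through the latent
#' resistance \eqn{V}, unobserved baseline confounding, and outcome
#' missingness.
#'
#' The selection model is \eqn{D = 1\{\Phi(\mu_D(x, z)) > V\}} with
#' \eqn{V \sim U[0,1]} independent of \eqn{(Z, X)}. The treatment-effect
#' model is \eqn{Y_1 - Y_0 = \tau_0 + \tau_x' x + \eta} with
#' \eqn{\eta = \rho_{ess}\,\sigma_g\,\Phi^{-1}(V) +
#' \sqrt{1-\rho_{ess}^2}\,\sigma_g\,\xi}, so that
#' \eqn{E[Y_1-Y_0 \mid x, V=v] = \tau_0 + \tau_x' x +
#' \rho_{ess}\sigma_g\Phi^{-1}(v)} is available in closed form (see
#' [closed_form_mte()]) while the marginal gain variance stays
#' \eqn{\sigma_g^2}. Baseline noise is correlated with selection through
#' \eqn{\epsilon_0 = \rho_{conf}\sigma_y\Phi^{-1}(V) +
#' \sqrt{1-\rho_{conf}^2}\sigma_y e}.
#'
#' Index coefficients (`selection_coefs`, `mu0_coefs`, `tau_x`) are named
#' vectors over `intercept`, `z`, the continuous covariates (`age`, `hba1c`,
#' `bmi`, `egfr`, `sbp`, `dbp`, `duration`; centred at their configured
#' means), `female`, ethnicity dummies (`eth_south_asian`,
#' `eth_black_mixed_other`) and centred squares `age2`, `hba1c2`.
#'
#' @param n_patients number of patients in the cohort.
#' @param n_clusters number of prescribing clusters (CCG analogues).
#' @param n_regions number of geographical regions grouping the clusters.
#' @param cluster_pref_spread SD of the cluster-level probit-scale preference
#'   shifts generating between-cluster tendency-to-prescribe variation.
#' @param base_ttp marginal prescribing share of the index drug class that
#'   cluster preferences are centred on.
#' @param bg_events_per_year background second-line initiation events per
#'   cluster per year feeding the rolling tendency-to-prescribe window
#'   (prescriptions to eligible patients outside the sampled cohort).
#' @param covariate_params list of covariate distribution parameters; see
#'   [default_covariate_params()].
#' @param selection_coefs named coefficients of the latent selection index
#'   \eqn{\mu_D(x, z)}; must contain a strictly positive `z` coefficient
#'   (monotonicity by construction).
#' @param mu0_coefs named coefficients of the untreated mean outcome
#'   \eqn{\mu_0(x)} (change in HbA1c, mmol/mol).
#' @param tau0 baseline treatment effect (mmol/mol; negative favours the
#'   index drug class).
#' @param tau_x named observed-effect-modifier coefficients.
#' @param rho_ess essential-heterogeneity strength in \[-1, 1\].
#' @param sigma_gain SD of the unobserved gain component (mmol/mol).
#' @param rho_conf correlation of baseline outcome noise with the selection
#'   unobservable (unobserved confounding), in \[-1, 1\].
#' @param sigma_y outcome noise SD (mmol/mol).
#' @param missing_outcome_prob probability the follow-up HbA1c is missing
#'   (independent of the outcome given covariates).
#' @param measurement_jitter_days SD of the follow-up measurement offset
#'   around day 364 (days).
#' @param min_ttp_events minimum prior events in the rolling window below
#'   which the instrument value is flagged low-support.
#' @param seed master integer seed; expanded into per-cluster streams so
#'   cluster subsets are reproducible.
#' @return An object of class `dgp_config` (a validated list).
#' @seealso [generate_cohort()], [closed_form_mte()], [true_estimands()]
#' @export
dgp_config <- function(n_patients = 10000L,
                       n_clusters = 160L,
                       n_regions = 10L,
                       cluster_pref_spread = 0.6,
                       base_ttp = 0.37,
                       bg_events_per_year = 60,
                       covariate_params = default_covariate_params(),
                       selection_coefs = c(intercept = -1.7, z = 3.5,
                                           hba1c = -0.012, bmi = 0.02),
                       mu0_coefs = c(intercept = -8, hba1c = -0.35),
                       tau0 = -1.3,
                       tau_x = c(hba1c = -0.1),
                       rho_ess = 0.4,
                       sigma_gain = 3,
                       rho_conf = 0.3,
                       sigma_y = 9,
                       missing_outcome_prob = 0.318,
                       measurement_jitter_days = 30,
                       min_ttp_events = 5L,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_clusters = as.integer(n_clusters),
              n_regions = as.integer(n_regions),
              cluster_pref_spread = cluster_pref_spread,
              base_ttp = base_ttp,
              bg_events_per_year = bg_events_per_year,
              covariate_params = covariate_params,
              selection_coefs = selection_coefs,
              mu0_coefs = mu0_coefs,
              tau0 = tau0, tau_x = tau_x,
              rho_ess = rho_ess, sigma_gain = sigma_gain,
              rho_conf = rho_conf, sigma_y = sigma_y,
              missing_outcome_prob = missing_outcome_prob,
              measurement_jitter_days = measurement_jitter_days,
              min_ttp_events = as.integer(min_ttp_events),
              seed = as.integer(seed))
  validate_dgp_config(cfg)
  class(cfg) <- "dgp_config"
  cfg
}

#' Default covariate distribution parameters
#'
#' Marginals broadly matching a UK primary-care type 2 diabetes cohort at
#' second-line treatment intensification: age about 61 (SD 12) years,
#' baseline HbA1c about 73 (SD 17) mmol/mol, BMI about 32.5 (SD 6.3) kg/m2,
#' about 40% female, ethnicity 87/9/4% white / South Asian /
#' black-mixed-other. Continuous covariates are truncated normals (diabetes
#' duration is gamma). The `mean` entries double as centring constants for
#' the index coefficients in [dgp_config()].
#'
#' @return A named list of per-covariate parameter lists.
#' @export
default_covariate_params <- function() {
  list(
    age      = list(mean = 61,   sd = 11.6, lower = 18,  upper = 95),
    hba1c    = list(mean = 73,   sd = 17,   lower = 31,  upper = 140),
    bmi      = list(mean = 32.5, sd = 6.3,  lower = 15,  upper = 60),
    egfr     = list(mean = 80,   sd = 18,   lower = 15,  upper = 130),
    sbp      = list(mean = 134,  sd = 15,   lower = 90,  upper = 200),
    dbp      = list(mean = 80,   sd = 10,   lower = 50,  upper = 120),
    duration = list(mean = 5.5,  sd = 4.8,  lower = 0,   upper = 40),
    female   = list(prob = 0.40),
    ethnicity = list(levels = c("white", "south_asian", "black_mixed_other"),
                     probs = c(0.87, 0.09, 0.04))
  )
}

#' Oracle configuration for parameter-recovery checks
#'
#' A [dgp_config()] preset used by the recovery tests: no observed effect
#' modification (`tau_x` empty) so the marginal treatment effect reduces to
#' \eqn{\tau_0 + \rho_{ess}\sigma_{gain}\Phi^{-1}(v)}; essential
#' heterogeneity at `rho_ess = 0.5`, `sigma_gain = 4` (MTE slope 2 per
#' probit quantile); no outcome missingness; a wide cluster preference
#' spread so the propensity support covers the interior of the unit
#' interval; and a small residual outcome SD so Monte-Carlo error is small
#' relative to the recovery tolerances. The estimator is given no knowledge
#' of the generating model beyond its observed columns.
#'
#' @param n_patients,seed passed to [dgp_config()].
#' @param ... overrides for any other [dgp_config()] argument.
#' @return A `dgp_config`.
#' @export
oracle_config <- function(n_patients = 50000L, seed = 1L, ...) {
  args <- list(n_patients = n_patients, seed = seed,
               tau0 = -1.3, tau_x = numeric(0),
               rho_ess = 0.5, sigma_gain = 4, rho_conf = 0.3,
               sigma_y = 2.5, base_ttp = 0.5, cluster_pref_spread = 1.0,
               selection_coefs = c(intercept = -1.75, z = 3.5,
                                   hba1c = -0.02, bmi = 0.03),
               missing_outcome_prob = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(dgp_config, args)
}

validate_dgp_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_patients <= 0L)
    stop("invalid dgp_config: n_patients must be positive", call. = FALSE)
  if (cfg$n_clusters <= 0L)
    stop("invalid dgp_config: n_clusters must be positive", call. = FALSE)
  if (cfg$n_clusters > cfg$n_patients)
    stop("invalid dgp_config: n_clusters exceeds n_patients", call. = FALSE)
  if (cfg$n_regions < 1L || cfg$n_regions > cfg$n_clusters)
    stop("invalid dgp_config: n_regions must be in [1, n_clusters]",
         call. = FALSE)
  for (nm in c("base_ttp", "missing_outcome_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("invalid dgp_config: %s must be in [0, 1]", nm),
           call. = FALSE)
  }
  for (nm in c("rho_ess", "rho_conf")) {
    if (abs(cfg[[nm]]) > 1)
      stop(sprintf("invalid dgp_config: %s must be in [-1, 1]", nm),
           call. = FALSE)
  }
  for (nm in c("cluster_pref_spread", "sigma_gain", "sigma_y",
               "measurement_jitter_days")) {
    if (cfg[[nm]] < 0)
      stop(sprintf("invalid dgp_config: %s must be >= 0", nm), call. = FALSE)
  }
  zc <- cfg$selection_coefs["z"]
  if (is.na(zc) || zc <= 0)
    stop("invalid dgp_config: selection_coefs must include a strictly ",
         "positive coefficient on z (monotonicity)", call. = FALSE)
  invisible(cfg)
}

# Truncated-normal sampler via the inverse-CDF of the truncated distribution.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Per-cluster seeds derived from the master seed; kept inside 32-bit range.
cluster_seeds <- function(seed, n_clusters) {
  (as.double(seed %% 65011L) * 32717 + 7919 * seq_len(n_clusters)) %%
    2147483587
}

# Evaluate a named index-coefficient vector on a covariate data.frame.
# Continuous covariates are centred at their configured means; `age2` and
# `hba1c2` are squares of the centred values.
eval_index <- function(coefs, x, z = NULL, centers) {
  idx <- rep(0, nrow(x))
  for (nm in names(coefs)) {
    b <- coefs[[nm]]
    idx <- idx + b * switch(nm,
      intercept = 1,
      z = { if (is.null(z)) stop("index uses z but none supplied"); z },
      female = x$female,
      eth_south_asian = as.numeric(x$ethnicity == "south_asian"),
      eth_black_mixed_other = as.numeric(x$ethnicity == "black_mixed_other"),
      age2 = (x$age - centers["age"])^2,
      hba1c2 = (x$hba1c - centers["hba1c"])^2,
      {
        if (!nm %in% names(x)) stop("unknown index term: ", nm)
        x[[nm]] - centers[nm]
      })
  }
  idx
}

index_centers <- function(covariate_params) {
  cont <- c("age", "hba1c", "bmi", "egfr", "sbp", "dbp", "duration")
  vapply(cont, function(nm) covariate_params[[nm]]$mean, numeric(1))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates a patient-level cohort per the configured data-generating
#' process: patients are assigned to clusters with heterogeneous prescribing
#' preferences; each patient's instrument value is the tendency-to-prescribe
#' computed from the cluster's prescription events (background events plus
#' earlier cohort patients' own prescriptions) in the 365 days preceding the
#' patient's index date; treatment follows the latent-index rule
#' \eqn{D = 1\{\Phi(\mu_D(x,z)) > V\}}; potential outcomes carry overt and
#' essential heterogeneity and correlated baseline noise; follow-up
#' measurement dates are jittered around day 364 and outcomes are set
#' missing at the configured rate.
#'
#' @param config a [dgp_config()] object.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `cohort` (patient-level data.frame, one row per patient), `truth`
#'   (parallel data.frame of simulation-only ground truth: `v`, `y0`, `y1`,
#'   `individual_effect`, `eta`, `eps0`), `history` (cluster prescription
#'   events: `cluster_id`, `event_date`, `drug_class`) and `dgp` (the
#'   config).
#' @export
generate_cohort <- function(config) {
  validate_dgp_config(config)
  cfg <- config
  set.seed(cfg$seed)

  centers <- index_centers(cfg$covariate_params)
  study_start <- 365L         # days since 2010-01-01; entry opens 2011-01-01
  study_end <- 2190L          # 2015-12-31
  origin <- as.Date("2010-01-01")

  cluster_region <- sort(rep_len(seq_len(cfg$n_regions), cfg$n_clusters))
  sizes <- as.vector(stats::rmultinom(1, cfg$n_patients,
                                      rep(1, cfg$n_clusters)))
  # guarantee no empty cluster when patients allow it
  while (any(sizes == 0L) && cfg$n_patients >= cfg$n_clusters) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
  }
  cseeds <- cluster_seeds(cfg$seed, cfg$n_clusters)

  cohort_list <- vector("list", cfg$n_clusters)
  truth_list <- vector("list", cfg$n_clusters)
  hist_list <- vector("list", cfg$n_clusters)
  next_id <- 1L

  for (k in seq_len(cfg$n_clusters)) {
    nk <- sizes[k]
    set.seed(cseeds[k])
    alpha_k <- stats::rnorm(1, 0, cfg$cluster_pref_spread)
    pi_k <- stats::pnorm(stats::qnorm(cfg$base_ttp) + alpha_k)

    # background prescriptions: burn-in year through study end
    n_bg <- max(1L, round(cfg$bg_events_per_year * (study_end / 365)))
    bg_date <- sort(stats::runif(n_bg, 0, study_end))
    bg_drug <- stats::rbinom(n_bg, 1, pi_k)
    bg_cum <- c(0, cumsum(bg_drug))

    if (nk == 0L) {
      hist_list[[k]] <- data.frame(cluster_id = k, event_date = bg_date,
                                   drug_class = bg_drug)
      next
    }

    idx_date <- sort(stats::runif(nk, study_start, study_end))
    cp <- cfg$covariate_params
    x <- data.frame(
      age = rtruncnorm(nk, cp$age$mean, cp$age$sd, cp$age$lower, cp$age$upper),
      female = stats::rbinom(nk, 1, cp$female$prob),
      ethnicity = sample(cp$ethnicity$levels, nk, TRUE, cp$ethnicity$probs),
      hba1c = rtruncnorm(nk, cp$hba1c$mean, cp$hba1c$sd, cp$hba1c$lower,
                         cp$hba1c$upper),
      bmi = rtruncnorm(nk, cp$bmi$mean, cp$bmi$sd, cp$bmi$lower, cp$bmi$upper),
      egfr = rtruncnorm(nk, cp$egfr$mean, cp$egfr$sd, cp$egfr$lower,
                        cp$egfr$upper),
      sbp = rtruncnorm(nk, cp$sbp$mean, cp$sbp$sd, cp$sbp$lower, cp$sbp$upper),
      dbp = rtruncnorm(nk, cp$dbp$mean, cp$dbp$sd, cp$dbp$lower, cp$dbp$upper),
      duration = pmin(stats::rgamma(nk,
                                    shape = (cp$duration$mean / cp$duration$sd)^2,
                                    rate = cp$duration$mean / cp$duration$sd^2),
                      cp$duration$upper)
    )
    v <- stats::runif(nk)
    w <- stats::qnorm(v)
    xi <- stats::rnorm(nk)
    e0 <- stats::rnorm(nk)
    jit <- round(stats::rnorm(nk, 0, cfg$measurement_jitter_days))
    miss <- stats::runif(nk) < cfg$missing_outcome_prob
    hb_lag <- pmin(round(stats::rexp(nk, 1 / 45)), 250)

    # rolling tendency-to-prescribe and sequential treatment assignment
    z <- numeric(nk); d <- integer(nk); low_support <- logical(nk)
    n_events <- integer(nk)
    sel_fixed <- eval_index(cfg$selection_coefs[setdiff(names(cfg$selection_coefs), "z")],
                            x, z = NULL, centers)
    zc <- cfg$selection_coefs[["z"]]
    cumd <- 0; cumd_pre <- numeric(nk + 1L)  # prefix sums of patient D
    lptr <- 1L
    for (i in seq_len(nk)) {
      lo <- idx_date[i] - 365
      a <- findInterval(lo, bg_date) + 1L
      b <- findInterval(idx_date[i] - 1e-9, bg_date)
      nb <- max(0L, b - a + 1L)
      sb <- if (nb > 0L) bg_cum[b + 1L] - bg_cum[a] else 0
      while (lptr < i && idx_date[lptr] < lo) lptr <- lptr + 1L
      np <- i - lptr
      sp <- cumd_pre[i] - cumd_pre[lptr]
      ntot <- nb + np
      if (ntot == 0L)
        stop("no prescription events in the preceding 365-day window for ",
             "cluster ", k, call. = FALSE)
      z[i] <- (sb + sp) / ntot
      n_events[i] <- ntot
      low_support[i] <- ntot < cfg$min_ttp_events
      d[i] <- as.integer(stats::pnorm(sel_fixed[i] + zc * z[i]) > v[i])
      cumd_pre[i + 1L] <- cumd_pre[i] + d[i]
    }

    gain <- cfg$tau0 + eval_index(cfg$tau_x, x, z = NULL, centers) +
      cfg$rho_ess * cfg$sigma_gain * w +
      sqrt(1 - cfg$rho_ess^2) * cfg$sigma_gain * xi
    eps0 <- cfg$rho_conf * cfg$sigma_y * w +
      sqrt(1 - cfg$rho_conf^2) * cfg$sigma_y * e0
    y0 <- eval_index(cfg$mu0_coefs, x, z = NULL, centers) + eps0
    y1 <- y0 + gain
    y <- ifelse(d == 1L, y1, y0)

    ids <- seq.int(next_id, next_id + nk - 1L)
    next_id <- next_id + nk

    followup_date <- idx_date + 364 + jit
    cohort_list[[k]] <- data.frame(
      patient_id = ids, cluster_id = k, region_id = cluster_region[k],
      index_date = origin + round(idx_date),
      d = d, ttp = z, ttp_events = n_events, ttp_low_support = low_support,
      x,
      baseline_hba1c_date = origin + round(idx_date) - hb_lag,
      followup_hba1c = ifelse(miss, NA_real_, x$hba1c + y),
      followup_date = as.Date(ifelse(miss, NA, origin + round(followup_date)),
                              origin = "1970-01-01"),
      y = ifelse(miss, NA_real_, y)
    )
    truth_list[[k]] <- data.frame(
      patient_id = ids, v = v, y0 = y0, y1 = y1,
      individual_effect = gain, eta = gain - cfg$tau0 -
        eval_index(cfg$tau_x, x, z = NULL, centers),
      eps0 = eps0
    )
    hist_list[[k]] <- data.frame(
      cluster_id = k,
      event_date = c(bg_date, idx_date),
      drug_class = c(bg_drug, d)
    )
  }

  cohort <- do.call(rbind, cohort_list)
  truth <- do.call(rbind, truth_list)
  rownames(cohort) <- rownames(truth) <- NULL
  if (length(unique(cohort$d)) < 2L)
    stop("degenerate treatment support: all patients received the same ",
         "treatment under this configuration", call. = FALSE)
  history <- do.call(rbind, hist_list)
  history <- history[order(history$cluster_id, history$event_date), ]
  rownames(history) <- NULL
  history$event_date <- origin + round(history$event_date)

  structure(list(cohort = cohort, truth = truth, history = history,
                 dgp = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "patients,",
      x$dgp$n_clusters, "clusters,", x$dgp$n_regions, "regions\n")
  cat(sprintf("  treated share: %.3f;  instrument range: [%.3f, %.3f]\n",
              mean(x$cohort$d), min(x$cohort$ttp), max(x$cohort$ttp)))
  cat(sprintf("  missing outcomes: %.1f%%\n",
              100 * mean(is.na(x$cohort$y))))
  invisible(x)
}

#' Closed-form marginal treatment effect of the generator
#'
#' For the generator's normal-gain model the marginal treatment effect at
#' latent resistance \eqn{v} is available in closed form:
#' \eqn{\Delta^{MTE}(x, v) = \tau_0 + \tau_x' x +
#' \rho_{ess}\,\sigma_{gain}\,\Phi^{-1}(v)}. This is the independent oracle
#' the fitted MTE curve is validated against.
#'
#' @param config a [dgp_config()].
#' @param x a one-row data.frame (or NULL when `tau_x` is empty) giving the
#'   covariate profile.
#' @param v latent resistance quantile(s), strictly inside (0, 1).
#' @return The MTE in mmol/mol (vectorised over `v`).
#' @export
closed_form_mte <- function(config, x = NULL, v) {
  if (any(v <= 0 | v >= 1))
    stop("v must lie strictly inside (0, 1)", call. = FALSE)
  centers <- index_centers(config$covariate_params)
  xterm <- 0
  if (length(config$tau_x)) {
    if (is.null(x))
      stop("config has tau_x effect modifiers; supply a covariate profile x",
           call. = FALSE)
    xterm <- eval_index(config$tau_x, as.data.frame(x), z = NULL, centers)
  }
  config$tau0 + xterm + config$rho_ess * config$sigma_gain * stats::qnorm(v)
}

#' True average and subgroup effects of a synthetic cohort
#'
#' Averages the simulated individual effects overall and within each stratum
#' of a subgroup scheme, giving the ground-truth ATE/CATEs that estimator
#' recovery is judged against.
#'
#' @param sc a `synthetic_cohort`.
#' @param scheme a [subgroup_scheme()]; `NULL` for the overall ATE only.
#' @return data.frame with columns `scheme`, `subgroup`, `n`, `true_effect`,
#'   and a logical `empty` flag for strata with no patients.
#' @export
true_estimands <- function(sc, scheme = NULL) {
  stopifnot(inherits(sc, "synthetic_cohort"))
  eff <- sc$truth$individual_effect
  out <- data.frame(scheme = "overall", subgroup = "overall",
                    n = length(eff), true_effect = mean(eff), empty = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(scheme)) {
    lab <- assign_subgroups(sc$cohort, scheme)
    for (sc_name in attr(scheme, "columns")) {
      col <- lab[[sc_name]]
      for (lv in levels(col)) {
        m <- !is.na(col) & col == lv
        out <- rbind(out, data.frame(
          scheme = sc_name, subgroup = lv, n = sum(m),
          true_effect = if (any(m)) mean(eff[m]) else NA_real_,
          empty = !any(m), stringsAsFactors = FALSE))
      }
    }
  }
  out
}
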