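#' Assemble a reproducible pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: the data-generating
#' configuration (or a path to an external cohort table), eligibility
#' settings, the subgroup scheme parameters, candidate terms, estimation
#' settings and seeds. The object round-trips losslessly through the YAML
#' config file written with each run.
#'
#' @param dgp a [dgp_config()], or NULL when `cohort_path` is given.
#' @param cohort_path optional path to an external cohort CSV in the
#'   [write_cohort()] schema.
#' @param hba1c_recency_days eligibility recency window for baseline HbA1c.
#' @param rct_age_range,rct_hba1c_range RCT-eligibility bounds.
#' @param select term-selection mode for [liv()].
#' @param pscore_poly_degree,n_draws,clip LIV estimation settings.
#' @param B bootstrap replicates (0 disables interval estimation).
#' @param alpha two-sided interval level.
#' @param benchmark optional list with `point` and `ci` (length 2) of a
#'   benchmark RCT estimate for the RCT-eligible population.
#' @param seed master seed for estimation streams (the DGP carries its own).
#' @return Object of class `run_config`.
#' @export
run_config <- function(dgp = dgp_config(), cohort_path = NULL,
                       hba1c_recency_days = 180,
                       rct_age_range = c(18, 78),
                       rct_hba1c_range = c(44, 87),
                       select = c("plugin", "none"),
                       pscore_poly_degree = 3L, n_draws = 1000L,
                       clip = 1e-3, B = 500L, alpha = 0.05,
                       benchmark = NULL, seed = 1L) {
  select <- match.arg(select)
  if (is.null(dgp) && is.null(cohort_path))
    stop("supply either a dgp config or a cohort_path", call. = FALSE)
  structure(list(dgp = dgp, cohort_path = cohort_path,
                 hba1c_recency_days = hba1c_recency_days,
                 rct_age_range = rct_age_range,
                 rct_hba1c_range = rct_hba1c_range,
                 select = select,
                 pscore_poly_degree = as.integer(pscore_poly_degree),
                 n_draws = as.integer(n_draws), clip = clip,
                 B = as.integer(B), alpha = alpha,
                 benchmark = benchmark, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read the cohort table schema
#'
#' Comma-separated, header row, ISO-8601 dates, empty string for missing.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out))
    if (inherits(out[[nm]], "Date")) out[[nm]] <- as.character(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  for (nm in intersect(c("index_date", "baseline_hba1c_date",
                         "followup_date"), names(x)))
    x[[nm]] <- as.Date(x[[nm]])
  x
}

# 32-bit FNV-1a hash of a character string, as 8 hex digits. Arithmetic is
# split into 16-bit halves so every intermediate stays exactly representable
# in doubles.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- (hl * prime + ((hh * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$dgp)) {
    cfg$dgp <- unclass(cfg$dgp)
    # named numeric vectors must become YAML mappings, not bare sequences
    for (nm in c("selection_coefs", "mu0_coefs", "tau_x"))
      cfg$dgp[[nm]] <- as.list(cfg$dgp[[nm]])
  }
  yaml::as.yaml(cfg, precision = 15)
}

#' Restore a run configuration from its YAML file
#'
#' @param path path to a `resolved_config.yaml` written by
#'   [run_pipeline()].
#' @return A `run_config` object.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$dgp)) {
    dg <- cfg$dgp
    for (nm in c("selection_coefs", "mu0_coefs", "tau_x")) {
      v <- unlist(dg[[nm]])
      dg[[nm]] <- if (is.null(v)) numeric(0) else v
    }
    cfg$dgp <- do.call(dgp_config, dg)
  }
  if (!is.null(cfg$benchmark)) cfg$benchmark$ci <- unlist(cfg$benchmark$ci)
  cfg$rct_age_range <- unlist(cfg$rct_age_range)
  cfg$rct_hba1c_range <- unlist(cfg$rct_hba1c_range)
  do.call(run_config, cfg[setdiff(names(cfg), character(0))])
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> eligibility -> subgroup labelling ->
#' RCT-eligibility split -> outcome windowing and complete-case filter ->
#' instrument diagnostics -> LIV estimation -> comparators -> aggregation
#' (-> bootstrap intervals -> benchmark agreement), writing every table,
#' the resolved configuration and a run manifest to `out_dir`. A stage
#' failure aborts with the stage name; outputs written so far are kept
#' under a `failed` marker file.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The run manifest (list), invisibly; all outputs are files.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (is.data.frame(obj)) write_cohort(obj, p) else
      yaml::write_yaml(obj, p)
    files <<- c(files, name)
  }
  stage <- "configure"
  on.exit({
    if (!is.null(stage))
      writeLines(paste("failed at stage:", stage),
                 file.path(out_dir, "FAILED"))
  })

  flow_counts <- list()
  stage <- "simulate"
  if (is.null(config$cohort_path)) {
    sc <- generate_cohort(config$dgp)
    cohort <- sc$cohort
    emit(sc$truth, "truth.csv")
  } else {
    sc <- NULL
    cohort <- read_cohort(config$cohort_path)
  }
  flow_counts$simulated <- nrow(cohort)
  emit(cohort, "cohort.csv")

  stage <- "eligibility"
  crit <- eligibility_criteria(hba1c_recency_days =
                                 config$hba1c_recency_days)
  el <- apply_eligibility(cohort, crit)
  cohort <- el$cohort
  emit(el$flow, "eligibility_flow.csv")
  flow_counts$eligible <- nrow(cohort)

  stage <- "subgroups"
  scheme <- subgroup_scheme()
  cohort <- assign_subgroups(cohort, scheme)
  cohort <- split_rct_eligibility(cohort, config$rct_age_range,
                                  config$rct_hba1c_range)

  stage <- "complete_case"
  cc <- complete_case_filter(cohort)
  emit(cc$missingness, "missingness.csv")
  cohort <- cc$cohort
  flow_counts$complete_case <- nrow(cohort)

  stage <- "instrument_diagnostics"
  ivd <- weak_iv_test(cohort)
  bal <- balance_by_iv(cohort)
  emit(bal, "iv_balance.csv")
  emit(data.frame(f_statistic = ivd$f_statistic,
                  f_benchmark = ivd$f_benchmark, coef_z = ivd$coef_z,
                  se_z = ivd$se_z, n_clusters = ivd$n_clusters,
                  cluster_var = ivd$cluster_var), "iv_diagnostics.csv")

  stage <- "liv_estimation"
  terms <- liv_terms(pscore_poly_degree = config$pscore_poly_degree)
  fit <- liv(y ~ d | ttp, cohort, terms = terms, select = config$select,
             n_draws = config$n_draws, clip = config$clip,
             seed = config$seed)
  emit(fit$pet$effects, "pet_effects.csv")

  populations <- list(
    target = function(d) rep(TRUE, nrow(d)),
    rct_eligible = function(d) d$rct_eligible %in% TRUE,
    rct_ineligible = function(d) d$rct_eligible %in% FALSE)
  masks <- lapply(populations, function(f) f(cohort))

  stage <- "comparators"
  ipw <- iptw_ra(cohort)
  tsls <- two_stage_least_squares(cohort)
  emit(aggregate_effects(ipw$effect, cohort, scheme, masks,
                         method = "IPTW-RA"), "effects_iptw_ra.csv")
  emit(data.frame(method = "2SLS", population = "target",
                  scheme = "overall", subgroup = "overall", n = tsls$n,
                  estimate = tsls$ate, ci_low = tsls$ci[1],
                  ci_high = tsls$ci[2], f_first_stage = tsls$f_first_stage),
       "effects_2sls.csv")

  stage <- "aggregation"
  if (config$B > 0L) {
    eff <- liv_boot(fit, cohort, B = config$B, alpha = config$alpha,
                    seed = config$seed, scheme = scheme,
                    populations = populations)
    attr(eff, "bootstrap") <- NULL
  } else {
    eff <- aggregate_effects(fit$pet, cohort, scheme, masks)
  }
  emit(eff, "effects_liv.csv")

  agreement <- NULL
  if (!is.null(config$benchmark)) {
    stage <- "agreement"
    pt <- eff$estimate[eff$population == "rct_eligible" &
                         eff$scheme == "overall"]
    agreement <- estimate_agreement(pt, config$benchmark$point,
                                    config$benchmark$ci)
    emit(agreement, "agreement.yaml")
  }

  stage <- "manifest"
  cfg_txt <- serialize_config(config)
  writeLines(cfg_txt, file.path(out_dir, "resolved_config.yaml"))
  files <- c(files, "resolved_config.yaml")
  manifest <- list(
    config_hash = fnv1a_hash(cfg_txt),
    seed = config$seed,
    dgp_seed = if (!is.null(config$dgp)) config$dgp$seed else NA,
    flow = flow_counts,
    f_statistic = ivd$f_statistic,
    n_unbalanced_covariates = sum(!bal$balanced),
    ate_liv = fit$ate,
    ate_iptw_ra = ipw$ate,
    ate_2sls = unname(tsls$ate),
    inference = if (config$B > 0L) paste0("bootstrap B=", config$B) else
      "skipped (B = 0)",
    agreement = if (!is.null(agreement)) agreement$agree else NA,
    files = files,
    package_version = as.character(utils::packageVersion("livhte")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  stage <- NULL
  invisible(manifest)
}
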