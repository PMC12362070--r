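## End-to-end orchestration from a single configuration.

.default_confounders <- function()
  c("recipient_age", "donor_age", "recipient_bmi", "recipient_sex",
    "ethnicity", "recipient_blood_group", "cmv_status", "prd",
    "imd_quintile", "transplant_year")

#' Run configuration
#'
#' Everything one full analysis needs: an input cohort CSV (or a generator
#' configuration), the confounder set, horizons, bootstrap size, master
#' seed, analysis toggles and an output directory.  May also be read from
#' a YAML file with the same field names.
#'
#' @param input path to a cohort CSV, or `NULL` to simulate.
#' @param generator a [registry_config()] used when `input` is `NULL`.
#' @param confounders character vector of confounder columns.
#' @param horizons,tau,n_boot,seed analysis settings (horizons must lie in
#'   `(0, tau]`, `n_boot >= 2`, seed explicit).
#' @param analyses character subset of `c("base", "subgroups",
#'   "sensitivity", "mi")`.
#' @param output_dir directory for result CSVs and the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = registry_config(),
                       confounders = .default_confounders(),
                       horizons = 1:7, tau = 7, n_boot = 250, seed = 1,
                       analyses = "base", output_dir = tempfile("iptwcr_")) {
  if (any(horizons <= 0) || any(horizons > tau))
    stop_iptwcr("horizons must lie in (0, tau]")
  if (n_boot < 2) stop_iptwcr("n_boot must be >= 2")
  if (is.null(seed)) stop_iptwcr("seed must be set explicitly")
  unknown <- setdiff(analyses, c("base", "subgroups", "sensitivity", "mi"))
  if (length(unknown))
    stop_iptwcr("unknown analyses: ", paste(unknown, collapse = ", "))
  structure(list(input = input, generator = generator,
                 confounders = confounders, horizons = horizons, tau = tau,
                 n_boot = n_boot, seed = as.integer(seed),
                 analyses = analyses, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; recognised keys mirror the [run_config()]
#'   arguments (generator sub-keys mirror [registry_config()]).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  gen <- do.call(registry_config, gen_args)
  run_config(input = y$input,
             generator = gen,
             confounders = y$confounders %||% .default_confounders(),
             horizons = y$horizons %||% 1:7,
             tau = y$tau %||% 7,
             n_boot = y$n_boot %||% 250,
             seed = y$seed,
             analyses = y$analyses %||% "base",
             output_dir = y$output_dir %||% tempfile("iptwcr_"))
}

#' Simulate a cohort and its ground truth to CSV
#'
#' Thin wrapper over [simulate_registry()] and [oracle_true_effects()]
#' writing the cohort and the true-contrast table as plain CSV.
#'
#' @param config a [registry_config()].
#' @param cohort_path,truth_path output CSV paths.
#' @param oracle_n Monte-Carlo size for the truth (default 2e5).
#' @param apply_missingness mask confounders per the config.
#' @return Invisibly, a list with both paths.
#' @export
simulate_command <- function(config, cohort_path, truth_path = NULL,
                             oracle_n = 2e5, apply_missingness = FALSE) {
  tab <- simulate_registry(config, apply_missingness = apply_missingness)
  write_cohort(tab, cohort_path)
  if (!is.null(truth_path)) {
    truth <- oracle_true_effects(config, oracle_n = oracle_n)
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(list(cohort = cohort_path, truth = truth_path))
}

#' Run the full analysis pipeline
#'
#' Executes, from one configuration: eligibility filters with exclusion
#' accounting, the zero-day time convention, (optionally) multiple
#' imputation, the propensity model and balance table, per-arm weighted
#' cumulative-incidence curves, causal contrasts at the horizons and
#' `tau` with bootstrap CIs and e-values, and any requested subgroup,
#' sensitivity and MI analyses.  All outputs are written as CSV to the
#' configured directory together with a manifest (input hashes, seed,
#' package version, exclusion report).  Idempotent for a fixed
#' configuration and seed.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return The manifest, invisibly (also written as `manifest.yaml`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    files <<- c(files, p)
    p
  }
  stage <- "input"
  res <- tryCatch({
    tab <- if (!is.null(config$input)) read_cohort(config$input,
                                                   registry_schema())
           else simulate_registry(config$generator)
    message("input: ", nrow(tab), " rows")

    stage <- "eligibility"
    flt <- apply_eligibility_filters(tab)
    tab <- adjust_zero_times(flt$table)
    emit(as.data.frame(flt$report), "exclusion_report.csv")
    message("eligible: ", flt$report$n_eligible, " rows")

    stage <- "base_analysis"
    confs <- intersect(config$confounders, names(tab))
    cc <- stats::complete.cases(tab[, confs, drop = FALSE])
    base_tab <- tab[cc, , drop = FALSE]
    message("complete cases: ", nrow(base_tab), " rows")
    fit <- iptw_cmprisk(Surv(time_years, event) ~ treatment, base_tab,
                        confs, horizons = config$horizons,
                        tau = config$tau, n_boot = config$n_boot,
                        seed = config$seed)
    ctr <- fit$contrasts
    ctr$analysis_id <- "base"
    emit(ctr, "contrasts.csv")
    emit(fit$balance, "balance.csv")
    emit(curves(fit), "curves.csv")
    emit(summarize_baseline(base_tab, weights = fit$weights$weights),
         "baseline_weighted.csv")
    emit(summarize_baseline(base_tab), "baseline_unweighted.csv")

    extra <- list()
    if ("subgroups" %in% config$analyses) {
      stage <- "subgroups"
      sg_defs <- list(older_donor = ~ donor_age >= 60,
                      hla_level_4 = ~ hla_mismatch_level == 4,
                      kss_or_altruistic = ~ kss_or_altruistic == 1)
      for (nm in names(sg_defs)) {
        sg <- run_subgroup_analysis(
          Surv(time_years, event) ~ treatment, base_tab, confs,
          predicate = sg_defs[[nm]], horizons = config$horizons,
          tau = config$tau, n_boot = config$n_boot, seed = config$seed)
        x <- sg$contrasts; x$analysis_id <- paste0("subgroup_", nm)
        extra[[length(extra) + 1L]] <- x
      }
    }
    if ("sensitivity" %in% config$analyses) {
      stage <- "sensitivity"
      for (v in c("exclude_covid_era", "include_hla_in_ps")) {
        sv <- run_sensitivity(Surv(time_years, event) ~ treatment,
                              base_tab, confs, variant = v,
                              horizons = config$horizons, tau = config$tau,
                              n_boot = config$n_boot, seed = config$seed)
        x <- sv$contrasts; x$analysis_id <- paste0("sensitivity_", v)
        extra[[length(extra) + 1L]] <- x
      }
    }
    if (length(extra))
      emit(do.call(rbind, extra), "contrasts_secondary.csv")

    if ("mi" %in% config$analyses) {
      stage <- "mi"
      imp <- impute_chained(tab, confs, m = 10, seed = config$seed)
      pooled <- mi_contrast(imp, Surv(time_years, event) ~ treatment,
                            confs, horizons = config$horizons,
                            tau = config$tau, n_boot = config$n_boot,
                            seed = config$seed)
      emit(data.frame(estimand = "risk_difference_5y",
                      point = pooled$point, se = pooled$se,
                      ci_low = pooled$ci_low, ci_high = pooled$ci_high,
                      m = pooled$m), "mi_pooled.csv")
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("iptwcr")),
      seed = config$seed,
      n_input = flt$report$n_input,
      n_eligible = flt$report$n_eligible,
      n_complete_case = nrow(base_tab),
      analyses = config$analyses,
      files = basename(files),
      file_md5 = as.list(tools::md5sum(files)))
    names(manifest$file_md5) <- basename(files)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    manifest
  }, error = function(e) {
    stop_iptwcr("pipeline failed at stage '", stage, "': ",
                conditionMessage(e))
  })
  invisible(res)
}

## Surv() is only needed symbolically inside package formulas; alias the
## survival package's constructor when available so user formulas work
## whether or not survival is attached.
Surv <- function(time, event) cbind(time = time, event = event)
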