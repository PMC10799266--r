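#' Analysis configuration for the end-to-end pipeline
#'
#' Mirrors the design grid of the lipid analysis: one exposure per run,
#' a binary disease outcome plus all-cause and three cause-specific
#' mortality outcomes, subgroups by sex and by recruitment age (<65 vs
#' >=65), linear MR with the sensitivity-estimator suite, and nonlinear MR
#' by doubly ranked stratification.
#'
#' @param sim An [sim_config()] for synthetic input, or `NULL` with
#'   `cohort_path` set.
#' @param cohort_path Path of a cohort written by [write_cohort()].
#' @param outcomes Character subset of
#'   `c("disease", "allcause", "cvd", "cancer", "other")`.
#' @param methods Character subset of
#'   `c("ratio", "ivw", "egger", "weighted_median", "conmix", "mvmr",
#'   "nonlinear")`.
#' @param subgroups Subset of `c("sex", "age65")`.
#' @param n_strata Strata for nonlinear MR (default 10).
#' @param rank_normalize Inverse rank-normalize the exposure in linear MR
#'   (nonlinear MR always uses the raw exposure scale).
#' @param seed Pipeline seed; fans out to per-stage substreams.
#' @param output_dir Where result tables and the manifest are written;
#'   `NULL` returns results without writing.
#' @return list of class `mr_analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(),
                            cohort_path = NULL,
                            outcomes = c("disease", "allcause", "cvd"),
                            methods = c("ratio", "ivw", "egger",
                                        "weighted_median", "conmix",
                                        "nonlinear"),
                            subgroups = c("sex"),
                            n_strata = 10L,
                            rank_normalize = TRUE,
                            seed = 1L,
                            output_dir = NULL) {
  outcomes <- match.arg(outcomes,
                        c("disease", "allcause", "cvd", "cancer", "other"),
                        several.ok = TRUE)
  methods <- match.arg(methods,
                       c("ratio", "ivw", "egger", "weighted_median",
                         "conmix", "mvmr", "nonlinear"), several.ok = TRUE)
  structure(list(sim = sim, cohort_path = cohort_path, outcomes = outcomes,
                 methods = methods, subgroups = subgroups,
                 n_strata = as.integer(n_strata),
                 rank_normalize = rank_normalize,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "mr_analysis_config")
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full MR analysis pipeline
#'
#' Simulate (or load) a cohort, build the genetic risk score from the true
#' simulation weights (standing in for external GWAS weights), run
#' instrument diagnostics, linear ratio MR per outcome and subgroup with
#' the summary-statistic sensitivity estimators, subgroup difference
#' z-tests, and nonlinear MR with fractional polynomial dose-response
#' curves. Results are returned as tidy tables and optionally written as
#' tab-delimited text with a YAML run manifest (seed, config hash,
#' package version) sufficient to reproduce the run.
#'
#' @param config An [analysis_config()].
#' @return list of class `mr_results`: `diagnostics`, `linear` (tidy
#'   estimates table), `subgroup_tests`, `strata`, `curves`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cohort <- pipeline_stage("simulate", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else {
      sim <- config$sim
      sim$seed <- stage_seed(config$seed, "simulate")
      validate_sim_config(sim)
      simulate_cohort(sim)
    }
  })
  d <- cohort$data
  n <- nrow(d)

  res <- pipeline_stage("instruments", {
    weights <- data.frame(variant_id = colnames(cohort$dosages),
                          effect_allele = cohort$variant_info$effect_allele,
                          weight = cohort$true_weights)
    score <- build_grs(cohort$dosages, weights, cohort$variant_info)
    covs_cad <- adjustment_set(d, "cad_set")
    diag <- score_strength(score, d$exposure, covs_cad)
    conf <- confounder_check(score, d[, c("sex", "age_at_recruitment")])
    list(score = score, diag = diag, conf = conf, covs_cad = covs_cad)
  })
  score <- res$score
  covs_mort <- adjustment_set(d, "mortality_set")

  covs_for <- function(outcome)
    if (outcome %in% c("disease")) res$covs_cad else covs_mort

  x_lin <- if (config$rank_normalize) inverse_rank_normalize(d$exposure)
           else d$exposure

  linear_rows <- list()
  sub_rows <- list()
  if (any(c("ratio", "ivw", "egger", "weighted_median", "conmix") %in%
          config$methods)) {
    linear_rows <- pipeline_stage("mr_linear", {
      rows <- list()
      for (oc in config$outcomes) {
        cv <- covs_for(oc)
        ax <- linear_assoc(x_lin, score, cv, adjustment = "preset")
        ay <- fit_outcome_assoc(d, oc, score, cv, adjustment = "preset")
        ests <- list()
        if ("ratio" %in% config$methods)
          ests$ratio <- ratio_estimate(ay, ax)
        if (any(c("ivw", "egger", "weighted_median", "conmix") %in%
                config$methods)) {
          ss <- compute_summary_stats(cohort, oc, cv,
                                      rank_normalize = config$rank_normalize)
          if ("ivw" %in% config$methods) ests$ivw <- mr_ivw(ss)
          if ("egger" %in% config$methods) ests$egger <- mr_egger(ss)
          if ("weighted_median" %in% config$methods)
            ests$weighted_median <-
              mr_weighted_median(ss, seed = stage_seed(config$seed, "boot"))
          if ("conmix" %in% config$methods) ests$conmix <- mr_conmix(ss)
        }
        rows[[oc]] <- tidy_estimates(ests, outcome = oc, subgroup = "all")
        # sex subgroups on the ratio method
        if ("sex" %in% config$subgroups && "ratio" %in% config$methods) {
          by_sex <- lapply(c(male = 0, female = 1), function(s) {
            idx <- d$sex == s
            cvs <- cv[idx, setdiff(colnames(cv), grep("sex", colnames(cv),
                                                      value = TRUE)),
                      drop = FALSE]
            axs <- linear_assoc(x_lin[idx], score[idx], cvs)
            ays <- fit_outcome_assoc(d[idx, ], oc, score[idx], cvs)
            ratio_estimate(ays, axs)
          })
          rows[[paste0(oc, "_sex")]] <- rbind(
            tidy_estimates(by_sex["male"], outcome = oc, subgroup = "male"),
            tidy_estimates(by_sex["female"], outcome = oc, subgroup = "female"))
          zt <- subgroup_difference_z(by_sex$male, by_sex$female)
          sub_rows[[oc]] <- data.frame(outcome = oc, comparison = "sex",
                                        z = zt$z, p = zt$p)
        }
        if ("age65" %in% config$subgroups && "ratio" %in% config$methods) {
          by_age <- lapply(c(young = TRUE, old = FALSE), function(young) {
            idx <- (d$age_at_recruitment < 65) == young
            cvs <- cv[idx, , drop = FALSE]
            axs <- linear_assoc(x_lin[idx], score[idx], cvs)
            ays <- fit_outcome_assoc(d[idx, ], oc, score[idx], cvs)
            ratio_estimate(ays, axs)
          })
          rows[[paste0(oc, "_age")]] <- rbind(
            tidy_estimates(by_age["young"], outcome = oc, subgroup = "age<65"),
            tidy_estimates(by_age["old"], outcome = oc, subgroup = "age>=65"))
        }
      }
      rows
    })
  }

  strata_tabs <- list(); curve_tabs <- list()
  if ("nonlinear" %in% config$methods) {
    nl <- pipeline_stage("mr_nonlinear", {
      st_list <- list(); cv_list <- list()
      assign <- doubly_ranked_strata(score, d$exposure, config$n_strata)
      for (oc in config$outcomes) {
        st <- stratum_lace(score, d$exposure, assign, d, oc, covs_for(oc))
        fit <- fp_meta_regress(st)
        st_list[[oc]] <- cbind(outcome = oc, as.data.frame(st),
                               p_trend = fit$p_trend,
                               p_fp_nonlinearity = fit$p_fp_nonlinearity)
        cv_list[[oc]] <- cbind(outcome = oc, fit$curve)
      }
      list(st = st_list, cv = cv_list)
    })
    strata_tabs <- nl$st; curve_tabs <- nl$cv
  }

  results <- list(
    diagnostics = list(score_r2 = res$diag$r2, f_stat = res$diag$f_stat,
                       n = n, confounder_assocs = res$conf),
    linear = if (length(linear_rows)) do.call(rbind, c(linear_rows,
                                                       make.row.names = FALSE)),
    subgroup_tests = if (length(sub_rows)) do.call(rbind, sub_rows),
    strata = if (length(strata_tabs)) do.call(rbind, c(strata_tabs,
                                                       make.row.names = FALSE)),
    curves = if (length(curve_tabs)) do.call(rbind, c(curve_tabs,
                                                      make.row.names = FALSE)),
    manifest = list(package_version = as.character(utils::packageVersion("mrdose")),
                    seed = config$seed,
                    n_individuals = n,
                    outcomes = config$outcomes,
                    methods = config$methods,
                    n_strata = config$n_strata))
  class(results) <- "mr_results"

  if (!is.null(config$output_dir)) {
    pipeline_stage("report", {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      wt <- function(x, f) if (!is.null(x))
        utils::write.table(x, file.path(config$output_dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      wt(results$linear, "linear_mr.tsv")
      wt(results$subgroup_tests, "subgroup_tests.tsv")
      wt(results$strata, "strata.tsv")
      wt(results$curves, "curves.tsv")
      man <- results$manifest
      man$config_hash <- config_hash(config)
      results$manifest <- man
      yaml::write_yaml(man, file.path(config$output_dir, "manifest.yaml"))
    })
  }
  results
}

## Stable hash of the analysis configuration (for the run manifest).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "output_dir")], file = tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.mr_results <- function(x, ...) {
  cat("MR pipeline results\n")
  cat(sprintf("  n = %d; score R^2 = %.3f (F = %.0f)\n",
              x$diagnostics$n, x$diagnostics$score_r2, x$diagnostics$f_stat))
  if (!is.null(x$linear)) {
    cat("  linear MR estimates:\n")
    print(utils::head(x$linear[, c("method", "outcome", "subgroup", "theta",
                                   "se", "ci_low", "ci_high", "p")], 12),
          digits = 3)
  }
  if (!is.null(x$subgroup_tests)) {
    cat("  subgroup difference tests:\n")
    print(x$subgroup_tests, digits = 3)
  }
  if (!is.null(x$strata))
    cat(sprintf("  nonlinear MR: %d strata per outcome; curves on %d grid points\n",
                max(x$strata$k), sum(x$curves$outcome == x$curves$outcome[1])))
  invisible(x)
}
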