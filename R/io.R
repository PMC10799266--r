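#' Read a GWAS-format variant weight file
#'
#' Expects the de-facto summary-statistics layout: tab- or
#' comma-delimited text with header columns `variant_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `p` (extra columns pass through).
#' Rows with missing `beta` are dropped with a message; duplicate variant
#' ids are an error.
#'
#' @param path File path.
#' @return data.frame with a `weight` column aliasing `beta`.
#' @export
read_weights <- function(path) {
  df <- utils::read.delim(path, sep = guess_sep(path), stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column(s): %s",
                          paste(miss, collapse = ", "))
  drop <- is.na(df$beta)
  if (any(drop)) {
    message(sprintf("%d row(s) with missing beta dropped", sum(drop)))
    df <- df[!drop, ]
  }
  if (nrow(df) == 0L) stopf("no variants")
  if (anyDuplicated(df$variant_id))
    stopf("duplicate variant ids: %s",
          paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "))
  df$weight <- df$beta
  df
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stopf("no variants")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read and harmonize a per-variant summary-statistics file
#'
#' Reads exposure and outcome associations (columns `variant_id`,
#' `effect_allele`, `other_allele`, `beta_gx`, `se_gx`, `beta_gy`,
#' `se_gy`). If a reference allele table is given, rows recorded on the
#' opposite allele have both betas flipped in sign (harmonization); alleles
#' matching neither orientation are an error. Rows with missing betas are
#' dropped with a message.
#'
#' @param path File path.
#' @param reference_alleles Optional data.frame (`variant_id`,
#'   `effect_allele`, `other_allele`) fixing the target orientation.
#' @param scale Outcome scale tag to record.
#' @return An [summary_stats()] table.
#' @export
read_summary_stats <- function(path, reference_alleles = NULL,
                               scale = "identity") {
  df <- utils::read.delim(path, sep = guess_sep(path), stringsAsFactors = FALSE)
  need <- c("variant_id", "beta_gx", "se_gx", "beta_gy", "se_gy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$variant_id))
    stopf("duplicate variant ids: %s",
          paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "))
  drop <- is.na(df$beta_gx) | is.na(df$beta_gy)
  if (any(drop)) {
    message(sprintf("%d row(s) with missing beta dropped", sum(drop)))
    df <- df[!drop, ]
  }
  if (nrow(df) == 0L) stopf("no variants")
  if (!is.null(reference_alleles) && "effect_allele" %in% names(df)) {
    ref <- reference_alleles[match(df$variant_id,
                                   reference_alleles$variant_id), ]
    same <- df$effect_allele == ref$effect_allele
    flipped <- df$effect_allele == ref$other_allele
    if (any(!same & !flipped, na.rm = TRUE))
      stopf("allele mismatch for: %s",
            paste(df$variant_id[!same & !flipped], collapse = ", "))
    if (any(flipped)) {
      message(sprintf("%d row(s) harmonized by allele flip", sum(flipped)))
      df$beta_gx[flipped] <- -df$beta_gx[flipped]
      df$beta_gy[flipped] <- -df$beta_gy[flipped]
    }
  }
  summary_stats(df$variant_id, df$beta_gx, df$se_gx, df$beta_gy, df$se_gy,
                scale = scale)
}

#' Write a simulated cohort to delimited text with a config sidecar
#'
#' One row per individual; dosage columns are prefixed `g_`. The
#' generating configuration (including the seed) goes to a YAML sidecar
#' `<path>.config.yaml`, so a written cohort is fully reproducible.
#'
#' @param cohort An `mr_cohort`.
#' @param path Output path for the tab-delimited table.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dos <- as.data.frame(cohort$dosages)
  names(dos) <- paste0("g_", names(dos))
  tab <- cbind(cohort$data, dos)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$causal_curve <- unclass(cfg$causal_curve)
  side <- list(config = unclass(cfg),
               variant_info = cohort$variant_info,
               true_weights = cohort$true_weights)
  yaml::write_yaml(side, paste0(path, ".config.yaml"), precision = 15)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Path of the table; the sidecar `<path>.config.yaml` must sit
#'   beside it.
#' @return An `mr_cohort`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  gcols <- grep("^g_", names(tab))
  dos <- as.matrix(tab[, gcols, drop = FALSE])
  colnames(dos) <- sub("^g_", "", colnames(dos))
  dat <- tab[, -gcols, drop = FALSE]
  dat$event_cause <- factor(dat$event_cause,
                            levels = c("none", "cvd", "cancer", "other"))
  side <- yaml::read_yaml(paste0(path, ".config.yaml"))
  cfg <- side$config
  cfg$causal_curve <- structure(cfg$causal_curve, class = "mr_curve")
  cfg$maf_range <- as.numeric(cfg$maf_range)
  cfg$recruitment_age_range <- as.numeric(cfg$recruitment_age_range)
  cfg$cause_effect_scale <- unlist(cfg$cause_effect_scale)
  class(cfg) <- "mr_sim_config"
  variant_info <- data.frame(variant_id = unlist(side$variant_info$variant_id),
                             effect_allele = unlist(side$variant_info$effect_allele),
                             other_allele = unlist(side$variant_info$other_allele),
                             maf = unlist(side$variant_info$maf),
                             stringsAsFactors = FALSE)
  attr(dos, "variant_info") <- variant_info
  structure(list(data = dat, dosages = dos, variant_info = variant_info,
                 true_weights = unlist(side$true_weights), config = cfg),
            class = "mr_cohort")
}

#' Tidy one or more MR estimates into a results table
#'
#' @param ... Named `mr_estimate` objects, or a single named list of them.
#' @param outcome,subgroup Labels recorded in the table.
#' @return data.frame: method, outcome, subgroup, theta, se, ci_low,
#'   ci_high, p, scale, extras (key=value string).
#' @export
tidy_estimates <- function(..., outcome = NA_character_,
                           subgroup = NA_character_) {
  ests <- list(...)
  if (length(ests) == 1L && !inherits(ests[[1]], "mr_estimate"))
    ests <- ests[[1]]
  rows <- lapply(ests, function(e) {
    keep <- vapply(e$extras, function(v)
      is.numeric(v) && length(v) == 1L, logical(1))
    extras <- if (any(keep))
      paste(names(e$extras)[keep], signif(unlist(e$extras[keep]), 6),
            sep = "=", collapse = ";")
    else ""
    data.frame(method = e$method, outcome = outcome, subgroup = subgroup,
               theta = e$theta, se = e$se,
               ci_low = unname(e$ci95[1]), ci_high = unname(e$ci95[2]),
               p = e$p, scale = e$scale, extras = extras,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
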