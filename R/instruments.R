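#' Build a weighted genetic risk score
#'
#' Multiplies the dosage of each variant's exposure-increasing allele by its
#' per-allele weight and sums across variants. Where a weight is recorded on
#' the opposite allele to the dosage matrix, the dosage is flipped to
#' `2 - d` before weighting.
#'
#' @param dosages Numeric matrix, columns named by variant id, counting the
#'   allele in `variant_info$effect_allele`.
#' @param weights data.frame with columns `variant_id`, `effect_allele`,
#'   `weight` (and optionally `other_allele`).
#' @param variant_info data.frame with `variant_id`, `effect_allele`,
#'   `other_allele` describing the dosage orientation; defaults to the
#'   `variant_info` attribute of `dosages`.
#' @return Numeric per-individual score vector.
#' @export
build_grs <- function(dosages, weights, variant_info = NULL) {
  variant_info <- variant_info %||% attr(dosages, "variant_info")
  if (is.null(variant_info)) stopf("variant_info required to orient alleles")
  missing <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing))
    stopf("variants missing from dosage matrix: %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(weights$variant_id))
    stopf("duplicate variant ids in weight set")
  info <- variant_info[match(weights$variant_id, variant_info$variant_id), ]
  score <- numeric(nrow(dosages))
  for (j in seq_len(nrow(weights))) {
    d <- dosages[, weights$variant_id[j]]
    ea <- weights$effect_allele[j]
    if (ea == info$effect_allele[j]) {
      # orientation matches
    } else if (ea == info$other_allele[j]) {
      d <- 2 - d
    } else {
      stopf("allele mismatch for %s: weight effect allele '%s' is neither '%s' nor '%s'",
            weights$variant_id[j], ea, info$effect_allele[j], info$other_allele[j])
    }
    score <- score + weights$weight[j] * d
  }
  score
}

#' Instrument-strength diagnostics for a genetic risk score
#'
#' Computes the proportion of exposure variance explained by the score
#' after covariate adjustment (incremental R^2: the relative residual
#' sum-of-squares reduction when the score enters a covariate-adjusted
#' linear model; equal to the plain R^2 when no covariates are supplied,
#' with marginal R^2 available as an option) and the univariate-form F
#' statistic `(n - 2) R^2 / (1 - R^2)`. F below 10 is flagged as a weak
#' instrument by the usual rule of thumb.
#'
#' @param score Per-individual score.
#' @param exposure Exposure vector.
#' @param covariates Optional numeric matrix/data.frame of adjustment
#'   covariates.
#' @param mode `"incremental"` (default) or `"marginal"` R^2.
#' @return `list(r2, f_stat, n, weak)` of class `mr_score_diag`.
#' @export
score_strength <- function(score, exposure, covariates = NULL,
                           mode = c("incremental", "marginal")) {
  mode <- match.arg(mode)
  if (stats::var(score) == 0) stopf("degenerate instrument")
  n <- length(score)
  if (n < 3L) stopf("need at least 3 observations")
  if (is.null(covariates) || mode == "marginal") {
    r2 <- stats::cor(score, exposure)^2
  } else {
    cv <- as.matrix(covariates)
    rss0 <- sum(stats::lm.fit(cbind(1, cv), exposure)$residuals^2)
    rss1 <- sum(stats::lm.fit(cbind(1, cv, score), exposure)$residuals^2)
    r2 <- (rss0 - rss1) / rss0
  }
  f <- (n - 2) * r2 / (1 - r2)
  structure(list(r2 = r2, f_stat = f, n = n, weak = f < 10),
            class = "mr_score_diag")
}

#' @export
print.mr_score_diag <- function(x, ...) {
  cat(sprintf("Score explains %.2f%% of exposure variance (n = %d); F = %.1f%s\n",
              100 * x$r2, x$n, x$f_stat,
              if (x$weak) " [weak instrument: F < 10]" else ""))
  invisible(x)
}

#' Greedy LD pruning of candidate instruments
#'
#' Sorts candidates by ascending association p-value and keeps a variant iff
#' its pairwise r-squared with every already-kept variant is below the
#' threshold. Ties in p-values are broken by variant id (lexicographic) so
#' the kept set is deterministic.
#'
#' @param variants data.frame with `variant_id` and `p`.
#' @param r2_matrix Square symmetric matrix of pairwise r^2, rows/columns
#'   aligned to (or named by) `variants$variant_id`.
#' @param r2_threshold Keep threshold; the default mirrors strict
#'   independence pruning (r^2 < 0.001).
#' @return Character vector of kept variant ids (in p-value order).
#' @export
prune_variants <- function(variants, r2_matrix, r2_threshold = 0.001) {
  m <- as.matrix(r2_matrix)
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stopf("r2 matrix must be square and symmetric")
  if (nrow(m) != nrow(variants))
    stopf("r2 matrix does not match the candidate list")
  if (!is.null(rownames(m)))
    m <- m[variants$variant_id, variants$variant_id]
  ord <- order(variants$p, variants$variant_id)
  kept <- integer(0)
  for (i in ord) {
    if (all(m[i, kept] < r2_threshold)) kept <- c(kept, i)
  }
  variants$variant_id[kept]
}

#' Screen a genetic risk score against possible confounders
#'
#' Regresses each candidate confounder on the standardized score (logistic
#' regression for binary covariates, linear otherwise) and flags
#' associations at p < .01, the usual inclusion rule for
#' confounder-adjusted sensitivity analyses.
#'
#' @param score Per-individual score; standardized internally.
#' @param covariates data.frame of candidate confounders.
#' @param p_flag Flagging threshold (default .01).
#' @return data.frame: covariate, estimate, se, p, flagged; constant
#'   covariates are skipped with a warning.
#' @export
confounder_check <- function(score, covariates, p_flag = 0.01) {
  z <- as.numeric(scale(score))
  out <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      warnf("covariate '%s' is constant; skipped", nm)
      return(NULL)
    }
    binary <- all(v %in% c(0, 1, NA))
    a <- if (binary) logistic_assoc(v, z) else linear_assoc(v, z)
    data.frame(covariate = nm, estimate = a$beta, se = a$se, p = a$p,
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(covariate = character(), estimate = numeric(),
                      se = numeric(), p = numeric(), flagged = logical()))
  res$flagged <- res$p < p_flag
  res
}

#' Inverse rank-normal transformation
#'
#' Maps values through their (tie-averaged) ranks to standard normal
#' quantiles using the Blom offset: rank `r` of `n` maps to
#' `qnorm((r - 3/8) / (n + 1/4))`. The result has mean ~0, SD ~1, preserves
#' rank order, and is invariant to any strictly increasing transform of the
#' input.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Transformed vector.
#' @export
inverse_rank_normalize <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  if (length(unique(values)) < 2L) stopf("no variation")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}
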