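#' Per-variant summary statistics container
#'
#' Variant-level gene-exposure and gene-outcome associations aligned to the
#' same effect allele, the input of the summary-statistic MR estimators.
#'
#' @param variant_id Character ids.
#' @param beta_gx,se_gx Gene-exposure associations and SEs.
#' @param beta_gy,se_gy Gene-outcome associations and SEs.
#' @param scale Outcome scale tag (`"logOR"`, `"logHR"`, `"identity"`).
#' @return data.frame of class `mr_sumstats`.
#' @export
summary_stats <- function(variant_id, beta_gx, se_gx, beta_gy, se_gy,
                          scale = "identity") {
  lens <- lengths(list(variant_id, beta_gx, se_gx, beta_gy, se_gy))
  if (length(unique(lens)) != 1L)
    stopf("all summary-stat vectors must share one length")
  if (any(se_gx <= 0) || any(se_gy <= 0)) stopf("standard errors must be positive")
  structure(data.frame(variant_id = as.character(variant_id),
                       beta_gx = beta_gx, se_gx = se_gx,
                       beta_gy = beta_gy, se_gy = se_gy,
                       stringsAsFactors = FALSE),
            scale = scale, class = c("mr_sumstats", "data.frame"))
}

mr_estimate <- function(theta, se, scale, method, n = NA_integer_,
                        extras = list(), ci95 = NULL) {
  ci <- ci95 %||% (theta + c(-1, 1) * 1.96 * se)
  structure(list(theta = theta, se = se,
                 ci95 = c(low = ci[1], high = ci[2]),
                 p = normal_p(theta, se),
                 scale = scale, method = method, n = n, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s, %s scale]: theta = %.4g (95%% CI %.4g to %.4g), se = %.4g, p = %.3g\n",
              x$method, x$scale, x$theta, x$ci95[1], x$ci95[2], x$se, x$p))
  if (x$method == "egger")
    cat(sprintf("  Egger intercept %.4g (se %.4g, p = %.3g)\n",
                x$extras$egger_intercept, x$extras$egger_intercept_se,
                x$extras$egger_intercept_p))
  invisible(x)
}

#' Ratio-method MR estimate from two associations
#'
#' Divides the score-outcome association by the score-exposure association;
#' the standard error is the first-order delta method `se_gy / |beta_gx|`,
#' adequate when instrument strength is high (F well above 10).
#'
#' @param assoc_gy Gene-outcome `mr_assoc` (or `list(beta=, se=)`).
#' @param assoc_gx Gene-exposure `mr_assoc`.
#' @return An `mr_estimate` (method `"ratio"`), on the outcome scale per
#'   exposure unit.
#' @export
ratio_estimate <- function(assoc_gy, assoc_gx) {
  if (assoc_gx$beta == 0) stopf("weak/null instrument: gene-exposure beta is zero")
  theta <- assoc_gy$beta / assoc_gx$beta
  se <- assoc_gy$se / abs(assoc_gx$beta)
  mr_estimate(theta, se, assoc_gy$scale %||% "identity", "ratio",
              n = assoc_gy$n %||% NA_integer_)
}

ratio_vectors <- function(stats) {
  keep <- stats$beta_gx != 0
  if (!all(keep)) {
    warnf("%d variant(s) with zero gene-exposure beta dropped", sum(!keep))
    stats <- stats[keep, ]
  }
  if (nrow(stats) == 0L) stopf("no usable variants")
  list(theta = stats$beta_gy / stats$beta_gx,
       se = stats$se_gy / abs(stats$beta_gx),
       stats = stats)
}

#' Inverse-variance weighted MR estimate
#'
#' Zero-intercept weighted regression of the gene-outcome on the
#' gene-exposure associations with weights `1/se_gy^2`; algebraically the
#' precision-weighted mean of per-variant ratio estimates. Heterogeneity is
#' absorbed by multiplicative random effects: the fixed-effect SE is scaled
#' by `sqrt(Q/(J-1))` whenever Cochran's Q exceeds its expectation.
#'
#' @param stats An [summary_stats()] table (>= 2 variants).
#' @return An `mr_estimate` (method `"ivw"`) with Q and the scaling factor
#'   in `extras`.
#' @export
mr_ivw <- function(stats) {
  if (nrow(stats) < 2L)
    stopf("IVW needs at least 2 variants; use ratio_estimate() for one")
  w <- 1 / stats$se_gy^2
  theta <- sum(w * stats$beta_gx * stats$beta_gy) / sum(w * stats$beta_gx^2)
  se_fixed <- sqrt(1 / sum(w * stats$beta_gx^2))
  Q <- sum(w * (stats$beta_gy - theta * stats$beta_gx)^2)
  J <- nrow(stats)
  scaling <- max(1, sqrt(Q / (J - 1)))
  mr_estimate(theta, se_fixed * scaling, attr(stats, "scale") %||% "identity",
              "ivw", n = J,
              extras = list(Q = Q, df = J - 1, se_scaling = scaling,
                            se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted regression of gene-outcome on gene-exposure associations with a
#' free intercept (weights `1/se_gy^2`), after orienting every variant so
#' its gene-exposure association is nonnegative. A nonzero intercept
#' indicates directional pleiotropy; the slope is the pleiotropy-adjusted
#' causal estimate under the InSIDE assumption.
#'
#' @param stats An [summary_stats()] table (>= 3 variants, with spread in
#'   `beta_gx`).
#' @return An `mr_estimate` (method `"egger"`) with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` in `extras`.
#' @export
mr_egger <- function(stats) {
  if (nrow(stats) < 3L) stopf("MR-Egger needs at least 3 variants")
  flip <- sign(stats$beta_gx)
  flip[flip == 0] <- 1
  bx <- stats$beta_gx * flip
  by <- stats$beta_gy * flip
  if (stats::var(bx) == 0) stopf("no instrument-strength spread")
  w <- 1 / stats$se_gy^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  coef <- solve(XtWX, crossprod(X, w * by))
  J <- nrow(stats)
  resid <- by - X %*% coef
  Q <- sum(w * resid^2)
  scaling <- max(1, sqrt(Q / (J - 2)))
  V <- chol2inv(chol(XtWX)) * scaling^2
  mr_estimate(coef[2], sqrt(V[2, 2]), attr(stats, "scale") %||% "identity",
              "egger", n = J,
              extras = list(egger_intercept = coef[1],
                            egger_intercept_se = sqrt(V[1, 1]),
                            egger_intercept_p = normal_p(coef[1], sqrt(V[1, 1])),
                            Q = Q, se_scaling = scaling))
}

## Weighted median of values x with weights w (normalized): linear
## interpolation of the weighted CDF at 0.5 using midpoint positions.
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) return(x[1])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5)$y
}

#' Weighted-median MR estimate
#'
#' The weighted median of per-variant ratio estimates with weights
#' proportional to `beta_gx^2 / se_gy^2` (inverse variance of the ratio),
#' consistent when at least half the weight lies on valid instruments. The
#' standard error comes from a seeded parametric bootstrap that redraws the
#' per-variant associations from their sampling distributions.
#'
#' @param stats An [summary_stats()] table (>= 3 usable variants; variants
#'   with zero gene-exposure beta are dropped with a warning).
#' @param n_boot Bootstrap draws for the SE (default 1000).
#' @param seed Bootstrap seed.
#' @return An `mr_estimate` (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(stats, n_boot = 1000L, seed = 1L) {
  rv <- ratio_vectors(stats)
  st <- rv$stats
  if (nrow(st) < 3L) stopf("weighted median needs at least 3 usable variants")
  w <- st$beta_gx^2 / st$se_gy^2
  theta <- weighted_median_value(rv$theta, w)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(st), st$beta_gx, st$se_gx)
      by <- stats::rnorm(nrow(st), st$beta_gy, st$se_gy)
      ok <- bx != 0
      weighted_median_value(by[ok] / bx[ok], bx[ok]^2 / st$se_gy[ok]^2)
    }, numeric(1))
  })
  mr_estimate(theta, stats::sd(boot), attr(stats, "scale") %||% "identity",
              "weighted_median", n = nrow(st),
              extras = list(n_boot = n_boot, seed = seed))
}

## Profile log-likelihood of theta under the contamination-mixture model:
## each variant is valid (ratio ~ N(theta, se_j)) or invalid
## (ratio ~ N(0, sqrt(se_j^2 + psi^2))); the profile takes the better of
## the two per variant.
conmix_loglik <- function(theta, ratio, se, psi) {
  ll_invalid <- stats::dnorm(ratio, 0, sqrt(se^2 + psi^2), log = TRUE)
  ll_valid <- vapply(theta, function(t)
    stats::dnorm(ratio, t, se, log = TRUE), numeric(length(ratio)))
  colSums(pmax(ll_valid, ll_invalid))
}

#' Contamination-mixture MR estimate
#'
#' Profile-likelihood estimator robust to invalid instruments: over a dense
#' grid of candidate causal effects, each variant's ratio estimate is
#' classified as valid (normal about the candidate effect with its own SE)
#' or invalid (normal about zero with variance inflated by `psi^2`), and
#' the causal estimate maximizes the resulting profile likelihood. The 95%
#' confidence set is the likelihood region `2*(max - loglik) < 3.84` and
#' may be disjoint; its hull is reported as `ci95` with the modes in
#' `extras`.
#'
#' @param stats An [summary_stats()] table (>= 3 usable variants).
#' @param psi Invalid-effect scale; default 1.5 times the SD of the
#'   per-variant ratio estimates.
#' @param grid_n Grid resolution (default 501 points spanning the ratio
#'   range extended by 25% each side).
#' @return An `mr_estimate` (method `"conmix"`) with `modes`,
#'   `n_valid`, `psi`, and the grid in `extras`.
#' @export
mr_conmix <- function(stats, psi = NULL, grid_n = 501L) {
  rv <- ratio_vectors(stats)
  if (length(rv$theta) < 3L) stopf("contamination mixture needs >= 3 usable variants")
  ratio <- rv$theta
  se <- rv$se
  if (grid_n < 2L) stopf("grid degenerate (width 0)")
  lo <- min(ratio); hi <- max(ratio)
  pad <- 0.25 * (hi - lo)
  if (pad == 0) pad <- max(4 * max(se), 1e-6)  # identical ratios: se-wide grid
  psi <- psi %||% (1.5 * max(stats::sd(ratio), max(se)))
  if (psi <= 0) stopf("psi must be positive")
  grid <- seq(lo - pad, hi + pad, length.out = grid_n)
  ll <- conmix_loglik(grid, ratio, se, psi)
  best <- which.max(ll)
  # refine around the likelihood region so the CI is resolved even when it
  # is narrower than the initial grid spacing
  near <- which(2 * (ll[best] - ll) < stats::qchisq(0.95, 1) + 6)
  step <- grid[2] - grid[1]
  win <- range(grid[near]) + c(-step, step)
  grid <- seq(win[1], win[2], length.out = grid_n)
  ll <- conmix_loglik(grid, ratio, se, psi)
  best <- which.max(ll)
  inside <- 2 * (ll[best] - ll) < stats::qchisq(0.95, 1)
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  modes <- cbind(low = grid[starts[runs$values]], high = grid[ends[runs$values]])
  hull <- c(min(modes[, "low"]), max(modes[, "high"]))
  theta <- grid[best]
  # SE proxy from the hull half-width (reported for completeness; the CI is
  # the likelihood region itself)
  se_proxy <- (hull[2] - hull[1]) / (2 * 1.96)
  valid <- stats::dnorm(ratio, theta, se, log = TRUE) >=
    stats::dnorm(ratio, 0, sqrt(se^2 + psi^2), log = TRUE)
  mr_estimate(theta, se_proxy, attr(stats, "scale") %||% "identity",
              "conmix", n = length(ratio), ci95 = hull,
              extras = list(modes = modes, n_modes = nrow(modes),
                            valid = valid, n_valid = sum(valid), psi = psi))
}

#' Two-sided z-test for a difference between subgroup estimates
#'
#' Compares two MR estimates on the same scale:
#' `z = (theta1 - theta2) / sqrt(se1^2 + se2^2)`, `p = 2 * pnorm(-|z|)`.
#'
#' @param est1,est2 `mr_estimate` objects (or `list(theta=, se=, scale=)`).
#' @return `list(z, p, diff, se_diff)`.
#' @export
subgroup_difference_z <- function(est1, est2) {
  if (!identical(est1$scale, est2$scale))
    stopf("estimates are on different scales (%s vs %s)", est1$scale, est2$scale)
  d <- est1$theta - est2$theta
  se <- sqrt(est1$se^2 + est2$se^2)
  z <- d / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), diff = d, se_diff = se)
}

#' Express a log-scale MR estimate as an OR/HR per exposure SD
#'
#' Rescales the causal estimate to per-SD units and exponentiates the point
#' estimate and confidence interval.
#'
#' @param est An `mr_estimate` on a log scale.
#' @param sd_units Exposure SD used for rescaling (default 1 = already per
#'   SD).
#' @return `list(estimate, ci95, measure)` with measure `"OR"` or `"HR"`.
#' @export
exponentiate_estimate <- function(est, sd_units = 1) {
  if (!est$scale %in% c("logOR", "logHR"))
    stopf("exponentiation requires a logOR or logHR scale estimate")
  theta <- est$theta * sd_units
  se <- est$se * sd_units
  list(estimate = exp(theta),
       ci95 = exp(theta + c(-1.96, 1.96) * se),
       measure = if (est$scale == "logOR") "OR" else "HR")
}

#' Recover a log-scale standard error from a printed ratio CI
#'
#' Utility for subgroup tests on published odds/hazard ratios:
#' `se = (log(hi) - log(lo)) / (2 * 1.96)`.
#'
#' @param point,lo,hi Ratio point estimate and 95% CI limits.
#' @param scale `"logOR"` or `"logHR"`.
#' @return An `mr_estimate` on the log scale.
#' @export
estimate_from_ci <- function(point, lo, hi, scale = "logOR") {
  mr_estimate(log(point), (log(hi) - log(lo)) / (2 * 1.96), scale,
              method = "ratio")
}

#' Per-variant summary statistics from an individual-level cohort
#'
#' Regresses the exposure and one outcome on each variant's dosage in turn
#' (with the given adjustment covariates), producing the summary-statistic
#' table consumed by the sensitivity estimators.
#'
#' @param cohort An `mr_cohort`.
#' @param outcome `"disease"`, `"allcause"`, `"cvd"`, `"cancer"`, `"other"`,
#'   or the name of a numeric column of `cohort$data` for a linear fit.
#' @param covariates Covariate matrix (or `NULL`).
#' @param rank_normalize Apply [inverse_rank_normalize()] to the exposure
#'   before the gene-exposure regressions.
#' @return An [summary_stats()] table.
#' @export
compute_summary_stats <- function(cohort, outcome = "disease",
                                  covariates = NULL, rank_normalize = FALSE) {
  d <- cohort$data
  x <- d$exposure
  if (rank_normalize) x <- inverse_rank_normalize(x)
  m <- ncol(cohort$dosages)
  bx <- sx <- by <- sy <- numeric(m)
  scale <- "identity"
  for (j in seq_len(m)) {
    g <- cohort$dosages[, j]
    ax <- linear_assoc(x, g, covariates)
    ay <- fit_outcome_assoc(d, outcome, g, covariates)
    bx[j] <- ax$beta; sx[j] <- ax$se
    by[j] <- ay$beta; sy[j] <- ay$se
    scale <- ay$scale
  }
  summary_stats(colnames(cohort$dosages), bx, sx, by, sy, scale = scale)
}

## Dispatch an outcome association by outcome spec name.
fit_outcome_assoc <- function(d, outcome, score, covariates,
                              adjustment = "none") {
  if (outcome == "disease")
    logistic_assoc(d$disease, score, covariates, adjustment)
  else if (outcome == "allcause")
    cox_assoc(d$entry_age, d$exit_age, as.integer(d$event_cause != "none"),
              score, covariates, adjustment)
  else if (outcome %in% c("cvd", "cancer", "other"))
    cause_specific_cox(d$entry_age, d$exit_age, d$event_cause, outcome,
                       score, covariates, adjustment)
  else if (outcome %in% names(d))
    linear_assoc(d[[outcome]], score, covariates, adjustment)
  else stopf("unknown outcome spec '%s'", outcome)
}
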