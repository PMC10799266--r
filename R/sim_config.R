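#' Specify the true causal dose-response curve of a simulation
#'
#' The curve is the log-odds (disease) or log-hazard (mortality) shift per
#' unit of exposure, the estimand of the nonlinear analysis. Four shapes are
#' supported:
#' \describe{
#'   \item{linear}{`f(x) = b1 * x`, coefficients `b1`.}
#'   \item{quadratic}{`f(x) = b1 * x + b2 * x^2`, coefficients `(b1, b2)`.}
#'   \item{threshold}{`f(x) = b1 * max(x - c, 0)`, coefficients `(b1, c)`:
#'     flat below the threshold `c`, linear above.}
#'   \item{jshape}{`f(x) = b1 * (x - c)^2`, coefficients `(b1, c)`: a
#'     J/U-shape with nadir at `c`.}
#' }
#'
#' @param shape One of `"linear"`, `"quadratic"`, `"threshold"`, `"jshape"`.
#' @param coefficients Numeric coefficient vector for the chosen shape.
#' @return An object of class `mr_curve`.
#' @seealso [true_curve()] to evaluate the curve against a median reference.
#' @export
causal_curve <- function(shape = c("linear", "quadratic", "threshold", "jshape"),
                         coefficients = 1) {
  shape <- match.arg(shape)
  coefficients <- as.numeric(coefficients)
  need <- switch(shape, linear = 1L, quadratic = 2L, threshold = 2L, jshape = 2L)
  if (length(coefficients) != need)
    stopf("shape '%s' needs %d coefficient(s), got %d", shape, need,
          length(coefficients))
  if (!all(is.finite(coefficients))) stopf("curve coefficients must be finite")
  structure(list(shape = shape, coefficients = coefficients),
            class = "mr_curve")
}

## Evaluate the raw (uncentered) curve.
eval_curve <- function(curve, x) {
  b <- curve$coefficients
  switch(curve$shape,
         linear    = b[1] * x,
         quadratic = b[1] * x + b[2] * x^2,
         threshold = b[1] * pmax(x - b[2], 0),
         jshape    = b[1] * (x - b[2])^2)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a large mid-life biobank
#' cohort of lipid exposures: a few hundred independent biallelic variants
#' with small per-allele effects jointly explaining about 12% of exposure
#' variance, an unmeasured confounder acting on exposure and outcomes,
#' disease prevalence near 7%, about 7% deaths split across three competing
#' causes, and recruitment ages 40-69 years. The exposure scale mimics
#' apolipoprotein B in g/L (mean 1.0, SD 0.25).
#'
#' @param n_individuals Cohort size before any selection.
#' @param n_variants Number of independent biallelic instruments.
#' @param maf_range Interval within (0, 0.5] from which per-variant minor
#'   allele frequencies are drawn uniformly.
#' @param variant_effect_sd Scale of raw per-allele effect draws; the draws
#'   are rescaled to hit `target_r2`, so only relative magnitudes matter.
#' @param target_r2 Fraction of exposure variance explained by the true
#'   genetic score, in (0, 1).
#' @param exposure_mean Location of the exposure (exposure units); `NULL`
#'   leaves the exposure as the raw weighted dosage sum plus noise.
#' @param confounder_effect_exposure Effect of the standard-normal hidden
#'   confounder on the exposure (exposure units per confounder SD).
#' @param confounder_effect_outcome Effect of the confounder on every
#'   outcome's log-odds / log-hazard.
#' @param residual_sd SD of the exposure's independent residual noise.
#' @param causal_curve An [causal_curve()] object: the true effect of
#'   exposure on outcome log-odds / log-hazard, per exposure unit.
#' @param disease_intercept Log-odds of disease at the reference exposure
#'   for a confounder-average individual; controls prevalence.
#' @param recruitment_age_range Interval of recruitment ages in years.
#' @param baseline_hazard Named list with entries `cvd`, `cancer`, `other`,
#'   each `list(shape=, rate=)` of a Weibull cause-specific baseline hazard
#'   on the age timescale (shape 1 gives a constant hazard).
#' @param cause_effect_scale Named multiplier of the causal curve per cause
#'   of death; the default puts the full effect on CVD death, none on
#'   cancer, and a quarter on other causes.
#' @param admin_censor_age Administrative censoring age in years.
#' @param selection Optional `list(intercept=, slope=)` pre-recruitment
#'   survival model: inclusion probability
#'   `plogis(intercept - slope * (exposure - centre))`, decreasing in the
#'   exposure when `slope > 0`. `NULL` disables selection.
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return An object of class `mr_sim_config`.
#' @export
sim_config <- function(n_individuals = 10000L,
                       n_variants = 150L,
                       maf_range = c(0.05, 0.45),
                       variant_effect_sd = 1,
                       target_r2 = 0.12,
                       exposure_mean = 1.0,
                       confounder_effect_exposure = 0.08,
                       confounder_effect_outcome = 0.3,
                       residual_sd = 0.22,
                       causal_curve = mrdose::causal_curve("linear", 2),
                       disease_intercept = stats::qlogis(0.07),
                       recruitment_age_range = c(40, 69),
                       baseline_hazard = list(
                         cvd    = list(shape = 1, rate = 0.0009),
                         cancer = list(shape = 1, rate = 0.0009),
                         other  = list(shape = 1, rate = 0.0009)),
                       cause_effect_scale = c(cvd = 1, cancer = 0, other = 0.25),
                       admin_censor_age = 82,
                       selection = NULL,
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              variant_effect_sd = variant_effect_sd,
              target_r2 = target_r2,
              exposure_mean = exposure_mean,
              confounder_effect_exposure = confounder_effect_exposure,
              confounder_effect_outcome = confounder_effect_outcome,
              residual_sd = residual_sd,
              causal_curve = causal_curve,
              disease_intercept = disease_intercept,
              recruitment_age_range = as.numeric(recruitment_age_range),
              baseline_hazard = baseline_hazard,
              cause_effect_scale = cause_effect_scale,
              admin_censor_age = admin_censor_age,
              selection = selection,
              seed = as.integer(seed))
  class(cfg) <- "mr_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1L) stopf("n_individuals must be positive")
  if (cfg$n_variants < 0L) stopf("n_variants must be nonnegative")
  mr <- cfg$maf_range
  if (length(mr) != 2L || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    stopf("maf_range must be an interval within (0, 0.5]")
  if (!is_scalar_num(cfg$target_r2) || cfg$target_r2 <= 0 || cfg$target_r2 >= 1)
    stopf("target_r2 must lie in (0, 1)")
  if (!inherits(cfg$causal_curve, "mr_curve"))
    stopf("causal_curve must be built with causal_curve()")
  causes <- c("cvd", "cancer", "other")
  if (!all(causes %in% names(cfg$baseline_hazard)))
    stopf("baseline_hazard must name all of: %s", paste(causes, collapse = ", "))
  for (cs in causes) {
    h <- cfg$baseline_hazard[[cs]]
    if (h$rate < 0 || h$shape <= 0)
      stopf("baseline hazard for '%s' needs rate >= 0 and shape > 0", cs)
  }
  ages <- cfg$recruitment_age_range
  if (ages[1] >= ages[2] || cfg$admin_censor_age <= ages[2])
    stopf("admin_censor_age must exceed the recruitment age range")
  if (!is.null(cfg$selection) &&
      !all(c("intercept", "slope") %in% names(cfg$selection)))
    stopf("selection must be NULL or list(intercept=, slope=)")
  invisible(cfg)
}

#' @export
print.mr_sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d, variants: %d, MAF in [%.2f, %.2f]\n",
              x$n_individuals, x$n_variants, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  target score R^2: %.3f, causal curve: %s(%s)\n",
              x$target_r2, x$causal_curve$shape,
              paste(signif(x$causal_curve$coefficients, 3), collapse = ", ")))
  cat(sprintf("  recruitment ages %g-%g, administrative censoring at %g\n",
              x$recruitment_age_range[1], x$recruitment_age_range[2],
              x$admin_censor_age))
  cat(sprintf("  selection: %s, seed: %d\n",
              if (is.null(x$selection)) "off" else "on", x$seed))
  invisible(x)
}
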