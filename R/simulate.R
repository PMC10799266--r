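#' Simulate independent biallelic genotype dosages
#'
#' Each variant's minor allele frequency is drawn uniformly from
#' `config$maf_range`; dosages are two independent allele draws, so column
#' `j` is Binomial(2, MAF_j). Columns are mutually independent (the
#' instruments are assumed LD-pruned to near-independence).
#'
#' @param config An [sim_config()] object.
#' @return A numeric `n x m` matrix with values in `{0, 1, 2}`, column names
#'   `v0001...`, and attributes `maf` (the drawn frequencies) and
#'   `variant_info` (a data.frame of variant_id, effect_allele, other_allele,
#'   maf; the dosage counts the effect allele).
#' @export
simulate_genotypes <- function(config) {
  if (config$n_variants == 0L) stopf("no instruments")
  n <- config$n_individuals
  m <- config$n_variants
  with_local_seed(stage_seed(config$seed, "simulate"), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    dos <- vapply(maf, function(p) stats::rbinom(n, 2L, p), numeric(n))
  })
  ids <- sprintf("v%04d", seq_len(m))
  colnames(dos) <- ids
  variant_info <- data.frame(variant_id = ids,
                             effect_allele = "A", other_allele = "G",
                             maf = maf, stringsAsFactors = FALSE)
  attr(dos, "maf") <- maf
  attr(dos, "variant_info") <- variant_info
  dos
}

#' Simulate the exposure from genotypes, a confounder, and noise
#'
#' Per-allele effects are drawn Normal(0, `variant_effect_sd`) and rescaled
#' so the genetic score's share of exposure variance matches
#' `config$target_r2` against the empirical non-genetic variance, i.e.
#' in-sample R^2 of exposure on the true score lands on target within
#' sampling error. The confounder contributes
#' `confounder_effect_exposure * U` and an independent Normal(0,
#' `residual_sd`) residual is added. If both the confounder effect and the
#' residual SD are zero the exposure is exactly the weighted dosage sum
#' (no rescaling is possible, nor needed). When `exposure_mean` is set the
#' exposure is recentred there.
#'
#' @param dosages Matrix from [simulate_genotypes()].
#' @param config An [sim_config()] object.
#' @param confounder Standard-normal n-vector; drawn internally if `NULL`.
#' @param seed RNG seed; defaults to a substream of `config$seed`.
#' @return `list(exposure, weights, confounder, intercept)`; `weights` are
#'   the true rescaled per-allele effects for oracle use.
#' @export
simulate_exposure <- function(dosages, config, confounder = NULL, seed = NULL) {
  if (config$target_r2 >= 1) stopf("target_r2 must be below 1")
  n <- nrow(dosages)
  seed <- seed %||% (stage_seed(config$seed, "simulate") + 1L)
  res <- with_local_seed(seed, {
    u <- confounder %||% stats::rnorm(n)
    w <- stats::rnorm(ncol(dosages), 0, config$variant_effect_sd)
    g <- drop(dosages %*% w)
    gam <- config$confounder_effect_exposure
    nongen <- gam * u + stats::rnorm(n, 0, config$residual_sd)
    v_non <- stats::var(nongen)
    if (v_non > 0) {
      # scale genetic variance to target_r2/(1-target_r2) of the rest
      v_target <- config$target_r2 / (1 - config$target_r2) * v_non
      s <- sqrt(v_target / stats::var(g))
      w <- w * s
      g <- g * s
    }
    x <- g + nongen
    list(x = x, w = w, u = u)
  })
  intercept <- 0
  if (!is.null(config$exposure_mean)) {
    intercept <- config$exposure_mean - mean(res$x)
    res$x <- res$x + intercept
  }
  list(exposure = res$x, weights = res$w, confounder = res$u,
       intercept = intercept)
}

#' Simulate disease status and cause-specific survival
#'
#' Disease follows a logistic model whose log-odds are
#' `disease_intercept + f(x) - f(ref) + confounder_effect_outcome * U`,
#' with `f` the configured causal curve and `ref` the exposure mean (so the
#' intercept directly controls prevalence). Deaths arise from three
#' competing cause-specific Weibull hazards on the age timescale, each with
#' log-hazard shifted by `cause_effect_scale[c] * (f(x) - f(ref))` plus the
#' confounder term; event times are drawn conditionally on survival to the
#' recruitment age (delayed entry), the earliest cause wins, and follow-up
#' is administratively censored at `admin_censor_age`.
#'
#' @param exposure,confounder n-vectors from [simulate_exposure()].
#' @param covariates data.frame with at least `age_at_recruitment`.
#' @param config An [sim_config()] object.
#' @param seed RNG seed; defaults to a substream of `config$seed`.
#' @return `list(disease, entry_age, exit_age, event_cause)` with
#'   `event_cause` a factor in `none, cvd, cancer, other` (`none` =
#'   administratively censored).
#' @export
simulate_outcomes <- function(exposure, confounder, covariates, config,
                              seed = NULL) {
  n <- length(exposure)
  rates <- vapply(config$baseline_hazard, `[[`, numeric(1), "rate")
  if (all(rates == 0)) stopf("no events possible")
  ref <- config$exposure_mean %||% stats::median(exposure)
  f <- eval_curve(config$causal_curve, exposure) -
    eval_curve(config$causal_curve, ref)
  u_term <- config$confounder_effect_outcome * confounder
  seed <- seed %||% (stage_seed(config$seed, "simulate") + 2L)
  with_local_seed(seed, {
    p_dis <- stats::plogis(config$disease_intercept + f + u_term)
    disease <- stats::rbinom(n, 1L, p_dis)

    entry <- covariates$age_at_recruitment
    causes <- c("cvd", "cancer", "other")
    times <- matrix(Inf, n, 3L, dimnames = list(NULL, causes))
    for (j in seq_along(causes)) {
      h <- config$baseline_hazard[[causes[j]]]
      if (h$rate == 0) next
      lp <- config$cause_effect_scale[[causes[j]]] * f + u_term
      # Weibull cumulative hazard rate*t^shape; invert conditional on entry
      e1 <- stats::rexp(n)
      times[, j] <- (entry^h$shape + e1 / (h$rate * exp(lp)))^(1 / h$shape)
    }
    t_event <- do.call(pmin, as.data.frame(times))
    which_c <- causes[max.col(-times, ties.method = "first")]
    censored <- t_event >= config$admin_censor_age
    exit <- pmin(t_event, config$admin_censor_age)
    cause <- ifelse(censored, "none", which_c)
    # guard exit > entry strictly (ties impossible a.s., but be safe)
    exit <- pmax(exit, entry + 1e-8)
    list(disease = disease, entry_age = entry, exit_age = exit,
         event_cause = factor(cause, levels = c("none", causes)))
  })
}

#' Simulate a complete analysis-ready cohort
#'
#' Composes [simulate_genotypes()], [simulate_exposure()] and
#' [simulate_outcomes()], adds sex, recruitment age/year, and 20 principal
#' components (independent standard normals with no effect, pure adjustment
#' covariates), and optionally applies pre-recruitment selection: each
#' individual is retained with probability
#' `plogis(intercept - slope * (exposure - centre))`, emulating survivors
#' of exposure-dependent mortality reaching recruitment.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `mr_cohort`: a list with `data` (one row per
#'   individual: id, exposure, confounder, sex, age_at_recruitment,
#'   recruitment_year, pc1..pc20, disease, entry_age, exit_age,
#'   event_cause), `dosages` (n x m matrix), `variant_info`, `true_weights`,
#'   and `config`. The confounder and true weights are exposed for tests
#'   only; estimators must not use them.
#' @export
simulate_cohort <- function(config) {
  dos <- simulate_genotypes(config)
  n <- config$n_individuals
  base_seed <- stage_seed(config$seed, "simulate")
  covars <- with_local_seed(base_seed + 3L, {
    data.frame(
      sex = stats::rbinom(n, 1L, 0.5),
      age_at_recruitment = stats::runif(n, config$recruitment_age_range[1],
                                        config$recruitment_age_range[2]),
      recruitment_year = sample(2006:2010, n, replace = TRUE))
  })
  pcs <- with_local_seed(base_seed + 4L,
                         matrix(stats::rnorm(n * 20L), n, 20L))
  colnames(pcs) <- sprintf("pc%d", 1:20)

  exp_sim <- simulate_exposure(dos, config)
  out <- simulate_outcomes(exp_sim$exposure, exp_sim$confounder, covars, config)

  dat <- cbind(
    data.frame(id = sprintf("i%06d", seq_len(n)),
               exposure = exp_sim$exposure,
               confounder = exp_sim$confounder),
    covars, as.data.frame(pcs),
    data.frame(disease = out$disease, entry_age = out$entry_age,
               exit_age = out$exit_age, event_cause = out$event_cause))

  keep <- rep(TRUE, n)
  if (!is.null(config$selection)) {
    ctr <- config$exposure_mean %||% stats::median(exp_sim$exposure)
    p_in <- stats::plogis(config$selection$intercept -
                            config$selection$slope * (exp_sim$exposure - ctr))
    keep <- with_local_seed(base_seed + 5L,
                            stats::runif(n) < p_in)
  }

  dos_keep <- dos[keep, , drop = FALSE]
  attr(dos_keep, "variant_info") <- attr(dos, "variant_info")
  structure(list(data = dat[keep, , drop = FALSE],
                 dosages = dos_keep,
                 variant_info = attr(dos, "variant_info"),
                 true_weights = exp_sim$weights,
                 config = config),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("Synthetic MR cohort: %d individuals, %d variants\n",
              nrow(d), ncol(x$dosages)))
  cat(sprintf("  disease prevalence %.1f%%; deaths %.1f%% (cvd %d, cancer %d, other %d)\n",
              100 * mean(d$disease),
              100 * mean(d$event_cause != "none"),
              sum(d$event_cause == "cvd"), sum(d$event_cause == "cancer"),
              sum(d$event_cause == "other")))
  cat(sprintf("  exposure mean %.3f (SD %.3f); recruitment ages %.0f-%.0f\n",
              mean(d$exposure), stats::sd(d$exposure),
              min(d$age_at_recruitment), max(d$age_at_recruitment)))
  invisible(x)
}

#' Evaluate the true causal curve on a grid, centred at the grid median
#'
#' Oracle for dose-response recovery tests: returns the configured causal
#' curve with the grid median as reference value 0, matching the convention
#' of reporting effects relative to the median of the exposure.
#'
#' @param config An [sim_config()] object.
#' @param grid Numeric vector of exposure values.
#' @return Numeric vector `f(grid) - f(median(grid))`.
#' @export
true_curve <- function(config, grid) {
  if (length(grid) == 0L) stopf("empty grid")
  f <- eval_curve(config$causal_curve, grid)
  f - eval_curve(config$causal_curve, stats::median(grid))
}
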