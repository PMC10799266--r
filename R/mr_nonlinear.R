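#' Doubly ranked stratification
#'
#' Stratifies a population so that strata differ in exposure level but the
#' instrument remains independent of confounders within each stratum.
#' Individuals are sorted by instrument score and partitioned consecutively
#' into pre-strata of size S; within each pre-stratum individuals are
#' ranked by exposure, and the individual with exposure rank j joins final
#' stratum j. A final incomplete pre-stratum of size r < S sends its
#' members to final strata 1..r after within-pre-stratum ranking. Ties in
#' the instrument are broken by exposure then input order; exposure ties
#' within a pre-stratum by instrument order — both deterministic.
#'
#' @param score Instrument (genetic risk score) vector.
#' @param exposure Exposure vector.
#' @param S Number of final strata (default 10).
#' @return Integer vector of final-stratum labels (1..S), in input order.
#' @export
doubly_ranked_strata <- function(score, exposure, S = 10L) {
  n <- length(score)
  if (S < 2L) stopf("need at least 2 strata")
  if (n < S * S) stopf("too few individuals for doubly ranked stratification (n < S^2)")
  ord <- order(score, exposure, seq_len(n))   # instrument rank, ties broken
  pre <- ceiling(seq_len(n) / S)              # consecutive pre-strata of size S
  assign_sorted <- integer(n)
  for (b in unique(pre)) {
    idx <- which(pre == b)
    # exposure rank within pre-stratum; ties by instrument order (= position)
    r <- order(order(exposure[ord[idx]], seq_along(idx)))
    assign_sorted[idx] <- r
  }
  out <- integer(n)
  out[ord] <- assign_sorted
  out
}

#' Stratum-specific MR estimates (LACE)
#'
#' For each stratum of a doubly ranked assignment, fits the gene-exposure
#' and gene-outcome associations on the raw exposure scale (no rank-normal
#' transform, so effects stay per absolute exposure unit) and forms the
#' ratio estimate: the localized average causal effect near the stratum's
#' mean exposure. Strata without events or without exposure variation are
#' flagged and excluded downstream with a warning.
#'
#' @param score Instrument score.
#' @param exposure Exposure (raw units).
#' @param assignment Stratum labels from [doubly_ranked_strata()].
#' @param data Cohort data.frame (for outcome columns).
#' @param outcome Outcome spec as in [compute_summary_stats()].
#' @param covariates Optional covariate matrix (subset per stratum).
#' @return data.frame of class `mr_strata`: k, n_k, xbar_k, theta_k, se_k,
#'   usable; with attributes `scale` and `reference_x` (the whole-sample
#'   exposure median).
#' @export
stratum_lace <- function(score, exposure, assignment, data,
                         outcome = "disease", covariates = NULL) {
  ks <- sort(unique(assignment))
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  scale <- "identity"
  rows <- lapply(ks, function(k) {
    idx <- which(assignment == k)
    cvk <- if (is.null(cv)) NULL else cv[idx, , drop = FALSE]
    res <- tryCatch({
      ax <- linear_assoc(exposure[idx], score[idx], cvk)
      ay <- fit_outcome_assoc(data[idx, , drop = FALSE], outcome,
                              score[idx], cvk)
      est <- ratio_estimate(ay, ax)
      scale <<- est$scale
      data.frame(k = k, n_k = length(idx), xbar_k = mean(exposure[idx]),
                 theta_k = est$theta, se_k = est$se, usable = TRUE)
    }, error = function(e) {
      warnf("stratum %d excluded: %s", k, conditionMessage(e))
      data.frame(k = k, n_k = length(idx), xbar_k = mean(exposure[idx]),
                 theta_k = NA_real_, se_k = NA_real_, usable = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "scale") <- scale
  attr(out, "reference_x") <- stats::median(exposure)
  attr(out, "exposure_range") <- range(exposure)
  class(out) <- c("mr_strata", "data.frame")
  out
}

## ---- fractional polynomial machinery -------------------------------------

fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2)

## All candidate power multisets up to degree_max.
fp_candidates <- function(degree_max) {
  P <- fp_power_set()
  cands <- lapply(P, function(p) p)
  if (degree_max >= 2) {
    for (i in seq_along(P)) for (j in i:length(P))
      cands <- c(cands, list(c(P[i], P[j])))
  }
  cands
}

## Curve basis h(x): x^p (p != 0) or log(x); repeated powers use the
## log-modified second term x^p*log(x) (p = 0: log(x), log(x)^2).
fp_curve_basis <- function(x, powers) {
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 1L) return(cbind(one(powers)))
  if (powers[1] != powers[2]) return(cbind(one(powers[1]), one(powers[2])))
  p <- powers[1]
  if (p == 0) cbind(log(x), log(x)^2) else cbind(x^p, x^p * log(x))
}

## Derivative basis h'(x), matching fp_curve_basis column-for-column.
fp_deriv_basis <- function(x, powers) {
  done <- function(p) if (p == 0) 1 / x else p * x^(p - 1)
  if (length(powers) == 1L) return(cbind(done(powers)))
  if (powers[1] != powers[2]) return(cbind(done(powers[1]), done(powers[2])))
  p <- powers[1]
  if (p == 0) cbind(1 / x, 2 * log(x) / x)
  else cbind(p * x^(p - 1), x^(p - 1) * (p * log(x) + 1))
}

## Weighted (1/se^2) regression of y on basis D without intercept; returns
## coefficients, covariance, and the Gaussian log-likelihood with known se.
fp_wls <- function(D, y, se) {
  w <- 1 / se^2
  XtWX <- crossprod(D * sqrt(w))
  ok <- tryCatch({ R <- chol(XtWX); TRUE }, error = function(e) FALSE)
  if (!ok) return(NULL)
  V <- chol2inv(R)
  beta <- drop(V %*% crossprod(D, w * y))
  fitted <- drop(D %*% beta)
  ll <- sum(stats::dnorm(y, fitted, se, log = TRUE))
  list(beta = beta, vcov = V, loglik = ll, fitted = fitted)
}

#' Fractional polynomial meta-regression of stratum estimates
#'
#' Treats the stratum-specific estimates as observations of the causal
#' curve's derivative at the stratum mean exposures (the LACE
#' interpretation) and meta-regresses them, with weights `1/se_k^2`,
#' against the derivative basis of every candidate fractional polynomial
#' with powers from \{-2, -1, -0.5, 0, 0.5, 1, 2\} (0 = log; repeated
#' powers take the log-modified basis) up to `degree_max`. The
#' best-likelihood model is selected (ties toward lower degree, then
#' toward power 1), and the causal curve is recovered by analytic
#' integration of each power term, reported relative to the reference
#' exposure (sample median by default). Exposures are shifted by
#' `1 - min(xbar)` before applying powers when any `xbar <= 0`; the shift
#' is inverted on output.
#'
#' @param strata An `mr_strata` table (or data.frame with xbar_k, theta_k,
#'   se_k); unusable strata are dropped with a warning.
#' @param degree_max 1 or 2.
#' @param reference_x Reference exposure (defaults to the `reference_x`
#'   attribute of `strata`, i.e. the sample median).
#' @param grid Exposure grid for the exported curve; defaults to 101 points
#'   over the stratum-mean range.
#' @return Object of class `mr_fpfit`: powers, degree, coefficients,
#'   covariance, shift, reference_x, loglik, `p_trend`,
#'   `p_fp_nonlinearity`, and `curve` (x, effect, ci_low, ci_high).
#' @export
fp_meta_regress <- function(strata, degree_max = 2L, reference_x = NULL,
                            grid = NULL) {
  st <- strata[!is.na(strata$theta_k) & !is.na(strata$se_k), , drop = FALSE]
  if (nrow(st) < nrow(strata))
    warnf("%d stratum/strata without usable estimates excluded",
          nrow(strata) - nrow(st))
  if (nrow(st) < 3L) stopf("need at least 3 usable strata")
  if (length(unique(st$xbar_k)) == 1L) stopf("no exposure spread")
  if (!degree_max %in% c(1L, 2L)) stopf("degree_max must be 1 or 2")

  shift <- if (min(st$xbar_k) <= 0) 1 - min(st$xbar_k) else 0
  xs <- st$xbar_k + shift
  reference_x <- reference_x %||% attr(strata, "reference_x") %||%
    stats::median(st$xbar_k)

  fits <- lapply(fp_candidates(degree_max), function(p) {
    f <- fp_wls(fp_deriv_basis(xs, p), st$theta_k, st$se_k)
    if (is.null(f)) return(NULL)
    f$powers <- p
    f
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stopf("no fractional polynomial candidate could be fitted")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  deg <- vapply(fits, function(f) length(f$powers), integer(1))
  is_lin <- vapply(fits, function(f) identical(f$powers, 1), logical(1))
  # best likelihood; break ties toward lower degree then toward p = 1
  ord <- order(-ll, deg, !is_lin)
  best <- fits[[ord[1]]]
  linear_fit <- fits[[which(is_lin)]]

  fit <- structure(list(powers = best$powers, degree = length(best$powers),
                        coefficients = best$beta, vcov = best$vcov,
                        loglik = best$loglik, shift = shift,
                        reference_x = reference_x,
                        linear_loglik = linear_fit$loglik,
                        strata = st,
                        exposure_range = attr(strata, "exposure_range") %||%
                          range(st$xbar_k),
                        scale = attr(strata, "scale") %||% "identity"),
                   class = "mr_fpfit")
  fit$p_trend <- trend_test(st)
  fit$p_fp_nonlinearity <- fp_nonlinearity_test(st, fit)
  grid <- grid %||% seq(min(st$xbar_k), max(st$xbar_k), length.out = 101)
  fit$curve <- export_curve(fit, grid)
  fit
}

#' @export
print.mr_fpfit <- function(x, ...) {
  cat(sprintf("Fractional polynomial fit: degree %d, powers (%s)\n",
              x$degree, paste(x$powers, collapse = ", ")))
  cat(sprintf("  coefficients: %s\n",
              paste(signif(x$coefficients, 4), collapse = ", ")))
  cat(sprintf("  reference exposure: %.4g; trend p = %.3g; nonlinearity p = %.3g\n",
              x$reference_x, x$p_trend, x$p_fp_nonlinearity))
  invisible(x)
}

#' Trend test across stratum estimates
#'
#' Fixed-effect weighted meta-regression of the stratum estimates on the
#' stratum mean exposures (weights `1/se_k^2`); returns the two-sided
#' p-value for the slope, i.e. for a linear trend in the localized causal
#' effects.
#'
#' @param strata An `mr_strata` table with >= 3 usable strata.
#' @return p-value for the trend slope.
#' @export
trend_test <- function(strata) {
  st <- strata[!is.na(strata$theta_k), , drop = FALSE]
  if (nrow(st) < 3L) stopf("need at least 3 usable strata")
  D <- cbind(1, st$xbar_k)
  f <- fp_wls(D, st$theta_k, st$se_k)
  if (is.null(f)) stopf("no exposure spread")
  normal_p(f$beta[2], sqrt(f$vcov[2, 2]))
}

#' Fractional polynomial test of nonlinearity
#'
#' Likelihood-ratio-style comparison of the best fractional polynomial
#' model against the linear model (degree 1, power 1), referred to a
#' chi-squared distribution with effective degrees of freedom accounting
#' for the power search: 1 when the best model has degree 1 (the searched
#' power) and 1.5 when it has degree 2 (one extra coefficient plus a
#' Satterthwaite-style half-df allowance for the searched power pair,
#' matched to the null mean of the statistic in meta-regression
#' simulations; the candidate bases are highly correlated, so the naive
#' parameter count would over-correct). If the best model is the linear
#' model the p-value is 1 by convention.
#'
#' @param strata The stratum table used for fitting (for interface
#'   symmetry; the fit carries what is needed).
#' @param fit An `mr_fpfit` from [fp_meta_regress()].
#' @return p-value for nonlinearity.
#' @export
fp_nonlinearity_test <- function(strata, fit) {
  if (identical(fit$powers, 1)) return(1)
  lr <- 2 * (fit$loglik - fit$linear_loglik)
  df <- if (fit$degree == 1) 1 else 1.5
  stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}

#' Export a dose-response curve from a fractional polynomial fit
#'
#' Evaluates the integrated causal curve and pointwise 95% CIs on a grid,
#' relative to the reference exposure (effect 0 there by construction).
#' Grid points outside the observed exposure range trigger an
#' extrapolation warning.
#'
#' @param fit An `mr_fpfit`.
#' @param grid Numeric exposure grid (raw units).
#' @param reference_x Override the fit's reference exposure.
#' @return data.frame: x, effect, se, ci_low, ci_high, scale, reference_x.
#' @export
export_curve <- function(fit, grid, reference_x = NULL) {
  reference_x <- reference_x %||% fit$reference_x
  rng <- fit$exposure_range
  if (any(grid < rng[1] - 1e-9) || any(grid > rng[2] + 1e-9))
    warnf("extrapolation: grid extends beyond the observed exposure range")
  H <- fp_curve_basis(grid + fit$shift, fit$powers)
  H0 <- fp_curve_basis(reference_x + fit$shift, fit$powers)
  G <- sweep(H, 2, H0)          # gradient wrt coefficients
  effect <- drop(G %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((G %*% fit$vcov) * G), 0))
  data.frame(x = grid, effect = effect, se = se,
             ci_low = effect - 1.96 * se, ci_high = effect + 1.96 * se,
             scale = fit$scale, reference_x = reference_x)
}
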