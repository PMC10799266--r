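assoc_result <- function(beta, se, n, scale, adjustment = "none",
                         extras = list()) {
  structure(list(beta = beta, se = se, p = normal_p(beta, se), n = n,
                 scale = scale, adjustment = adjustment, extras = extras),
            class = "mr_assoc")
}

#' @export
print.mr_assoc <- function(x, ...) {
  cat(sprintf("Association (%s, adj: %s): beta = %.4g, se = %.4g, p = %.3g, n = %d\n",
              x$scale, x$adjustment, x$beta, x$se, x$p, x$n))
  invisible(x)
}

## Assemble a covariate matrix; `covariates` may be NULL, a matrix or df.
covar_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(nrow = n, ncol = 0))
  m <- as.matrix(as.data.frame(covariates))
  storage.mode(m) <- "double"
  m
}

## Error on rank deficiency, naming the offending columns.
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
}

#' Standard covariate adjustment sets
#'
#' Builds the two preset adjustment designs used throughout the analysis:
#' `"cad_set"` for lipid traits and disease (baseline age, age squared,
#' sex, their interactions, and 20 principal components) and
#' `"mortality_set"` for mortality models on the attained-age timescale
#' (birth year, birth year squared, sex, their interactions, and 20
#' principal components). `"none"` returns no covariates.
#'
#' @param data Cohort data.frame (needs `age_at_recruitment`, `sex`,
#'   `recruitment_year`, `pc1..pc20` as applicable).
#' @param preset `"none"`, `"cad_set"` or `"mortality_set"`.
#' @return Numeric covariate matrix (possibly zero columns).
#' @export
adjustment_set <- function(data, preset = c("none", "cad_set", "mortality_set")) {
  preset <- match.arg(preset)
  if (preset == "none") return(matrix(nrow = nrow(data), ncol = 0))
  pcs <- as.matrix(data[, sprintf("pc%d", 1:20)])
  sex <- data$sex
  base <- if (preset == "cad_set") data$age_at_recruitment
          else data$recruitment_year - data$age_at_recruitment  # birth year
  nm <- if (preset == "cad_set") "age" else "birth_year"
  X <- cbind(base, base^2, sex, base * sex, base^2 * sex, pcs)
  colnames(X) <- c(nm, paste0(nm, "_sq"), "sex", paste0(nm, "_x_sex"),
                   paste0(nm, "_sq_x_sex"), colnames(pcs))
  X
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a quantitative outcome on a genetic score plus
#' covariates; returns the score coefficient with a normal-reference
#' p-value.
#'
#' @param outcome Numeric outcome vector.
#' @param score Genetic score (or any single regressor of interest).
#' @param covariates Optional covariate matrix/data.frame.
#' @param adjustment Label recorded in the result.
#' @return An `mr_assoc` with scale `"identity"`.
#' @export
linear_assoc <- function(outcome, score, covariates = NULL,
                         adjustment = "none") {
  n <- length(outcome)
  cv <- covar_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, score = score, cv)
  check_full_rank(X)
  fit <- stats::lm.fit(X, outcome)
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  if (df <= 0) stopf("more parameters than observations")
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  assoc_result(unname(fit$coefficients["score"]), se, n, "identity", adjustment)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on a genetic
#' score plus covariates; the score coefficient is a log odds ratio.
#' Complete separation and non-convergence are raised as errors rather than
#' returned as unstable estimates.
#'
#' @inheritParams linear_assoc
#' @return An `mr_assoc` with scale `"logOR"`.
#' @export
logistic_assoc <- function(outcome, score, covariates = NULL,
                           adjustment = "none") {
  if (length(unique(outcome)) < 2L) stopf("both outcome classes must be present")
  n <- length(outcome)
  cv <- covar_matrix(covariates, n)
  X <- cbind(`(Intercept)` = 1, score = score, cv)
  check_full_rank(X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, outcome, family = stats::binomial(),
                   control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients["score"])
  if (!fit$converged)
    stopf("logistic fit did not converge after %d iterations", fit$iter)
  if (sep && abs(beta) > 15) stopf("separation detected")
  W <- fit$weights
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(W))))
  se <- sqrt(XtWXinv[2, 2])
  assoc_result(beta, se, n, "logOR", adjustment)
}

#' Cox association on the attained-age timescale
#'
#' Cox proportional-hazards partial likelihood with delayed entry: the risk
#' set at age t contains individuals with `entry_age < t <= exit_age`. Ties
#' are handled by the Efron method. Attained age as the time axis makes age
#' the implicit baseline covariate; calendar confounding is absorbed by the
#' birth-year adjustment set.
#'
#' @param entry_age,exit_age Numeric vectors of entry and exit ages (years);
#'   `entry_age = NULL` means no delayed entry (time starts at 0).
#' @param status 0/1 event indicator at `exit_age`.
#' @param score Regressor of interest.
#' @param covariates Optional covariate matrix/data.frame.
#' @param adjustment Label recorded in the result.
#' @return An `mr_assoc` with scale `"logHR"`.
#' @export
cox_assoc <- function(entry_age, exit_age, status, score, covariates = NULL,
                      adjustment = "none") {
  if (sum(status) == 0) stopf("zero events")
  if (stats::var(score) == 0) stopf("non-identifiable: score is constant")
  n <- length(exit_age)
  if (!is.null(entry_age) && any(exit_age <= entry_age))
    stopf("exit_age must exceed entry_age")
  cv <- covar_matrix(covariates, n)
  X <- cbind(score = score, cv)
  y <- if (is.null(entry_age)) survival::Surv(exit_age, status)
       else survival::Surv(entry_age, exit_age, status)
  dd <- data.frame(X)
  form <- stats::as.formula(paste("y ~", paste(colnames(dd), collapse = " + ")))
  dd$y <- y
  inf_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dd, ties = "efron",
                    control = survival::coxph.control(eps = 1e-8, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) inf_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients["score"])
  se <- sqrt(diag(fit$var))[1]
  if (is.na(beta) || (inf_warn && abs(beta) > 15))
    stopf("non-identifiable: monotone partial likelihood")
  assoc_result(beta, se, n, "logHR", adjustment,
               extras = list(n_events = sum(status), iter = fit$iter))
}

#' Cause-specific Cox association
#'
#' Fits [cox_assoc()] for one cause of death, treating deaths from the
#' competing causes as censorings at their event age (cause-specific
#' hazards, not subdistribution hazards).
#'
#' @param entry_age,exit_age Entry/exit ages.
#' @param event_cause Factor/character in `none, cvd, cancer, other`.
#' @param cause The cause of interest.
#' @inheritParams cox_assoc
#' @return An `mr_assoc` with scale `"logHR"`.
#' @export
cause_specific_cox <- function(entry_age, exit_age, event_cause,
                               cause = c("cvd", "cancer", "other"),
                               score, covariates = NULL,
                               adjustment = "none") {
  cause <- match.arg(cause)
  status <- as.integer(event_cause == cause)
  if (sum(status) == 0) stopf("no events of cause '%s'", cause)
  cox_assoc(entry_age, exit_age, status, score, covariates, adjustment)
}
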