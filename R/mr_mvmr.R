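## Multi-coefficient outcome fit: returns the score-block coefficients and
## their covariance for linear, logistic, or Cox (delayed-entry) models.
multi_fit <- function(scores, covariates, outcome_type, outcome = NULL,
                      entry_age = NULL, exit_age = NULL, status = NULL) {
  n <- nrow(scores)
  cv <- covar_matrix(covariates, n)
  k <- ncol(scores)
  if (outcome_type == "cox") {
    X <- cbind(scores, cv)
    colnames(X) <- make.names(colnames(X) %||% sprintf("x%d", seq_len(ncol(X))),
                              unique = TRUE)
    dd <- data.frame(X)
    y <- if (is.null(entry_age)) survival::Surv(exit_age, status)
         else survival::Surv(entry_age, exit_age, status)
    form <- stats::as.formula(paste("y ~", paste(colnames(dd), collapse = "+")))
    dd$y <- y
    fit <- survival::coxph(form, data = dd, ties = "efron")
    idx <- seq_len(k)
    return(list(coef = unname(fit$coefficients[idx]),
                vcov = fit$var[idx, idx, drop = FALSE]))
  }
  X <- cbind(1, scores, cv)
  check_full_rank(X)
  idx <- 1L + seq_len(k)
  if (outcome_type == "linear") {
    fit <- stats::lm.fit(X, outcome)
    sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
    V <- chol2inv(chol(crossprod(X))) * sigma2
  } else {
    fit <- stats::glm.fit(X, outcome, family = stats::binomial())
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  }
  list(coef = unname(fit$coefficients[idx]), vcov = V[idx, idx, drop = FALSE])
}

#' Multivariable MR with genetic risk scores
#'
#' Two-stage estimation of direct causal effects of several exposures.
#' Stage 1 regresses each exposure on all the scores (plus covariates),
#' giving the score-exposure coefficient matrix B. Stage 2 regresses the
#' outcome on all the scores (plus covariates), giving score-outcome
#' coefficients c with covariance V. The direct effects solve `B' theta =
#' c`; standard errors come from the delta method treating B as fixed
#' (`Var(theta) = A V A'` with `A = inv(B')`). A score with (numerically)
#' zero variance cannot identify its exposure: that exposure is dropped
#' from both stages with a warning, so the remaining model reduces to the
#' lower-dimensional analysis.
#'
#' @param exposures Numeric n x K matrix/data.frame of exposures.
#' @param scores Numeric n x K matrix of per-exposure genetic risk scores
#'   (column order matching `exposures`).
#' @param outcome Outcome vector (linear/logistic), or `NULL` for Cox.
#' @param outcome_type `"linear"`, `"logistic"`, or `"cox"`.
#' @param covariates Optional covariate matrix.
#' @param entry_age,exit_age,status Survival inputs when
#'   `outcome_type = "cox"`.
#' @return Object of class `mr_mvmr`: data.frame `estimates` (exposure,
#'   theta, se, ci_low, ci_high, conditional_f), the `scale`, and a `note`
#'   naming the exposures each estimate is adjusted for.
#' @export
mvmr_grs <- function(exposures, scores, outcome = NULL,
                     outcome_type = c("linear", "logistic", "cox"),
                     covariates = NULL,
                     entry_age = NULL, exit_age = NULL, status = NULL) {
  outcome_type <- match.arg(outcome_type)
  exposures <- as.matrix(exposures)
  scores <- as.matrix(scores)
  K <- ncol(exposures)
  if (K < 2L) stopf("multivariable MR needs >= 2 exposures")
  if (ncol(scores) != K) stopf("need one score per exposure")
  enames <- colnames(exposures) %||% sprintf("exposure%d", seq_len(K))
  colnames(scores) <- paste0("score_", enames)

  keep <- apply(scores, 2, stats::var) > 1e-12
  if (!all(keep)) {
    warnf("degenerate score(s) for %s: exposure(s) dropped from the model",
          paste(enames[!keep], collapse = ", "))
    exposures <- exposures[, keep, drop = FALSE]
    scores <- scores[, keep, drop = FALSE]
    enames <- enames[keep]
    K <- ncol(exposures)
  }
  if (K == 0L) stopf("no usable scores")

  n <- nrow(scores)
  cv <- covar_matrix(covariates, n)
  # stage 1: exposures on all scores (+ covariates)
  X1 <- cbind(1, scores, cv)
  check_full_rank(X1)
  B <- matrix(0, K, K, dimnames = list(enames, colnames(scores)))
  for (e in seq_len(K))
    B[e, ] <- stats::lm.fit(X1, exposures[, e])$coefficients[1L + seq_len(K)]
  if (abs(det(B)) < 1e-12 * max(abs(B))^K)
    stopf("exposures not separately identified: score-exposure matrix is singular")

  # stage 2: outcome on all scores (+ covariates)
  s2 <- multi_fit(scores, covariates, outcome_type, outcome,
                  entry_age, exit_age, status)
  A <- solve(t(B))
  theta <- drop(A %*% s2$coef)
  V <- A %*% s2$vcov %*% t(A)
  se <- sqrt(diag(V))

  cf <- if (K >= 2L) conditional_f(exposures, scores, covariates)
        else score_strength(scores[, 1], exposures[, 1], covariates)$f_stat
  scale <- switch(outcome_type, linear = "identity", logistic = "logOR",
                  cox = "logHR")
  est <- data.frame(exposure = enames, theta = theta, se = se,
                    ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
                    p = vapply(seq_len(K), function(i) normal_p(theta[i], se[i]),
                               numeric(1)),
                    conditional_f = cf, row.names = NULL)
  note <- if (K > 1L)
    vapply(seq_len(K), function(i)
      paste("adjusted for genetically predicted",
            paste(enames[-i], collapse = ", ")), character(1))
  else "univariable (no co-exposure retained)"
  structure(list(estimates = est, scale = scale, note = note,
                 stage1_B = B), class = "mr_mvmr")
}

#' @export
print.mr_mvmr <- function(x, ...) {
  cat(sprintf("Multivariable MR (%s scale)\n", x$scale))
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Conditional instrument-strength statistics
#'
#' Sanderson-Windmeijer-style conditional F: for each exposure, the
#' instruments' incremental F statistic in a regression of that exposure on
#' the genetically predicted values of the other exposures. Collinear
#' instrument sets drive the conditional F toward zero even when every
#' marginal F is large.
#'
#' @param exposures n x K exposure matrix.
#' @param scores n x K score matrix (the instruments).
#' @param covariates Optional covariate matrix, partialled out first.
#' @return Named numeric vector of per-exposure conditional F statistics.
#' @export
conditional_f <- function(exposures, scores, covariates = NULL) {
  exposures <- as.matrix(exposures)
  scores <- as.matrix(scores)
  K <- ncol(exposures)
  if (K < 2L)
    stopf("conditional F needs >= 2 exposures; use score_strength() for one")
  n <- nrow(exposures)
  cv <- covar_matrix(covariates, n)
  resid_on <- function(y, M) stats::lm.fit(cbind(1, M), y)$residuals
  # partial out measured covariates everywhere
  if (ncol(cv) > 0) {
    exposures <- apply(exposures, 2, function(y) resid_on(y, cv))
    scores <- apply(scores, 2, function(y) resid_on(y, cv))
  }
  # genetically predicted exposures: projections onto the instrument span
  # (stable even when the scores are collinear)
  pred <- exposures - apply(exposures, 2, function(y) resid_on(y, scores))
  fstat <- numeric(K)
  for (e in seq_len(K)) {
    pred_others <- pred[, -e, drop = FALSE]
    rss0 <- sum(resid_on(exposures[, e], pred_others)^2)
    rss1 <- sum(resid_on(exposures[, e], scores)^2)
    df1 <- ncol(scores) - (K - 1)
    df2 <- n - ncol(scores) - 1 - ncol(cv)
    fstat[e] <- max(0, (rss0 - rss1) / df1 / (rss1 / df2))
  }
  names(fstat) <- colnames(exposures) %||% sprintf("exposure%d", seq_len(K))
  fstat
}
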