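# Build a stratum table directly from a known derivative function: theta_k
# observes f'(xbar_k) with the given noise.
strata_from_derivative <- function(xbar, fprime, se = 1e-4, seed = 1,
                                   reference_x = median(xbar)) {
  set.seed(seed)
  st <- data.frame(k = seq_along(xbar), n_k = 100L, xbar_k = xbar,
                   theta_k = fprime(xbar) + rnorm(length(xbar), 0, se),
                   se_k = se, usable = TRUE)
  attr(st, "reference_x") <- reference_x
  attr(st, "exposure_range") <- range(xbar)
  attr(st, "scale") <- "logOR"
  class(st) <- c("mr_strata", "data.frame")
  st
}

test_that("doubly ranked assignment matches the hand-enumerated example", {
  # instrument order 1..9, exposures (5,1,9 | 4,2,8 | 3,7,6)
  score <- 1:9
  expo <- c(5, 1, 9, 4, 2, 8, 3, 7, 6)
  a <- doubly_ranked_strata(score, expo, S = 3)
  expect_equal(a, c(2, 1, 3, 2, 1, 3, 1, 3, 2))
  expect_equal(sort(expo[a == 1]), c(1, 2, 3))
  expect_equal(sort(expo[a == 2]), c(4, 5, 6))
  expect_equal(sort(expo[a == 3]), c(7, 8, 9))

  expect_error(doubly_ranked_strata(1:8, rnorm(8), S = 3), "too few")
})

test_that("stratification is exact-sized, rank-based, and monotone when
           exposure follows the instrument", {
  set.seed(2)
  n <- 400; S <- 10
  score <- rnorm(n)
  expo <- 2 * score + rnorm(n, 0, 1e-9)   # exposure monotone in instrument
  a <- doubly_ranked_strata(score, expo, S)
  expect_true(all(table(a) == n / S))
  xb <- tapply(expo, a, mean)
  expect_true(all(diff(xb) > 0))

  # permutation invariance: assignments travel with individuals
  p <- sample(n)
  a_p <- doubly_ranked_strata(score[p], expo[p], S)
  expect_equal(a_p, a[p])

  # assignments depend only on ranks
  a_r <- doubly_ranked_strata(rank(score), exp(expo), S)
  expect_equal(a_r, a)

  # remainder handling: sizes differ by at most 1, total preserved
  a2 <- doubly_ranked_strata(rnorm(103), rnorm(103), S = 10)
  expect_equal(length(a2), 103)
  expect_lte(diff(range(table(a2))), 1)
})

test_that("the instrument stays independent of the confounder within doubly
           ranked strata but not within naive exposure deciles", {
  # conditioning on exposure deciles induces a score-confounder association
  # (collider); doubly ranked strata avoid it by construction
  ps_dr <- ps_naive <- numeric(40)
  for (i in 1:40) {
    co <- cohort_with_score(quick_config(n = 1500, m = 30, seed = 300 + i,
                                         confounder_effect_exposure = 0.1))
    d <- co$data
    a_dr <- doubly_ranked_strata(co$score, d$exposure, 10)
    a_nv <- cut(rank(d$exposure, ties.method = "first"), 10, labels = FALSE)
    ps_dr[i] <- summary(lm(d$confounder ~ co$score + factor(a_dr))
                        )$coefficients[2, 4]
    ps_naive[i] <- summary(lm(d$confounder ~ co$score + factor(a_nv))
                           )$coefficients[2, 4]
  }
  # doubly ranked: within-stratum score-confounder p-values look uniform
  expect_gt(ks.test(ps_dr, "punif")$p.value, 0.01)
  expect_gt(mean(ps_dr), 0.25)
  # naive exposure deciles: strong induced association
  expect_lt(median(ps_naive), 1e-6)

  # and the instrument spans its full range inside every final stratum,
  # unlike naive stratification which slices the score distribution too
  rng <- range(co$score)
  spans <- vapply(1:10, function(k) diff(range(co$score[a_dr == k])),
                  numeric(1))
  expect_true(all(spans > 0.6 * diff(rng)))
  spans_nv <- vapply(1:10, function(k) diff(range(co$score[a_nv == k])),
                     numeric(1))
  expect_gt(mean(spans), mean(spans_nv))
})

test_that("stratum LACE estimates reduce to and recover the linear effect", {
  cfg <- sim_config(n_individuals = 6000, n_variants = 40,
                    causal_curve = causal_curve("linear", 2), seed = 9)
  co <- cohort_with_score(cfg)
  d <- co$data

  # S = 1 reduces to the whole-sample ratio estimate
  st1 <- stratum_lace(co$score, d$exposure, rep(1L, nrow(d)), d, "disease")
  whole <- ratio_estimate(logistic_assoc(d$disease, co$score),
                          linear_assoc(d$exposure, co$score))
  expect_equal(st1$theta_k, whole$theta, tolerance = 1e-10)
  expect_equal(st1$se_k, whole$se, tolerance = 1e-10)

  # homogeneous linear effect: stratum estimates agree with the truth
  a <- doubly_ranked_strata(co$score, d$exposure, 10)
  st <- stratum_lace(co$score, d$exposure, a, d, "disease")
  expect_equal(sum(st$n_k), nrow(d))
  expect_true(all(diff(st$xbar_k) > 0))
  covered <- abs(st$theta_k - 2) < 2 * st$se_k
  expect_gte(mean(covered), 0.8)
  # Cochran Q across strata consistent with homogeneity
  w <- 1 / st$se_k^2
  tbar <- sum(w * st$theta_k) / sum(w)
  Q <- sum(w * (st$theta_k - tbar)^2)
  expect_lt(Q, qchisq(0.999, df = nrow(st) - 1))
})

test_that("stratum estimates track the curvature of a quadratic effect", {
  hits <- logical(8)
  for (i in seq_along(hits)) {
    cfg <- sim_config(n_individuals = 8000, n_variants = 40,
                      causal_curve = causal_curve("quadratic", c(-6, 4)),
                      disease_intercept = qlogis(0.15), seed = 400 + i)
    co <- cohort_with_score(cfg)
    d <- co$data
    a <- doubly_ranked_strata(co$score, d$exposure, 10)
    st <- stratum_lace(co$score, d$exposure, a, d, "disease")
    # f'(x) = -6 + 8x increases in x: positive rank correlation expected
    hits[i] <- cor(st$xbar_k, st$theta_k, method = "spearman") > 0
  }
  expect_gte(mean(hits), 0.85)
})

test_that("constant stratum estimates select the linear model exactly", {
  xb <- seq(0.6, 1.4, length.out = 10)
  st <- strata_from_derivative(xb, function(x) rep(0.8, length(x)), se = 1e-6)
  st$theta_k <- 0.8   # exactly constant
  fit <- fp_meta_regress(st)
  expect_equal(fit$powers, 1)
  expect_equal(fit$degree, 1)
  expect_equal(unname(fit$coefficients), 0.8, tolerance = 1e-9)
  expect_equal(fit$p_fp_nonlinearity, 1)
  # curve is c * (x - reference)
  expect_equal(fit$curve$effect, 0.8 * (fit$curve$x - fit$reference_x),
               tolerance = 1e-8)
})

test_that("power-1 meta-regression equals an independent WLS solve", {
  xb <- seq(0.5, 2, length.out = 8)
  st <- strata_from_derivative(xb, function(x) 0.3 + 0 * x, se = 0.05,
                               seed = 3)
  st$theta_k <- st$theta_k + 0.1 * xb    # add some trend
  # degree-1 power 1 basis is the constant; fit it directly
  f <- fp_meta_regress(st, degree_max = 1)
  # trend test oracle: WLS of theta on (1, xbar)
  w <- 1 / st$se_k^2
  Xd <- cbind(1, st$xbar_k)
  beta <- solve(t(Xd) %*% (Xd * w), t(Xd) %*% (st$theta_k * w))
  V <- solve(t(Xd) %*% (Xd * w))
  z <- beta[2] / sqrt(V[2, 2])
  expect_equal(trend_test(st), 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("a known quadratic curve is recovered within 1% on the interior", {
  b <- c(-6, 4)                       # f(x) = -6x + 4x^2, f'(x) = -6 + 8x
  xb <- seq(0.55, 1.45, length.out = 10)
  st <- strata_from_derivative(xb, function(x) b[1] + 2 * b[2] * x,
                               se = 1e-4, seed = 4, reference_x = 1)
  fit <- fp_meta_regress(st)
  grid <- seq(min(xb), max(xb), length.out = 101)
  truth <- (b[1] * grid + b[2] * grid^2) - (b[1] * 1 + b[2] * 1^2)
  curve <- export_curve(fit, grid, reference_x = 1)
  keep <- abs(truth) > 0.05 * max(abs(truth))
  rel <- abs(curve$effect[keep] - truth[keep]) / abs(truth[keep])
  expect_lt(max(rel), 0.01)
  # and the strong curvature is detected
  expect_lt(fit$p_fp_nonlinearity, 1e-6)
})

test_that("trend test behaves at its extremes", {
  xb <- seq(0.5, 1.5, length.out = 10)
  flat <- strata_from_derivative(xb, function(x) rep(0.5, length(x)),
                                 se = 0.05, seed = 5)
  flat$theta_k <- 0.5
  expect_gt(trend_test(flat), 0.99)

  sloped <- strata_from_derivative(xb, function(x) 0.2 + 0.5 * x, se = 1e-5,
                                   seed = 6)
  expect_lt(trend_test(sloped), 1e-10)
  expect_error(trend_test(flat[1:2, ]), "at least 3")
})

test_that("curve export honours the reference and transform conventions", {
  xb <- seq(0.5, 1.5, length.out = 10)
  st <- strata_from_derivative(xb, function(x) 1 - x, se = 0.01, seed = 7)
  fit <- fp_meta_regress(st)
  curve <- fit$curve
  at_ref <- which.min(abs(curve$x - fit$reference_x))
  ref_curve <- export_curve(fit, fit$reference_x)
  expect_equal(ref_curve$effect, 0)
  expect_equal(ref_curve$ci_low, 0)
  expect_equal(ref_curve$ci_high, 0)
  expect_true(all(curve$ci_low <= curve$effect & curve$effect <= curve$ci_high))
  # exponentiated export equals exp of the log-scale columns
  expect_equal(exp(curve$effect), exp(1)^curve$effect)
  orhr <- exp(curve[, c("effect", "ci_low", "ci_high")])
  expect_true(all(orhr$ci_low <= orhr$effect & orhr$effect <= orhr$ci_high))
  expect_warning(export_curve(fit, seq(0, 3, by = 0.5)), "extrapolation")
})

test_that("stratum tables with failures degrade gracefully", {
  xb <- seq(0.5, 1.5, length.out = 10)
  st <- strata_from_derivative(xb, function(x) 0.5 * x, se = 0.02, seed = 8)
  st$theta_k[4] <- NA; st$se_k[4] <- NA; st$usable[4] <- FALSE
  expect_warning(fit <- fp_meta_regress(st), "excluded")
  expect_true(is.finite(fit$loglik))
  expect_error(fp_meta_regress(st[1:3, ][c(1, 1, 1), ]), "spread|usable")
})
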