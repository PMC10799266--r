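test_that("ratio estimate follows the delta method", {
  gy <- list(beta = 0.4, se = 0.1, scale = "logOR", n = 100L)
  gx <- list(beta = 0.2, se = 0.01, scale = "identity", n = 100L)
  est <- ratio_estimate(gy, gx)
  expect_equal(est$theta, 2.0)
  expect_equal(est$se, 0.5)
  expect_equal(est$scale, "logOR")

  expect_equal(ratio_estimate(list(beta = 0, se = 0.1, scale = "logOR"),
                              gx)$theta, 0)
  expect_error(ratio_estimate(gy, list(beta = 0, se = 0.1)), "instrument")
})

test_that("first-order ratio se is within the bootstrap second-order correction", {
  by <- 0.4; sy <- 0.1; bx <- 0.2; sx <- 0.015
  est <- ratio_estimate(list(beta = by, se = sy, scale = "identity"),
                        list(beta = bx, se = sx))
  set.seed(1)
  boot <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  second <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  correction <- second - sy / bx
  # bootstrap sd sits between the first-order se and first-order + correction
  expect_lt(abs(sd(boot) - est$se), correction + 0.02 * second)
})

test_that("IVW equals closed-form weighted least squares", {
  ss <- summary_stats(c("a", "b"), beta_gx = c(0.1, 0.2), se_gx = c(0.01, 0.01),
                      beta_gy = c(0.2, 0.2), se_gy = c(0.1, 0.1))
  est <- mr_ivw(ss)
  expect_equal(est$theta, 1.2, tolerance = 1e-12)
  expect_equal(est$extras$se_fixed, 1 / sqrt(5), tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(5), tolerance = 1e-12)  # Q below expectation

  # independent WLS oracle on a larger random fixture
  set.seed(2)
  J <- 20
  bx <- runif(J, 0.05, 0.3); by <- 0.7 * bx + rnorm(J, 0, 0.05)
  sy <- runif(J, 0.02, 0.1)
  ssJ <- summary_stats(sprintf("v%d", 1:J), bx, rep(0.01, J), by, sy)
  oracle <- wls_solve(cbind(bx), by, 1 / sy^2)
  expect_equal(mr_ivw(ssJ)$theta, unname(drop(oracle)), tolerance = 1e-10)

  # algebraic identity: precision-weighted mean of ratios, weights bx^2/se^2
  w <- bx^2 / sy^2
  expect_equal(mr_ivw(ssJ)$theta, sum(w * by / bx) / sum(w), tolerance = 1e-10)

  # consistency: shared ratio with tiny ses
  ssc <- summary_stats(c("a", "b", "c"), c(0.1, 0.2, 0.3), rep(1e-4, 3),
                       c(0.05, 0.1, 0.15), rep(1e-4, 3))
  expect_equal(mr_ivw(ssc)$theta, 0.5, tolerance = 1e-8)

  # two identical variants reduce to the ratio estimate
  ss1 <- summary_stats(c("a", "a2"), c(0.1, 0.1), c(0.01, 0.01),
                       c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(mr_ivw(ss1)$theta, 2, tolerance = 1e-12)
  expect_error(mr_ivw(ss1[1, ]), "ratio_estimate")
})

test_that("MR-Egger solves the free-intercept weighted regression", {
  # exact line by = 0.05 + 0.8 bx
  bx <- c(0.1, 0.2, 0.3)
  ss <- summary_stats(c("a", "b", "c"), bx, rep(0.01, 3),
                      0.05 + 0.8 * bx, rep(0.05, 3))
  est <- mr_egger(ss)
  expect_equal(est$theta, 0.8, tolerance = 1e-10)
  expect_equal(est$extras$egger_intercept, 0.05, tolerance = 1e-10)

  # zero-intercept data: Egger slope matches IVW slope
  set.seed(3)
  J <- 40
  bxJ <- runif(J, 0.05, 0.3)
  byJ <- 0.5 * bxJ + rnorm(J, 0, 1e-4)
  ssJ <- summary_stats(sprintf("v%d", 1:J), bxJ, rep(0.01, J), byJ,
                       rep(0.05, J))
  expect_equal(mr_egger(ssJ)$theta, mr_ivw(ssJ)$theta, tolerance = 1e-3)

  # directional pleiotropy detection power at favourable settings
  set.seed(4)
  hits <- vapply(1:200, function(i) {
    bx <- runif(50, 0.05, 0.3)
    by <- 0.1 + 0.5 * bx + rnorm(50, 0, 0.02)
    s <- summary_stats(sprintf("v%d", 1:50), bx, rep(0.01, 50), by,
                       rep(0.02, 50))
    mr_egger(s)$extras$egger_intercept_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)

  expect_error(mr_egger(ss[1:2, ]), "at least 3")
  ssflat <- summary_stats(c("a", "b", "c"), rep(0.1, 3), rep(0.01, 3),
                          c(0.1, 0.2, 0.3), rep(0.05, 3))
  expect_error(mr_egger(ssflat), "spread")
})

test_that("weighted median interpolates the cumulative weight function", {
  # plain median with equal weights
  ss <- summary_stats(c("a", "b", "c"), c(0.1, 0.1, 0.1), rep(1e-6, 3),
                      c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(mr_weighted_median(ss, n_boot = 50)$theta, 2, tolerance = 1e-9)

  # hand-enumerated cumulative-weight case: ratios (1,2,3), weights
  # (0.5, 0.25, 0.25) -> 1 + (0.5 - 0.25)/(0.625 - 0.25) = 5/3
  # weights are bx^2/se_gy^2: bx = (sqrt(2), 1, 1), se_gy = 1 gives (2,1,1)
  ssw <- summary_stats(c("a", "b", "c"), c(sqrt(2), 1, 1), rep(1e-6, 3),
                       c(sqrt(2) * 1, 1 * 2, 1 * 3), rep(1, 3))
  expect_equal(mr_weighted_median(ssw, n_boot = 50)$theta, 5 / 3,
               tolerance = 1e-9)

  # breakdown: <= 50% weight on wildly invalid variants barely moves it
  set.seed(5)
  J <- 40
  bx <- runif(J, 0.1, 0.3)
  by <- 1 * bx
  by[1:12] <- by[1:12] + runif(12, 2, 5)     # ~30% of weight corrupted
  ssb <- summary_stats(sprintf("v%d", 1:J), bx, rep(0.01, J),
                       by + rnorm(J, 0, 0.02), rep(0.02, J))
  est <- mr_weighted_median(ssb, n_boot = 500, seed = 11)
  expect_lt(abs(est$theta - 1), 2 * est$se + 0.1)

  # bootstrap se is seeded and reproducible
  e1 <- mr_weighted_median(ssb, n_boot = 200, seed = 3)
  e2 <- mr_weighted_median(ssb, n_boot = 200, seed = 3)
  expect_identical(e1$se, e2$se)

  ssz <- summary_stats(c("a", "b", "c", "d"), c(0, 0.1, 0.1, 0.1),
                       rep(0.01, 4), c(0.1, 0.1, 0.2, 0.3), rep(0.1, 4))
  expect_warning(mr_weighted_median(ssz, n_boot = 50), "dropped")
})

test_that("contamination mixture matches exhaustive configuration enumeration", {
  # no contamination: identical ratios, single mode
  ss0 <- summary_stats(c("a", "b", "c"), c(0.1, 0.2, 0.4), rep(1e-6, 3),
                       0.5 * c(0.1, 0.2, 0.4), c(0.001, 0.002, 0.004))
  e0 <- mr_conmix(ss0)
  expect_equal(e0$theta, 0.5, tolerance = 0.01)
  expect_equal(e0$extras$n_modes, 1)
  expect_true(all(e0$extras$valid))

  # 2 valid at theta=1, 1 outlier at 5: outlier classified invalid and the
  # profile maximum equals brute force over all 2^3 validity configurations
  ratios <- c(1, 1, 5); se <- rep(0.05, 3)
  ss1 <- summary_stats(c("a", "b", "c"), rep(1, 3), rep(1e-6, 3),
                       ratios, se)
  psi <- 3
  e1 <- mr_conmix(ss1, psi = psi)
  expect_lt(abs(e1$theta - 1), 0.05)
  expect_equal(e1$extras$valid, c(TRUE, TRUE, FALSE))

  # brute-force oracle: enumerate configurations over the same grid
  grid <- seq(min(ratios) - 1, max(ratios) + 1, length.out = 2001)
  configs <- expand.grid(rep(list(c(TRUE, FALSE)), 3))
  best <- -Inf; best_theta <- NA
  for (g in grid) {
    for (r in seq_len(nrow(configs))) {
      v <- unlist(configs[r, ])
      ll <- sum(ifelse(v, dnorm(ratios, g, se, log = TRUE),
                       dnorm(ratios, 0, sqrt(se^2 + psi^2), log = TRUE)))
      if (ll > best) { best <- ll; best_theta <- g }
    }
  }
  expect_equal(e1$theta, best_theta, tolerance = 0.01)

  # widening psi inflates the all-invalid likelihood while the invalid SD
  # stays below the smallest |ratio| (dnorm(x, 0, s) rises in s for s < |x|)
  ll_all_invalid <- function(psi)
    sum(dnorm(ratios, 0, sqrt(se^2 + psi^2), log = TRUE))
  psis <- c(0.2, 0.4, 0.6, 0.9)
  expect_true(all(diff(vapply(psis, ll_all_invalid, numeric(1))) >= 0))

  expect_error(mr_conmix(ss1, grid_n = 1), "degenerate")
})

test_that("all summary estimators are sign-flip invariant per variant", {
  ss <- sim_sumstats(J = 30, theta = 0.4, seed = 6)
  flip <- rep(c(1, -1), length.out = 30)
  ssf <- summary_stats(ss$variant_id, ss$beta_gx * flip, ss$se_gx,
                       ss$beta_gy * flip, ss$se_gy)
  expect_equal(mr_ivw(ssf)$theta, mr_ivw(ss)$theta, tolerance = 1e-10)
  expect_equal(mr_egger(ssf)$theta, mr_egger(ss)$theta, tolerance = 1e-10)
  expect_equal(mr_weighted_median(ssf, n_boot = 50, seed = 1)$theta,
               mr_weighted_median(ss, n_boot = 50, seed = 1)$theta,
               tolerance = 1e-10)
  expect_equal(mr_conmix(ssf)$theta, mr_conmix(ss)$theta, tolerance = 1e-8)
})

test_that("estimators recover the causal slope under valid instruments", {
  ss <- sim_sumstats(J = 50, theta = 0.5, se_gy = 0.02, seed = 7)
  for (f in list(mr_ivw, mr_egger,
                 function(s) mr_weighted_median(s, n_boot = 300, seed = 2),
                 mr_conmix)) {
    est <- f(ss)
    expect_lt(abs(est$theta - 0.5), 2 * max(est$se, 0.01))
  }
})

test_that("subgroup z-test reproduces the printed worked examples", {
  # male vs female disease odds ratios
  m <- estimate_from_ci(1.81, 1.70, 1.92, "logOR")
  f <- estimate_from_ci(1.43, 1.32, 1.55, "logOR")
  zt <- subgroup_difference_z(m, f)
  expect_lt(zt$p, 0.001)

  # male vs female all-cause hazard ratios: p rounds to .17
  mh <- estimate_from_ci(1.14, 1.08, 1.21, "logHR")
  fh <- estimate_from_ci(1.07, 1.00, 1.15, "logHR")
  zt2 <- subgroup_difference_z(mh, fh)
  expect_lt(abs(zt2$p - 0.17), 0.02)

  # identical estimates: z = 0, p = 1
  z0 <- subgroup_difference_z(m, m)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)

  expect_error(subgroup_difference_z(m, mh), "scales")
})

test_that("exponentiation maps log-scale estimates to ORs per SD", {
  e0 <- mr_estimate <- ratio_estimate(list(beta = 0, se = 0.1, scale = "logOR"),
                                      list(beta = 1, se = 0.01))
  x0 <- exponentiate_estimate(e0)
  expect_equal(x0$estimate, 1)
  expect_true(x0$ci95[1] < 1 && x0$ci95[2] > 1)

  e2 <- ratio_estimate(list(beta = log(2), se = 0, scale = "logHR"),
                       list(beta = 1, se = 0))
  expect_equal(exponentiate_estimate(e2)$estimate, 2)
  expect_equal(exponentiate_estimate(e2)$measure, "HR")

  # round trip
  e <- ratio_estimate(list(beta = 0.3, se = 0.05, scale = "logOR"),
                      list(beta = 0.5, se = 0.01))
  expect_equal(log(exponentiate_estimate(e)$estimate), e$theta)

  eid <- ratio_estimate(list(beta = 0.3, se = 0.05, scale = "identity"),
                        list(beta = 0.5, se = 0.01))
  expect_error(exponentiate_estimate(eid), "log")
})
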