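# Small cohort configurations reused across tests. Kept deliberately small;
# statistical checks that need power set their own sizes.

quick_config <- function(n = 2000, m = 30, seed = 7, ...) {
  sim_config(n_individuals = n, n_variants = m, seed = seed, ...)
}

# A cohort plus its GRS built from the true generator weights.
cohort_with_score <- function(cfg = quick_config()) {
  co <- simulate_cohort(cfg)
  w <- data.frame(variant_id = colnames(co$dosages),
                  effect_allele = "A",
                  weight = co$true_weights)
  co$score <- build_grs(co$dosages, w)
  co
}

# Independent weighted-least-squares solve (the oracle for IVW/Egger).
wls_solve <- function(X, y, w) {
  solve(t(X) %*% (X * w), t(X) %*% (y * w))
}

# Summary statistics with a known causal slope theta and optional pleiotropy
# drawn at the summary level (no individual data involved).
sim_sumstats <- function(J = 50, theta = 0.5, se_gy = 0.05, se_gx = 0.01,
                         pleio_sd = 0, pleio_mean = 0, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    bx_true <- runif(J, 0.05, 0.2)
    alpha <- rnorm(J, pleio_mean, pleio_sd)
    bx <- rnorm(J, bx_true, se_gx)
    by <- rnorm(J, theta * bx_true + alpha, se_gy)
    summary_stats(sprintf("v%03d", 1:J), bx, rep(se_gx, J), by, rep(se_gy, J))
  })
}
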