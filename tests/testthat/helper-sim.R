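# Small simulation configurations reused across tests.

tiny_cfg <- function(...) {
  args <- list(n_strains = 12L, n_proteins = 200L, n_phosphosites = 250L,
               n_regulators = 2L, targets_per_regulator = 8L,
               phospho_targets_per_regulator = 8L,
               n_modules = 0L, n_assignment_groups = 3L, n_batches = 4L,
               noise_sd = 0.05, loading_cv = 0.1, missing_rate_plex = 0.05,
               seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

noiseless_cfg <- function(...) {
  tiny_cfg(noise_sd = 0, loading_cv = 0, missing_rate_plex = 0, ...)
}

run_sim <- function(cfg) {
  truth <- build_truth(cfg)
  design <- build_design(cfg)
  simulate_reporter_data(truth, design, cfg)
}

# brute-force Pearson r and p (direct covariance formula + t transform)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(r = r, p = p)
}

# exhaustive hypergeometric upper tail from binomial coefficients
oracle_hyper_tail <- function(k, K, n, N) {
  total <- choose(N, n)
  sum(vapply(k:min(K, n), function(i) choose(K, i) * choose(N - K, n - i), 0)) / total
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
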