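# Shared fixtures: everything is generated in code at test time.

quick_cfg <- function(seed = 1L, chains = 1L, n = 600L, burn = 300L, ...) {
  mcmc_config(n_samples = n, n_burnin = burn, n_chains = chains, seed = seed, ...)
}

toy_feature <- function(seed = 1L, I = 30L, rho = 0.5, ...) {
  generate_dataset(sim_config(n_cells = I, n_features = 1L,
                              rho_source = "values", rho_values = rho,
                              seed = seed, ...))$features[[1]]
}

# A hand-built posterior_samples object with k identical draws at a point
# (degenerate posterior), including consistent log-likelihoods.
point_mass_posterior <- function(data, params, k = 20L, variant = "zip") {
  pi_val <- if (variant == "zip") params$pi else 0
  ll <- sum(zip_log_pmf(data$y1, params$X[, 1], data$s, pi_val)) +
    sum(binom_probit_log_pmf(data$y2[data$n > 0], params$X[data$n > 0, 2],
                             data$n[data$n > 0]))
  draws <- matrix(rep(c(params$mu1, params$mu2, params$sigma1, params$sigma2,
                        params$rho, pi_val), each = k), nrow = k)
  posterior_samples(list(draws), loglik = list(rep(ll, k)),
                    X_mean = params$X, variant = variant,
                    feature_id = data$feature_id)
}
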