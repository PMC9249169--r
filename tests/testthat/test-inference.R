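# Sampler and diagnostics.

test_that("gelman_rubin reproduces the classical formula and its limits", {
  # two chains of two draws: hand evaluation of the between/within ratio
  draws <- cbind(c(1, 3), c(2, 4))
  n <- 2
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  expect_equal(gelman_rubin(draws), sqrt(((n - 1) / n * W + B / n) / W))

  # long well-mixed chains converge to 1
  set.seed(1)
  big <- matrix(rnorm(4 * 4000), ncol = 4)
  expect_equal(gelman_rubin(big), 1, tolerance = 0.01)

  # a shifted chain is flagged
  shifted <- big
  shifted[, 1] <- shifted[, 1] + 10
  expect_gt(gelman_rubin(shifted), 1.1)

  # split variant catches within-chain drift that whole chains hide
  drift <- replicate(2, c(rnorm(500), rnorm(500) + 5))
  expect_gt(gelman_rubin(drift), 1.1)
  expect_lt(gelman_rubin(drift, split = FALSE), 1.05)

  expect_error(gelman_rubin(matrix(1, 10, 2)), "degenerate")
  expect_error(gelman_rubin(matrix(1:4, ncol = 1)), "2 chains")
})

test_that("fit_feature is bitwise reproducible for a fixed seed", {
  fd <- toy_feature(seed = 2, I = 25)
  cfg <- quick_cfg(seed = 42, chains = 2, n = 400L, burn = 200L)
  f1 <- fit_feature(fd, config = cfg)
  f2 <- fit_feature(fd, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  # different seed gives different draws
  f3 <- fit_feature(fd, config = quick_cfg(seed = 43, chains = 2, n = 400L, burn = 200L))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("draws respect parameter supports and bookkeeping", {
  fd <- toy_feature(seed = 6, I = 40)
  cfg <- quick_cfg(seed = 7, chains = 2)
  fit <- fit_feature(fd, config = cfg)
  d <- do.call(rbind, fit$draws)
  expect_equal(nrow(fit$draws[[1]]), cfg$n_samples - cfg$n_burnin)
  expect_length(fit$draws, 2L)
  expect_true(all(abs(d[, "rho"]) < 1))
  expect_true(all(d[, "pi"] >= 0 & d[, "pi"] <= 1))
  expect_true(all(d[, c("sigma1", "sigma2")] > 0))
  expect_equal(dim(fit$X_mean), c(40L, 2L))
  # the Poisson variant pins pi at zero
  pfit <- fit_feature(fd, config = cfg, zero_inflated = FALSE)
  expect_true(all(do.call(rbind, pfit$draws)[, "pi"] == 0))
  expect_identical(pfit$variant, "poisson")
})

test_that("vacuous likelihood returns the prior on rho", {
  # all-zero expression with zero coverage everywhere carries no
  # information about the latent correlation, so its posterior must match
  # the scaled-Beta prior's first two moments (sd = sqrt(4 d1 d2 /
  # ((d1+d2)^2 (d1+d2+1))) = 0.1796 for d1 = d2 = 15)
  fd <- feature_data("void", y1 = rep(0, 50), y2 = rep(0, 50), n = rep(0, 50))
  fit <- fit_feature(fd, config = mcmc_config(3000, 1000, n_chains = 2, seed = 4))
  r <- rho_draws(fit)
  prior_sd <- sqrt(4 * 15 * 15 / (30^2 * 31))
  expect_equal(mean(r), 0, tolerance = 3 * prior_sd / sqrt(200))  # heavy autocorrelation margin
  expect_equal(sd(r), prior_sd, tolerance = 0.03)
})

test_that("posterior recovers a strong correlation at large cell counts", {
  fd <- toy_feature(seed = 12, I = 1600, rho = 0.6)
  fit <- fit_feature(fd, config = mcmc_config(1000, 500, n_chains = 1, seed = 5))
  expect_equal(mean(rho_draws(fit)), 0.6, tolerance = 0.1)
  expect_equal(mean(do.call(rbind, fit$draws)[, "pi"]), 0.2, tolerance = 0.08)
})

test_that("initialization failures name the offending term", {
  fd <- toy_feature(seed = 3, I = 10)
  X <- cbind(rep(4, 10), rep(0, 10))
  # pi exactly 1 has zero Beta(2, 8) prior density
  bad_prior <- feature_params(4, 0, 1, 1, rho = 0, pi = 1, X = X)
  expect_error(scLatentCor:::check_finite_at_init(fd, hyperparams(), bad_prior),
               "prior")
  # an infinite latent state breaks the expression likelihood first
  bad_like <- feature_params(4, 0, 1, 1, rho = 0, pi = 0.2,
                             X = cbind(rep(Inf, 10), rep(0, 10)))
  expect_error(scLatentCor:::check_finite_at_init(fd, hyperparams(), bad_like),
               "expression_likelihood")
})

test_that("fit_all is independent of the worker count and derives seeds", {
  ds <- generate_dataset(sim_config(n_cells = 20, n_features = 6, seed = 9))
  cfg <- quick_cfg(seed = 11, n = 300L, burn = 150L)
  serial <- fit_all(ds, config = cfg, n_workers = 1)
  parallel <- fit_all(ds, config = cfg, n_workers = 3)
  expect_equal(lapply(serial, `[[`, "draws"), lapply(parallel, `[[`, "draws"))
  # per-feature seeds differ so features are not identical copies
  expect_false(identical(serial[[1]]$draws, serial[[2]]$draws))
  expect_error(fit_all(list(), config = cfg), "empty")
})

test_that("90% credible intervals cover the truth at the nominal rate", {
  ds <- generate_dataset(sim_config(n_features = 100, seed = 33))
  fits <- fit_all(ds, config = mcmc_config(1000, 500, n_chains = 1L, seed = 33))
  covered <- vapply(seq_along(fits), function(j) {
    ci <- quantile(rho_draws(fits[[j]]), c(0.05, 0.95))
    ds$truth$rho[j] >= ci[1] && ds$truth$rho[j] <= ci[2]
  }, logical(1))
  expect_equal(mean(covered), 0.90, tolerance = 0.07 / 0.90)
})

test_that("posterior_summary tabulates one row per fitted feature", {
  ds <- generate_dataset(sim_config(n_cells = 20, n_features = 3, seed = 13))
  fits <- fit_all(ds, config = quick_cfg(seed = 2, chains = 2, n = 300L, burn = 150L))
  s <- posterior_summary(fits)
  expect_equal(nrow(s), 3L)
  expect_true(all(c("feature_id", "rho_mean", "rho_q05", "rho_q95", "rhat_max") %in% names(s)))
  expect_true(all(s$rho_q05 <= s$rho_mean & s$rho_mean <= s$rho_q95))
  tmp <- tempfile(fileext = ".tsv")
  write_posterior_summary(fits, tmp)
  back <- read.delim(tmp)
  expect_equal(back$rho_mean, s$rho_mean, tolerance = 1e-12)
})
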