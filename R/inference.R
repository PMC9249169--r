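#' MCMC sampler configuration
#'
#' Defaults follow the reference analysis settings: 5000 iterations per
#' chain with the first 3000 discarded as burn-in, step size adapted
#' during burn-in toward a 0.65 acceptance statistic, and 4 chains for
#' split-R-hat convergence monitoring.
#'
#' @param n_samples total iterations per chain.
#' @param n_burnin iterations discarded (and used for adaptation).
#' @param target_accept dual-averaging acceptance target in (0, 1).
#' @param n_chains number of independent chains.
#' @param seed integer seed; identical seed + config + data reproduce
#'   draws bitwise.
#' @param max_treedepth maximum doubling depth of the trajectory tree.
#' @param store_latent keep full latent-state draws (memory heavy); the
#'   posterior mean of the latent states is always retained.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 5000L, n_burnin = 3000L,
                        target_accept = 0.65, n_chains = 4L, seed = 1L,
                        max_treedepth = 10L, store_latent = FALSE) {
  n_samples <- as.integer(n_samples); n_burnin <- as.integer(n_burnin)
  if (n_burnin >= n_samples) stop("n_burnin must be smaller than n_samples")
  if (n_burnin < 0L) stop("n_burnin must be non-negative")
  if (target_accept <= 0 || target_accept >= 1) stop("target_accept must lie in (0, 1)")
  if (n_chains < 1L) stop("need at least one chain")
  structure(list(n_samples = n_samples, n_burnin = n_burnin,
                 target_accept = target_accept, n_chains = as.integer(n_chains),
                 seed = as.integer(seed), max_treedepth = as.integer(max_treedepth),
                 store_latent = isTRUE(store_latent)),
            class = "mcmc_config")
}

par_names <- c("mu1", "mu2", "sigma1", "sigma2", "rho", "pi")

#' Container for per-feature posterior draws
#'
#' Mostly produced by [fit_feature()]; the constructor is exported so that
#' draw sets from other sources (e.g. hand-built fixtures) can flow into
#' the decision and model-selection machinery.
#'
#' @param draws list of per-chain matrices (draws x 6) with columns
#'   `mu1, mu2, sigma1, sigma2, rho, pi` on the natural scale.
#' @param loglik list of per-chain vectors of observation log-likelihoods
#'   conditional on the latent states (used for DIC), or `NULL`.
#' @param X_mean I x 2 posterior mean of the latent states, or `NULL`.
#' @param variant `"zip"` or `"poisson"` (expression likelihood used).
#' @param feature_id feature identifier.
#' @param rhat named vector of split-R-hat values, or `NULL`.
#' @param accept mean acceptance statistic, or `NA`.
#' @param extra list of additional elements (step sizes, divergences,
#'   latent draws).
#' @return An object of class `posterior_samples`.
#' @export
posterior_samples <- function(draws, loglik = NULL, X_mean = NULL,
                              variant = "zip", feature_id = NA_character_,
                              rhat = NULL, accept = NA_real_, extra = list()) {
  if (!is.list(draws) || !length(draws)) stop("draws must be a nonempty list of chain matrices")
  draws <- lapply(draws, function(d) {
    d <- as.matrix(d)
    if (ncol(d) != 6L) stop("each chain matrix must have 6 parameter columns")
    colnames(d) <- par_names
    d
  })
  structure(list(draws = draws, loglik = loglik, X_mean = X_mean,
                 variant = match.arg(variant, c("zip", "poisson")),
                 feature_id = feature_id, rhat = rhat, accept = accept,
                 extra = extra),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- do.call(rbind, x$draws)
  cat(sprintf("<posterior_samples> %s (%s likelihood): %d chains x %d draws\n",
              x$feature_id, x$variant, length(x$draws), nrow(x$draws[[1]])))
  cat(sprintf("  rho: mean %.3f, 90%% CI [%.3f, %.3f]",
              mean(d[, "rho"]), quantile(d[, "rho"], 0.05), quantile(d[, "rho"], 0.95)))
  if (!is.null(x$rhat)) cat(sprintf(", max rhat %.3f", max(x$rhat)))
  cat("\n")
  invisible(x)
}

#' Pooled posterior draws of the latent correlation
#'
#' @param fit a `posterior_samples` object.
#' @return Numeric vector of rho draws pooled across chains.
#' @export
rho_draws <- function(fit) {
  unlist(lapply(fit$draws, function(d) d[, "rho"]), use.names = FALSE)
}

# Moment-based initial values on the unconstrained scale: global means
# from pooled rates, unit latent sds, zero correlation, and per-cell
# latent states at their observation-wise estimates (shrunk rates), which
# keeps the log posterior finite and starts each chain near the bulk of
# the likelihood.
initial_state <- function(data, hyper, zero_inflated) {
  mu1 <- log(mean(data$y1 / data$s) + 1e-3)
  tot <- sum(data$n)
  rate <- if (tot > 0) (sum(data$y2) + 0.5) / (tot + 1) else 0.5
  mu2 <- qnorm(min(max(rate, 1e-3), 1 - 1e-3))
  pi0 <- min(max(0.5 * mean(data$y1 == 0), 0.02), 0.9)
  x1 <- log((data$y1 + 0.5) / data$s)
  r2 <- (data$y2 + 0.5) / (data$n + 1)
  x2 <- ifelse(data$n > 0, qnorm(pmin(pmax(r2, 1e-3), 1 - 1e-3)), mu2)
  c(mu1, mu2, 0, 0, 0, if (zero_inflated) qlogis(pi0), x1, x2)
}

check_finite_at_init <- function(data, hyper, params, zero_inflated = TRUE) {
  prior_params <- params
  # under the plain-Poisson variant pi is not a model parameter; evaluate
  # the prior at an interior point so its Beta factor cannot trip the check
  if (!zero_inflated) prior_params$pi <- 0.5
  terms <- c(
    expression_likelihood = sum(zip_log_pmf(data$y1, params$X[, 1], data$s, params$pi)),
    epigenome_likelihood = {
      cov <- data$n > 0
      sum(binom_probit_log_pmf(data$y2[cov], params$X[cov, 2], data$n[cov]))
    },
    latent_density = sum(latent_log_density(params$X, params)),
    prior = log_prior(prior_params, hyper))
  bad <- names(terms)[!is.finite(terms)]
  if (length(bad))
    stop("non-finite log posterior at initialization: ", paste(bad, collapse = ", "))
  invisible(terms)
}

#' Sample the per-feature posterior with a No-U-Turn sampler
#'
#' Runs `config$n_chains` Hamiltonian chains on the unconstrained
#' parameterisation (log sigmas, atanh correlation, logit zero-inflation,
#' non-centred latent states), adapts the step size toward
#' `config$target_accept` by dual averaging during burn-in, and returns
#' post-burn-in draws with split-R-hat diagnostics. With
#' `zero_inflated = FALSE` the zero-inflation probability is fixed at 0
#' (plain Poisson expression likelihood), which is the alternative model
#' used in DIC comparisons.
#'
#' @param data a [feature_data] object.
#' @param hyper a [hyperparams] object.
#' @param config an [mcmc_config] object.
#' @param zero_inflated logical; fit the zero-inflated (default) or plain
#'   Poisson expression likelihood.
#' @return A [posterior_samples] object.
#' @export
fit_feature <- function(data, hyper = hyperparams(), config = mcmc_config(),
                        zero_inflated = TRUE) {
  stopifnot(inherits(data, "feature_data"))
  set.seed(config$seed)
  I <- length(data$y1)
  q0 <- initial_state(data, hyper, zero_inflated)
  off <- 5L + as.integer(zero_inflated)
  init_params <- feature_params(
    mu1 = q0[1], mu2 = q0[2], sigma1 = 1, sigma2 = 1, rho = 0,
    pi = if (zero_inflated) plogis(q0[6]) else 0,
    X = cbind(q0[off + seq_len(I)], q0[off + I + seq_len(I)]))
  check_finite_at_init(data, hyper, init_params, zero_inflated)

  kept <- config$n_samples - config$n_burnin
  chains <- vector("list", config$n_chains)
  logliks <- vector("list", config$n_chains)
  Xm <- matrix(0, I, 2)
  acc <- num_div <- 0
  extra <- list(step_size = numeric(config$n_chains))
  if (config$store_latent) extra$X_draws <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    qc <- q0 + rnorm(length(q0), 0, 0.1)
    res <- nuts_sample_cpp(data$y1, data$y2, data$n, data$s,
                           unclass(hyper), zero_inflated,
                           config$n_samples, config$n_burnin,
                           config$target_accept, config$max_treedepth,
                           qc, config$store_latent)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    logliks[[ch]] <- res$loglik
    Xm <- Xm + res$X_mean / config$n_chains
    acc <- acc + mean(res$accept) / config$n_chains
    num_div <- num_div + res$n_divergent
    extra$step_size[ch] <- res$step_size
    if (config$store_latent)
      extra$X_draws[[ch]] <- list(X1 = res$X1_draws, X2 = res$X2_draws)
  }
  monitored <- if (zero_inflated) par_names else par_names[1:5]
  rhat <- vapply(monitored, function(p) {
    if (config$n_chains < 2L) return(NA_real_)  # R-hat needs several chains
    m <- vapply(chains, function(d) d[, p], numeric(kept))
    gelman_rubin(as.matrix(m))
  }, numeric(1))
  extra$n_divergent <- num_div
  posterior_samples(chains, loglik = logliks, X_mean = Xm,
                    variant = if (zero_inflated) "zip" else "poisson",
                    feature_id = data$feature_id, rhat = rhat,
                    accept = acc, extra = extra)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain R-hat: each chain is split in half (when at least 4 draws
#' are available) and the classical between/within variance ratio is
#' computed on the resulting chains. Values near 1 indicate convergence;
#' values above ~1.05 flag disagreement between chains.
#'
#' @param draws matrix with one column per chain and one row per draw.
#' @param split split chains in half first (default) when long enough.
#' @return Scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(draws, split = TRUE) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L || nrow(draws) < 2L)
    stop("need at least 2 chains with at least 2 draws each")
  if (split && nrow(draws) >= 4L) {
    half <- floor(nrow(draws) / 2)
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[nrow(draws) - half + seq_len(half), , drop = FALSE])
  }
  n <- nrow(draws); m <- ncol(draws)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, var))
  B <- n * var(means)
  if (!is.finite(W) || (W <= 0 && B <= 0)) stop("degenerate chains: zero total variance")
  if (W <= 0) return(Inf)
  vplus <- (n - 1) / n * W + B / n
  sqrt(vplus / W)
}

feature_seed <- function(seed, j) {
  as.integer((as.numeric(seed) * 7919 + j) %% 2147483646) + 1L
}

#' Fit every feature of a dataset
#'
#' Features are statistically independent, so fitting parallelises
#' trivially. Each feature gets a seed derived deterministically from
#' `config$seed` and its index, making results identical whatever the
#' worker count. Individual failures are recorded and skipped.
#'
#' @param dataset a list of [feature_data] objects or an object returned
#'   by [generate_dataset()].
#' @param hyper a [hyperparams] object.
#' @param config an [mcmc_config] object.
#' @param n_workers number of parallel forked workers (1 = sequential).
#' @param zero_inflated fit the zero-inflated (default) or plain Poisson
#'   expression likelihood.
#' @return List of [posterior_samples] (failed features carry class
#'   `fit_error`), with a `failures` attribute naming failed features.
#' @export
fit_all <- function(dataset, hyper = hyperparams(), config = mcmc_config(),
                    n_workers = 1L, zero_inflated = TRUE) {
  features <- dataset_features(dataset)
  if (!length(features)) stop("empty dataset")
  fit_one <- function(j) {
    cfg <- config
    cfg$seed <- feature_seed(config$seed, j)
    tryCatch(fit_feature(features[[j]], hyper, cfg, zero_inflated),
             error = function(e) structure(
               list(feature_id = features[[j]]$feature_id,
                    message = conditionMessage(e)),
               class = "fit_error"))
  }
  idx <- seq_along(features)
  fits <- if (n_workers > 1L) {
    parallel::mclapply(idx, fit_one, mc.cores = n_workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, fit_one)
  }
  failed <- vapply(fits, inherits, logical(1), "fit_error")
  if (any(failed))
    warning(sum(failed), " feature(s) failed to fit and were skipped")
  attr(fits, "failures") <- vapply(fits[failed], `[[`, character(1), "feature_id")
  fits
}

# Accept either a bare list of feature_data or a generated dataset object.
dataset_features <- function(dataset) {
  if (inherits(dataset, "slc_dataset")) return(dataset$features)
  if (inherits(dataset, "feature_data")) return(list(dataset))
  dataset
}

#' Posterior summary table across features
#'
#' @param fits list of [posterior_samples] as returned by [fit_all()].
#' @return data.frame with per-parameter posterior mean / median / sd /
#'   5% and 95% quantiles plus the maximum split-R-hat per feature.
#' @export
posterior_summary <- function(fits) {
  fits <- Filter(function(f) inherits(f, "posterior_samples"), fits)
  rows <- lapply(fits, function(f) {
    d <- do.call(rbind, f$draws)
    stats <- lapply(par_names, function(p) {
      v <- d[, p]
      setNames(c(mean(v), median(v), sd(v), quantile(v, c(0.05, 0.95))),
               paste0(p, c("_mean", "_median", "_sd", "_q05", "_q95")))
    })
    c(list(feature_id = f$feature_id), as.list(unlist(stats)),
      list(rhat_max = if (is.null(f$rhat)) NA_real_ else max(f$rhat)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write posterior summaries as TSV
#'
#' @param fits list of [posterior_samples].
#' @param path output TSV path.
#' @return The summary data.frame, invisibly.
#' @export
write_posterior_summary <- function(fits, path) {
  s <- posterior_summary(fits)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(s)
}
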