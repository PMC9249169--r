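#' Synthetic dataset configuration
#'
#' Defaults reproduce the reference simulation grid: 300 features by 60
#' cells, latent moments `mu1 = 4, mu2 = 1, sigma1 = 3, sigma2 = 2`, a
#' 20% structural-zero rate in expression, coverage drawn uniformly on
#' \[50, 500\] (mean 275), unit scaling factors, and per-feature
#' correlations drawn from a Beta(15, 15) rescaled to \[-1, 1\].
#'
#' @param n_cells cells per feature (I).
#' @param n_features features (J).
#' @param mu1,mu2,sigma1,sigma2 latent Gaussian moments.
#' @param pi structural-zero (zero-inflation) probability for expression.
#' @param coverage_low,coverage_high inclusive integer coverage range.
#' @param rho_source `"beta"` (rescaled Beta(d1, d2) draws), `"uniform"`
#'   (Uniform on `rho_range`), or `"values"` (use `rho_values`).
#' @param rho_beta shapes of the Beta correlation source.
#' @param rho_range range of the uniform correlation source.
#' @param rho_values explicit per-feature correlations (recycled to J).
#' @param s cell scaling factors: a scalar, a length-I vector, or `NULL`
#'   for unit factors.
#' @param seed integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 60L, n_features = 300L,
                       mu1 = 4, mu2 = 1, sigma1 = 3, sigma2 = 2,
                       pi = 0.20, coverage_low = 50L, coverage_high = 500L,
                       rho_source = c("beta", "uniform", "values"),
                       rho_beta = c(15, 15), rho_range = c(-0.8, -0.6),
                       rho_values = NULL, s = NULL, seed = 1L) {
  rho_source <- match.arg(rho_source)
  if (coverage_low > coverage_high) stop("coverage_low must not exceed coverage_high")
  if (coverage_low < 0) stop("coverage must be non-negative")
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigmas must be positive")
  if (n_cells < 2L || n_features < 1L) stop("need at least 2 cells and 1 feature")
  if (rho_source == "values" && is.null(rho_values)) stop("rho_values required")
  if (!is.null(rho_values) && any(abs(rho_values) >= 1)) stop("rho_values must lie in (-1, 1)")
  if (is.null(s)) s <- 1
  if (any(s <= 0)) stop("scaling factors must be positive")
  structure(list(n_cells = as.integer(n_cells), n_features = as.integer(n_features),
                 mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 pi = pi, coverage_low = as.integer(coverage_low),
                 coverage_high = as.integer(coverage_high),
                 rho_source = rho_source, rho_beta = rho_beta,
                 rho_range = rho_range, rho_values = rho_values,
                 s = s, seed = as.integer(seed)),
            class = "sim_config")
}

draw_rhos <- function(config) {
  J <- config$n_features
  switch(config$rho_source,
         beta = 2 * rbeta(J, config$rho_beta[1], config$rho_beta[2]) - 1,
         uniform = runif(J, config$rho_range[1], config$rho_range[2]),
         values = rep_len(config$rho_values, J))
}

simulate_layers <- function(config, X1, X2, s) {
  I <- config$n_cells
  n <- sample(seq.int(config$coverage_low, config$coverage_high), I, replace = TRUE)
  y2 <- rbinom(I, n, pnorm(X2))
  structural <- runif(I) < config$pi
  lam <- pmin(s * exp(X1), 1e9)  # guard against astronomically rare overflow
  y1 <- ifelse(structural, 0, rpois(I, lam))
  list(y1 = y1, y2 = y2, n = n, structural = structural)
}

#' Generate a synthetic dataset from the generative model
#'
#' For each feature: draws a correlation from the configured source,
#' simulates latent bivariate Gaussian states across cells, then pushes
#' them through the observation models — zero-inflated Poisson with
#' exponential link for expression and Binomial-probit for the epigenome
#' layer, with coverage drawn uniformly over the configured integer
#' range. Ground truth is returned alongside the data.
#'
#' @param config a [sim_config] object.
#' @return An object of class `slc_dataset`: `features` (list of
#'   [feature_data]), `truth` (data.frame with true parameters, the
#'   per-feature count of structural zeros and the latent state moments)
#'   and the config.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  I <- config$n_cells; J <- config$n_features
  s <- rep_len(config$s, I)
  rhos <- draw_rhos(config)
  ids <- sprintf("feature_%04d", seq_len(J))
  features <- vector("list", J)
  truth <- vector("list", J)
  for (j in seq_len(J)) {
    r <- rhos[j]
    z1 <- rnorm(I); z2 <- rnorm(I)
    X1 <- config$mu1 + config$sigma1 * z1
    X2 <- config$mu2 + config$sigma2 * (r * z1 + sqrt(1 - r^2) * z2)
    obs <- simulate_layers(config, X1, X2, s)
    features[[j]] <- feature_data(ids[j], obs$y1, obs$y2, obs$n, s)
    truth[[j]] <- data.frame(
      feature_id = ids[j], rho = r, mu1 = config$mu1, mu2 = config$mu2,
      sigma1 = config$sigma1, sigma2 = config$sigma2, pi = config$pi,
      structural_zeros = sum(obs$structural),
      mean_X1 = mean(X1), sd_X1 = sd(X1),
      mean_X2 = mean(X2), sd_X2 = sd(X2),
      cor_X = cor(X1, X2), stringsAsFactors = FALSE)
  }
  structure(list(features = features, truth = do.call(rbind, truth),
                 config = config),
            class = "slc_dataset")
}

#' @export
print.slc_dataset <- function(x, ...) {
  cat(sprintf("<slc_dataset> %d features x %d cells (seed %d)\n",
              length(x$features), x$config$n_cells, x$config$seed))
  invisible(x)
}

#' Generate data with externally supplied latent expression states
#'
#' Model-mismatch scenario: the Gaussian latent expression states are
#' replaced by a supplied I x J matrix (e.g. latent means from an
#' external autoencoder fit), while the epigenome layer and both noise
#' models are unchanged. The supplied column is standardised per feature
#' so the configured correlation still couples the two layers.
#'
#' @param latent_matrix I x J matrix of latent log-expression states.
#' @param config a [sim_config] object.
#' @return An `slc_dataset`, as from [generate_dataset()].
#' @export
generate_with_external_latents <- function(latent_matrix, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  latent_matrix <- as.matrix(latent_matrix)
  if (nrow(latent_matrix) != config$n_cells || ncol(latent_matrix) != config$n_features)
    stop(sprintf("latent matrix must be %d x %d", config$n_cells, config$n_features))
  set.seed(config$seed)
  I <- config$n_cells; J <- config$n_features
  s <- rep_len(config$s, I)
  rhos <- draw_rhos(config)
  ids <- sprintf("feature_%04d", seq_len(J))
  features <- vector("list", J)
  truth <- vector("list", J)
  for (j in seq_len(J)) {
    r <- rhos[j]
    X1 <- latent_matrix[, j]
    sd1 <- sd(X1)
    z1 <- if (sd1 > 0) (X1 - mean(X1)) / sd1 else rep(0, I)
    z2 <- rnorm(I)
    X2 <- config$mu2 + config$sigma2 * (r * z1 + sqrt(1 - r^2) * z2)
    obs <- simulate_layers(config, X1, X2, s)
    features[[j]] <- feature_data(ids[j], obs$y1, obs$y2, obs$n, s)
    truth[[j]] <- data.frame(
      feature_id = ids[j], rho = r, mu1 = mean(X1), mu2 = config$mu2,
      sigma1 = sd1, sigma2 = config$sigma2, pi = config$pi,
      structural_zeros = sum(obs$structural),
      mean_X1 = mean(X1), sd_X1 = sd1,
      mean_X2 = mean(X2), sd_X2 = sd(X2),
      cor_X = if (sd1 > 0) cor(X1, X2) else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(features = features, truth = do.call(rbind, truth),
                 config = config),
            class = "slc_dataset")
}

#' Negative-control permutation of a dataset
#'
#' For each feature, the cell indices of the two layers are permuted
#' independently: expression counts travel alone, while methylated
#' counts and their coverage travel together so `y2 <= n` is never
#' broken. Per-layer marginal distributions are preserved exactly while
#' any cross-layer association is destroyed — features called significant
#' on such data are false positives.
#'
#' @param dataset an `slc_dataset` or list of [feature_data].
#' @param seed integer seed for the permutations.
#' @return A dataset of the same shape with `permuted = TRUE` recorded in
#'   its truth table (true correlation is 0 by construction).
#' @export
make_negative_control <- function(dataset, seed = 1L) {
  features <- dataset_features(dataset)
  set.seed(as.integer(seed))
  perm <- lapply(features, function(fd) {
    I <- length(fd$y1)
    p1 <- sample.int(I); p2 <- sample.int(I)
    feature_data(fd$feature_id, fd$y1[p1], fd$y2[p2], fd$n[p2], fd$s)
  })
  if (inherits(dataset, "slc_dataset")) {
    truth <- dataset$truth
    truth$rho <- 0
    truth$permuted <- TRUE
    structure(list(features = perm, truth = truth, config = dataset$config),
              class = "slc_dataset")
  } else {
    perm
  }
}
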