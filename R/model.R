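#' Per-feature paired observations across cells
#'
#' Bundles, for one genomic feature, the expression counts and the
#' epigenome counts observed in the same cells: `y1[i]` raw expression
#' reads, `y2[i]` methylated-CpG (or open-peak) counts out of `n[i]`
#' covered calls, and known positive cell scaling factors `s[i]`.
#' Cells with `n[i] = 0` carry no epigenome information and contribute
#' only through the expression likelihood.
#'
#' @param feature_id character scalar identifying the feature.
#' @param y1 non-negative integer vector of expression counts, length I.
#' @param y2 non-negative integer vector of methylated/open counts.
#' @param n non-negative integer vector of coverage; `y2 <= n` elementwise.
#' @param s positive numeric vector of cell scaling factors (default 1).
#' @return An object of class `feature_data`.
#' @export
feature_data <- function(feature_id, y1, y2, n, s = NULL) {
  I <- length(y1)
  if (is.null(s)) s <- rep(1, I)
  if (I < 2L) stop("feature_data requires at least 2 cells")
  if (length(y2) != I || length(n) != I || length(s) != I)
    stop("y1, y2, n, s must have equal length")
  if (any(y1 < 0) || any(y1 != floor(y1))) stop("y1 must be non-negative integers")
  if (any(n < 0) || any(y2 < 0)) stop("y2 and n must be non-negative")
  if (any(y2 > n)) stop("y2 must not exceed coverage n")
  if (any(s <= 0) || any(!is.finite(s))) stop("scaling factors s must be positive")
  structure(
    list(feature_id = as.character(feature_id),
         y1 = as.numeric(y1), y2 = as.numeric(y2),
         n = as.numeric(n), s = as.numeric(s)),
    class = "feature_data")
}

#' @export
print.feature_data <- function(x, ...) {
  cat(sprintf("<feature_data> %s: %d cells, %.0f%% expression zeros, mean coverage %.1f\n",
              x$feature_id, length(x$y1), 100 * mean(x$y1 == 0), mean(x$n)))
  invisible(x)
}

#' Per-feature model parameters
#'
#' The parameter vector of the hierarchical model for one feature:
#' latent means (`mu1` on the log-expression scale, `mu2` on the probit
#' scale), latent standard deviations, latent correlation `rho`, the
#' zero-inflation probability `pi`, and optionally the latent state matrix
#' `X` (I x 2).
#'
#' @param mu1,mu2 latent means.
#' @param sigma1,sigma2 positive latent standard deviations.
#' @param rho latent correlation in (-1, 1).
#' @param pi zero-inflation probability in \[0, 1\].
#' @param X optional I x 2 matrix of latent states.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(mu1, mu2, sigma1, sigma2, rho, pi, X = NULL) {
  if (sigma1 <= 0 || sigma2 <= 0) stop("sigma1 and sigma2 must be positive")
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (ncol(X) != 2L) stop("X must have two columns")
  }
  structure(list(mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
                 rho = rho, pi = pi, X = X),
            class = "feature_params")
}

#' Prior hyper-parameters
#'
#' Defaults encode weak prior information appropriate for log-scale
#' expression means around 4 and probit-scale epigenome means near `m[2]`:
#' Beta(a, b) on the zero-inflation probability (a = 2, b = 8 favours low
#' inflation), bivariate Gaussian N(m, H) on the latent means,
#' inverse-Gamma(c1, c2) on each latent standard deviation, and a Beta
#' distribution rescaled to support \[-1, 1\] on the correlation. With
#' d1 = d2 the correlation prior is symmetric about zero, so neither sign
#' is favoured a priori; d1 = d2 = 15 concentrates mass on moderate
#' correlations and suppresses spurious detections on null data.
#'
#' @param a,b Beta prior shape parameters for `pi`.
#' @param m length-2 prior mean for `(mu1, mu2)`; use `c(4, 0)` for
#'   methylation-expression pairs, `c(4, 3)` for sparse accessibility data.
#' @param H 2 x 2 positive-definite prior covariance of the means.
#' @param c1,c2 inverse-Gamma shape and scale for the standard deviations.
#' @param d1,d2 shapes of the rescaled Beta prior on the correlation.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(a = 2, b = 8, m = c(4, 0), H = diag(2),
                        c1 = 2.5, c2 = 4.5, d1 = 15, d2 = 15) {
  if (any(c(a, b, c1, c2, d1, d2) <= 0)) stop("all shape/scale hyper-parameters must be positive")
  if (length(m) != 2L) stop("m must have length 2")
  H <- as.matrix(H)
  if (!isTRUE(all.equal(H, t(H))) || any(eigen(H, only.values = TRUE)$values <= 0))
    stop("H must be symmetric positive definite")
  structure(list(a = a, b = b, m = as.numeric(m), H = H,
                 c1 = c1, c2 = c2, d1 = d1, d2 = d2),
            class = "hyperparams")
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # when both terms are -Inf the sum is -Inf
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Zero-inflated Poisson log-pmf with exponential link
#'
#' Log-probability of observing `y` expression reads given the latent
#' log-expression state `x`, scaling factor `s` and zero-inflation
#' probability `pi`. The Poisson rate is `s * exp(x)`; a zero is observed
#' either structurally (probability `pi`) or from the Poisson component.
#' Vectorised over all arguments.
#'
#' @param y non-negative integer counts.
#' @param x latent log-expression states.
#' @param s positive scaling factors.
#' @param pi zero-inflation probabilities in \[0, 1\].
#' @return Log-probabilities, same length as the recycled inputs.
#' @export
zip_log_pmf <- function(y, x, s, pi) {
  k <- max(length(y), length(x), length(s), length(pi))
  y <- rep_len(y, k); x <- rep_len(x, k); s <- rep_len(s, k); pi <- rep_len(pi, k)
  if (any(y < 0)) stop("y must be non-negative")
  if (any(s <= 0)) stop("s must be positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  lam <- s * exp(x)
  out <- log1p(-pi) + dpois(y, lam, log = TRUE)
  z <- y == 0
  if (any(z)) out[z] <- log_sum_exp(log(pi[z]), log1p(-pi[z]) - lam[z])
  out
}

#' Binomial log-pmf with probit link
#'
#' Log-probability of `y` methylated (or open) calls out of `n` covered
#' calls, with success probability `pnorm(x)`. Evaluated through the
#' normal log-CDF so it stays finite for extreme latent states. Coverage
#' `n = 0` is a vacuous observation and returns 0.
#'
#' @param y non-negative integer counts, `y <= n`.
#' @param x latent probit-scale states.
#' @param n non-negative integer coverage.
#' @return Log-probabilities.
#' @export
binom_probit_log_pmf <- function(y, x, n) {
  k <- max(length(y), length(x), length(n))
  y <- rep_len(y, k); x <- rep_len(x, k); n <- rep_len(n, k)
  if (any(y < 0) || any(y > n)) stop("require 0 <= y <= n")
  out <- y * pnorm(x, log.p = TRUE) +
    (n - y) * pnorm(x, lower.tail = FALSE, log.p = TRUE) +
    lchoose(n, y)
  out[n == 0] <- 0
  out
}

#' Bivariate Gaussian log-density of the latent state
#'
#' Density of one (or a matrix of) latent pair(s) under the feature's
#' latent Gaussian with mean `(mu1, mu2)` and covariance built from
#' `(sigma1, sigma2, rho)`.
#'
#' @param x length-2 vector or I x 2 matrix of latent states.
#' @param params a [feature_params] object.
#' @return Log-density (vector of length I for matrix input).
#' @export
latent_log_density <- function(x, params) {
  if (abs(params$rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  if (params$sigma1 <= 0 || params$sigma2 <= 0) stop("sigmas must be positive")
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  r <- params$rho
  z1 <- (x[, 1] - params$mu1) / params$sigma1
  z2 <- (x[, 2] - params$mu2) / params$sigma2
  q <- (z1^2 - 2 * r * z1 * z2 + z2^2) / (1 - r^2)
  -log(2 * pi) - log(params$sigma1) - log(params$sigma2) -
    0.5 * log1p(-r^2) - 0.5 * q
}

#' Log-density of the rescaled Beta prior on the correlation
#'
#' A Beta(d1, d2) density linearly rescaled from (0, 1) to (-1, 1):
#' `f(rho) = 0.5 * dbeta((rho + 1) / 2, d1, d2)`. With `d1 = d2` the
#' prior is symmetric about zero.
#'
#' @param rho correlation values.
#' @param d1,d2 positive shape parameters.
#' @return Log-density; `-Inf` outside \[-1, 1\].
#' @export
scaled_beta_log_pdf <- function(rho, d1, d2) {
  log(0.5) + dbeta((rho + 1) / 2, d1, d2, log = TRUE)
}

dinvgamma_log <- function(x, shape, scale) {
  ifelse(x > 0,
         shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x,
         -Inf)
}

#' Log prior density of the per-feature parameters
#'
#' Sum of the log prior densities: Beta(a, b) on `pi`, bivariate Gaussian
#' N(m, H) on the means, inverse-Gamma(c1, c2) on each standard deviation
#' and the rescaled Beta(d1, d2) on the correlation. Returns `-Inf` for
#' parameters outside their support.
#'
#' @param params a [feature_params] object.
#' @param hyper a [hyperparams] object.
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, hyper) {
  if (params$sigma1 <= 0 || params$sigma2 <= 0 ||
      abs(params$rho) >= 1 || params$pi < 0 || params$pi > 1) return(-Inf)
  Hi <- solve(hyper$H)
  dm <- c(params$mu1, params$mu2) - hyper$m
  lp_mu <- -log(2 * pi) - 0.5 * determinant(hyper$H)$modulus[1] -
    0.5 * as.numeric(t(dm) %*% Hi %*% dm)
  dbeta(params$pi, hyper$a, hyper$b, log = TRUE) + lp_mu +
    dinvgamma_log(params$sigma1, hyper$c1, hyper$c2) +
    dinvgamma_log(params$sigma2, hyper$c1, hyper$c2) +
    scaled_beta_log_pdf(params$rho, hyper$d1, hyper$d2)
}

#' Joint log posterior density (up to a constant)
#'
#' Sum over cells of the expression, epigenome and latent-Gaussian terms,
#' plus the log prior. `params$X` must be present (I x 2). Cells with
#' zero coverage contribute no epigenome term.
#'
#' @param data a [feature_data] object.
#' @param params a [feature_params] object carrying the latent matrix `X`.
#' @param hyper a [hyperparams] object.
#' @return Scalar log posterior density (unnormalised).
#' @export
joint_log_posterior <- function(data, params, hyper) {
  if (is.null(params$X)) stop("params$X (latent states) is required")
  X <- params$X
  if (nrow(X) != length(data$y1)) stop("dimension mismatch between data and latent X")
  ll1 <- sum(zip_log_pmf(data$y1, X[, 1], data$s, params$pi))
  cov <- data$n > 0
  ll2 <- sum(binom_probit_log_pmf(data$y2[cov], X[cov, 2], data$n[cov]))
  sum(latent_log_density(X, params)) + ll1 + ll2 + log_prior(params, hyper)
}
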