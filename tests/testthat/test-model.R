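# Density layer: hand-computed values, independent oracles, and
# normalization properties.

test_that("zip_log_pmf matches direct evaluation and handles edge cases", {
  # structural zero with pi = 1 is certain
  expect_identical(zip_log_pmf(0, 0, 1, 1), 0)
  # y > 0: log(1 - pi) + Poisson pmf, via an independent dpois oracle
  expect_equal(zip_log_pmf(2, log(2), 1, 0.2),
               log(0.8) + dpois(2, 2, log = TRUE))
  expect_equal(zip_log_pmf(2, log(2), 1, 0.2), -1.5300, tolerance = 1e-3)
  # y = 0 mixture branch
  expect_equal(zip_log_pmf(0, 0, 1, 0.2), log(0.2 + 0.8 * exp(-1)))
  expect_equal(zip_log_pmf(0, 0, 1, 0.2), -0.7045, tolerance = 1e-3)
  # pi = 0 reduces to plain Poisson
  expect_equal(zip_log_pmf(3, 1.2, 0.7, 0), dpois(3, 0.7 * exp(1.2), log = TRUE))
  # pi = 1 makes positive counts impossible
  expect_identical(zip_log_pmf(1, 0, 1, 1), -Inf)
  # domain errors
  expect_error(zip_log_pmf(-1, 0, 1, 0.2), "non-negative")
  expect_error(zip_log_pmf(0, 0, 0, 0.2), "positive")
  expect_error(zip_log_pmf(0, 0, 1, 1.2), "0, 1")
})

test_that("zip_log_pmf is a normalized pmf (brute-force summation)", {
  for (case in list(c(x = 0, s = 1, pi = 0.2), c(x = 2, s = 0.5, pi = 0),
                    c(x = -1, s = 3, pi = 0.9), c(x = 3, s = 1, pi = 0.5))) {
    total <- sum(exp(zip_log_pmf(0:1000, case["x"], case["s"], case["pi"])))
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("binom_probit_log_pmf matches direct evaluation and is stable", {
  expect_equal(binom_probit_log_pmf(1, 0, 2), log(0.5))
  expect_identical(binom_probit_log_pmf(0, 137.2, 0), 0)  # vacuous coverage
  expect_equal(binom_probit_log_pmf(2, 1, 3),
               log(3 * pnorm(1)^2 * (1 - pnorm(1))))
  expect_equal(binom_probit_log_pmf(2, 1, 3), -1.0877, tolerance = 1e-3)
  # log-CDF formulation keeps extreme latent states finite
  expect_true(is.finite(binom_probit_log_pmf(0, 12, 50)))
  expect_true(is.finite(binom_probit_log_pmf(50, -12, 50)))
  expect_error(binom_probit_log_pmf(3, 0, 2), "y <= n")
  expect_error(binom_probit_log_pmf(-1, 0, 2), "y <= n")
})

test_that("binom_probit_log_pmf is normalized for n up to 30", {
  for (x in c(-2, -0.3, 0, 1.5)) {
    for (n in c(1, 7, 30)) {
      total <- sum(exp(binom_probit_log_pmf(0:n, x, n)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("latent_log_density matches the closed-form bivariate normal", {
  std <- feature_params(0, 0, 1, 1, rho = 0, pi = 0)
  expect_equal(latent_log_density(c(0, 0), std), -log(2 * pi))
  half <- feature_params(0, 0, 1, 1, rho = 0.5, pi = 0)
  expect_equal(latent_log_density(c(0, 0), half), -log(2 * pi) - 0.5 * log(0.75))
  # rho = 0 factorizes into two univariate normals
  set.seed(4)
  X <- matrix(rnorm(20), ncol = 2)
  p <- feature_params(0.5, -1, 2, 0.7, rho = 0, pi = 0)
  expect_equal(latent_log_density(X, p),
               dnorm(X[, 1], 0.5, 2, log = TRUE) + dnorm(X[, 2], -1, 0.7, log = TRUE))
  expect_error(feature_params(0, 0, 1, 1, rho = 1, pi = 0), "strictly inside")
})

test_that("scaled Beta prior on rho is proper, centered and symmetric", {
  f <- function(r) exp(scaled_beta_log_pdf(r, 15, 15))
  expect_equal(integrate(f, -1, 1, rel.tol = 1e-10)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(function(r) r * f(r), -1, 1)$value, 0, tolerance = 1e-8)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(scaled_beta_log_pdf(r, 15, 15), scaled_beta_log_pdf(-r, 15, 15))
  expect_equal(exp(scaled_beta_log_pdf(0, 15, 15)), 0.5 * dbeta(0.5, 15, 15))
  expect_identical(scaled_beta_log_pdf(1.5, 15, 15), -Inf)
})

test_that("log_prior sums the component densities and respects support", {
  hy <- hyperparams()
  p <- feature_params(3.5, 0.2, 2, 1.5, rho = 0.3, pi = 0.15)
  manual <- dbeta(0.15, 2, 8, log = TRUE) +
    dnorm(3.5, 4, 1, log = TRUE) + dnorm(0.2, 0, 1, log = TRUE) +
    (2.5 * log(4.5) - lgamma(2.5) - 3.5 * log(2) - 4.5 / 2) +
    (2.5 * log(4.5) - lgamma(2.5) - 3.5 * log(1.5) - 4.5 / 1.5) +
    log(0.5) + dbeta(0.65, 15, 15, log = TRUE)
  expect_equal(log_prior(p, hy), manual)
  bad <- p; bad$rho <- 1.5
  expect_identical(log_prior(bad, hy), -Inf)
  bad2 <- p; bad2$sigma1 <- -1
  expect_identical(log_prior(bad2, hy), -Inf)
})

test_that("joint_log_posterior equals a term-by-term oracle and is exchangeable", {
  set.seed(11)
  I <- 8
  fd <- toy_feature(seed = 3, I = I)
  X <- cbind(rnorm(I, 4, 1), rnorm(I, 1, 1))
  p <- feature_params(4.2, 0.8, 2.5, 1.8, rho = 0.4, pi = 0.25, X = X)
  hy <- hyperparams()
  # independent re-evaluation: plain R densities, no package log-pmfs
  oracle <- log_prior(p, hy)
  for (i in seq_len(I)) {
    lam <- fd$s[i] * exp(X[i, 1])
    lik <- (1 - p$pi) * dpois(fd$y1[i], lam)
    if (fd$y1[i] == 0) lik <- lik + p$pi
    oracle <- oracle + log(lik)
    if (fd$n[i] > 0)
      oracle <- oracle + dbinom(fd$y2[i], fd$n[i], pnorm(X[i, 2]), log = TRUE)
    S <- matrix(c(p$sigma1^2, p$rho * p$sigma1 * p$sigma2,
                  p$rho * p$sigma1 * p$sigma2, p$sigma2^2), 2)
    d <- X[i, ] - c(p$mu1, p$mu2)
    oracle <- oracle - log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
      0.5 * as.numeric(t(d) %*% solve(S) %*% d)
  }
  expect_equal(joint_log_posterior(fd, p, hy), as.numeric(oracle))

  # invariance under a simultaneous permutation of the cell index
  perm <- sample(I)
  fd2 <- feature_data(fd$feature_id, fd$y1[perm], fd$y2[perm], fd$n[perm], fd$s[perm])
  p2 <- p; p2$X <- X[perm, ]
  expect_equal(joint_log_posterior(fd2, p2, hy), joint_log_posterior(fd, p, hy))

  # dimension mismatch
  p3 <- p; p3$X <- X[1:4, ]
  expect_error(joint_log_posterior(fd, p3, hy), "mismatch")
})

test_that("zero-count expression likelihood is monotone in pi", {
  pis <- seq(0, 0.95, by = 0.05)
  vals <- zip_log_pmf(rep(0, length(pis)), x = 0.5, s = 1, pi = pis)
  expect_true(all(diff(vals) >= 0))
})

test_that("compiled log posterior agrees with the R reference", {
  # holding (sigma, rho, pi) fixed, differences of the joint log posterior
  # over (mu, X) must agree between the C++ sampling target and the R
  # densities (the additive constants and transform Jacobians cancel)
  set.seed(21)
  I <- 6
  fd <- toy_feature(seed = 5, I = I)
  hy <- hyperparams()
  hyl <- unclass(hy)
  make_q <- function(mu, X) c(mu, log(2), log(1.5), atanh(0.3), qlogis(0.2),
                              X[, 1], X[, 2])
  make_p <- function(mu, X) feature_params(mu[1], mu[2], 2, 1.5, 0.3, 0.2, X = X)
  lp_cpp <- function(mu, X) {
    scLatentCor:::logpost_cpp(make_q(mu, X), fd$y1, fd$y2, fd$n, fd$s, hyl, TRUE)
  }
  pts <- replicate(4, list(mu = rnorm(2, c(4, 1), 0.5),
                           X = cbind(rnorm(I, 4, 2), rnorm(I, 1, 1))),
                   simplify = FALSE)
  ref <- sapply(pts, function(pt) joint_log_posterior(fd, make_p(pt$mu, pt$X), hy))
  cpp <- sapply(pts, function(pt) lp_cpp(pt$mu, pt$X))
  expect_equal(diff(cpp), diff(ref), tolerance = 1e-8)
})
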