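#' Decision rule configuration
#'
#' @param gamma minimum correlation of interest in (0, 1), or `"auto"` to
#'   calibrate it from negative-control fits.
#' @param target_efdr expected false discovery rate target (default 10%).
#' @param gamma_quantile quantile of negative-control posterior-median
#'   `|rho|` used when `gamma = "auto"`.
#' @param alpha_grid_step grid resolution of the probability-threshold
#'   search.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(gamma = "auto", target_efdr = 0.10,
                            gamma_quantile = 0.90, alpha_grid_step = 0.001) {
  if (!identical(gamma, "auto")) {
    gamma <- as.numeric(gamma)
    if (is.na(gamma) || gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1) or be 'auto'")
  }
  if (target_efdr <= 0 || target_efdr >= 1) stop("target_efdr must lie in (0, 1)")
  if (alpha_grid_step <= 0) stop("alpha_grid_step must be positive")
  structure(list(gamma = gamma, target_efdr = target_efdr,
                 gamma_quantile = gamma_quantile,
                 alpha_grid_step = alpha_grid_step),
            class = "decision_config")
}

#' Tail posterior probability of a strong correlation
#'
#' Monte-Carlo estimate of `P(|rho| >= gamma)` from posterior draws: the
#' fraction of draws whose absolute value reaches the minimum correlation
#' of interest.
#'
#' @param rho_draws numeric vector of posterior correlation draws.
#' @param gamma threshold in (0, 1).
#' @return Value in \[0, 1\].
#' @export
tail_prob <- function(rho_draws, gamma) {
  if (!length(rho_draws)) stop("empty draw vector")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  mean(abs(rho_draws) >= gamma)
}

#' Calibrate the minimum correlation of interest on negative controls
#'
#' Takes per-feature posterior estimates of `|rho|` obtained on
#' negative-control (permuted) data — correlations expected purely by
#' chance at the given sample size and depth — and returns their stated
#' quantile under the nearest-rank-above convention: the smallest value
#' with at least `quantile * n` values at or below it.
#'
#' @param negctrl_abs_rho numeric vector of per-feature posterior-median
#'   `|rho|` estimates from negative-control fits (at least 10).
#' @param quantile quantile level in (0, 1\].
#' @return The calibrated gamma.
#' @export
choose_gamma <- function(negctrl_abs_rho, quantile = 0.90) {
  n <- length(negctrl_abs_rho)
  if (!n) stop("empty negative-control estimates")
  if (n < 10L) warning("fewer than 10 negative-control features; gamma calibration is unstable")
  sorted <- sort(negctrl_abs_rho)
  sorted[max(1L, ceiling(quantile * n))]
}

#' Expected false discovery rate at a probability threshold
#'
#' Average posterior probability of a false call among features passing
#' the threshold: `sum((1 - p_j) * [p_j >= alpha]) / sum([p_j >= alpha])`.
#' Defined as 0 when no feature passes (empty-set convention).
#'
#' @param tail_probs per-feature tail probabilities in \[0, 1\].
#' @param alpha probability threshold.
#' @return EFDR value in \[0, 1\].
#' @export
efdr <- function(tail_probs, alpha) {
  pass <- tail_probs >= alpha
  if (!any(pass)) return(0)
  mean(1 - tail_probs[pass])
}

#' Grid search for the probability threshold under an EFDR target
#'
#' Scans `alpha` over `{0, step, 2 step, ..., 1}` and returns the smallest
#' value whose discovery set is nonempty and whose EFDR does not exceed
#' the target — maximising discoveries under EFDR control. If no such
#' threshold exists, returns 1 with a warning (zero discoveries).
#'
#' @param tail_probs per-feature tail probabilities.
#' @param target_efdr EFDR target in (0, 1).
#' @param grid_step grid resolution.
#' @return The selected alpha.
#' @export
calibrate_alpha <- function(tail_probs, target_efdr = 0.10, grid_step = 0.001) {
  if (!length(tail_probs)) stop("empty tail probability vector")
  grid <- seq(0, 1, by = grid_step)
  for (alpha in grid) {
    if (!any(tail_probs >= alpha)) next
    # tiny slack so that an EFDR exactly at the target is accepted despite
    # floating-point representation of the grid
    if (efdr(tail_probs, alpha) <= target_efdr + 1e-12) return(alpha)
  }
  warning("no probability threshold attains the EFDR target; no discoveries")
  1
}

#' Call significant correlations from posterior fits
#'
#' Assembles the full decision rule: fixes or calibrates the minimum
#' correlation of interest `gamma` (the latter from negative-control
#' fits), computes per-feature tail probabilities, grid-searches the
#' probability threshold `alpha` under the EFDR target, and reports
#' calls. A feature is significant when its tail probability reaches
#' `alpha`.
#'
#' @param posteriors list of [posterior_samples].
#' @param negctrl_posteriors list of [posterior_samples] fitted on
#'   negative-control data; required when `config$gamma == "auto"`.
#' @param config a [decision_config] object.
#' @param estimate `"median"` (default) or `"mean"`: the posterior summary
#'   of `|rho|` used for gamma calibration.
#' @return An object of class `decision_result`: a data.frame of
#'   per-feature results plus `gamma`, `alpha` and achieved EFDR.
#' @export
decide <- function(posteriors, negctrl_posteriors = NULL,
                   config = decision_config(), estimate = c("median", "mean")) {
  estimate <- match.arg(estimate)
  posteriors <- Filter(function(f) inherits(f, "posterior_samples"), posteriors)
  if (!length(posteriors)) stop("no posterior fits supplied")
  gamma <- config$gamma
  if (identical(gamma, "auto")) {
    if (is.null(negctrl_posteriors))
      stop("gamma = 'auto' requires negative-control posterior fits")
    negctrl_posteriors <- Filter(function(f) inherits(f, "posterior_samples"),
                                 negctrl_posteriors)
    absr <- vapply(negctrl_posteriors, function(f) {
      v <- abs(rho_draws(f))
      if (estimate == "median") median(v) else mean(v)
    }, numeric(1))
    gamma <- choose_gamma(absr, config$gamma_quantile)
  }
  p <- vapply(posteriors, function(f) tail_prob(rho_draws(f), gamma), numeric(1))
  alpha <- calibrate_alpha(p, config$target_efdr, config$alpha_grid_step)
  table <- data.frame(
    feature_id = vapply(posteriors, `[[`, character(1), "feature_id"),
    posterior_median_rho = vapply(posteriors, function(f) median(rho_draws(f)), numeric(1)),
    tail_prob = p,
    significant = as.integer(p >= alpha),
    stringsAsFactors = FALSE)
  structure(list(table = table, gamma = gamma, alpha = alpha,
                 efdr = efdr(p, alpha), target_efdr = config$target_efdr),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf("<decision_result> %d features, %d significant\n",
              nrow(x$table), sum(x$table$significant)))
  cat(sprintf("  gamma = %.4f, alpha = %.4f, achieved EFDR = %.4f (target %.2f)\n",
              x$gamma, x$alpha, x$efdr, x$target_efdr))
  invisible(x)
}

#' Write decision results (TSV table + JSON run metadata)
#'
#' @param result a `decision_result`.
#' @param path output TSV path; a `.json` sidecar with gamma, alpha and
#'   achieved EFDR is written next to it.
#' @return `result`, invisibly.
#' @export
write_decision <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(gamma = result$gamma, alpha = result$alpha,
               efdr = result$efdr, target_efdr = result$target_efdr,
               n_significant = sum(result$table$significant))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(result)
}
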