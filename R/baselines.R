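#' Frequentist baseline configuration
#'
#' @param u interval-null threshold on the absolute correlation; `u = 0`
#'   gives the standard two-sided test of no correlation.
#' @param fdr Benjamini-Hochberg FDR level for calls.
#' @param pseudocount added before log-transforming normalised expression.
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(u = 0, fdr = 0.10, pseudocount = 1) {
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  structure(list(u = u, fdr = fdr, pseudocount = pseudocount),
            class = "baseline_config")
}

#' Normalise a feature for correlation-based analysis
#'
#' Expression counts are divided by the cell scaling factor and
#' log-transformed after adding a pseudocount; methylation/accessibility
#' is normalised by coverage. Cells without coverage carry no rate
#' estimate and are dropped pairwise.
#'
#' @param data a [feature_data] object.
#' @param pseudocount pseudocount for the log transform.
#' @return Two-column matrix (`expr`, `rate`) with one row per covered cell.
#' @export
normalize_for_baseline <- function(data, pseudocount = 1) {
  keep <- data$n > 0
  if (!any(keep)) stop("all cells have zero coverage; nothing to correlate")
  cbind(expr = log(pseudocount + data$y1[keep] / data$s[keep]),
        rate = data$y2[keep] / data$n[keep])
}

#' Pearson or Spearman sample correlation
#'
#' Spearman is Pearson applied to midranks; ties receive average ranks,
#' which is what erodes Spearman's power when both layers are dominated
#' by zeros.
#'
#' @param pairs two-column matrix of paired observations.
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation in \[-1, 1\].
#' @export
correlate <- function(pairs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3L) stop("need at least 3 complete pairs")
  if (var(pairs[, 1]) == 0 || var(pairs[, 2]) == 0)
    stop("undefined correlation: zero variance in one coordinate")
  cor(pairs[, 1], pairs[, 2], method = method)
}

#' Interval-null correlation test via the Fisher z transform
#'
#' Tests `H0: |r| <= u` against `H1: |r| > u` using
#' `z = atanh(r)`, `se = 1 / sqrt(n - 3)`: the p-value is
#' `P(|Z| >= (|z| - atanh(u)) / se)`, set to 1 whenever `|r| <= u`.
#' With `u = 0` this is the standard two-sided Fisher-z test.
#'
#' @param r sample correlation.
#' @param n_obs number of paired observations (at least 4).
#' @param u interval-null threshold.
#' @return p-value.
#' @export
correlation_test <- function(r, n_obs, u = 0) {
  if (n_obs < 4L) stop("need at least 4 observations")
  if (abs(r) >= 1) return(0)
  if (abs(r) <= u) return(1)
  z <- (atanh(abs(r)) - atanh(u)) * sqrt(n_obs - 3)
  2 * pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @return Monotone adjusted q-values capped at 1, in input order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * pvals[o]))
  q[order(o)]
}

#' Run the Pearson/Spearman baseline over a dataset
#'
#' For every feature: normalise, compute both correlations, test each
#' against the interval null and adjust with Benjamini-Hochberg across
#' features. Features where the correlation is undefined (zero variance
#' or too few covered cells) get `NA` estimates and p-value 1.
#'
#' @param dataset list of [feature_data] or a generated dataset.
#' @param config a [baseline_config] object.
#' @return data.frame with columns `feature_id`, `r_pearson`,
#'   `r_spearman`, `p_pearson`, `p_spearman`, `q_pearson`, `q_spearman`,
#'   `sig_pearson`, `sig_spearman`.
#' @export
baseline_correlations <- function(dataset, config = baseline_config()) {
  features <- dataset_features(dataset)
  one <- function(fd) {
    out <- list(feature_id = fd$feature_id, r_pearson = NA_real_,
                r_spearman = NA_real_, p_pearson = 1, p_spearman = 1)
    ok <- tryCatch({
      pairs <- normalize_for_baseline(fd, config$pseudocount)
      n_obs <- nrow(pairs)
      if (n_obs >= 4L && var(pairs[, 1]) > 0 && var(pairs[, 2]) > 0) {
        out$r_pearson <- correlate(pairs, "pearson")
        out$r_spearman <- correlate(pairs, "spearman")
        out$p_pearson <- correlation_test(out$r_pearson, n_obs, config$u)
        out$p_spearman <- correlation_test(out$r_spearman, n_obs, config$u)
      }
      TRUE
    }, error = function(e) FALSE)
    out
  }
  rows <- lapply(features, one)
  res <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  res$q_pearson <- bh_adjust(res$p_pearson)
  res$q_spearman <- bh_adjust(res$p_spearman)
  res$sig_pearson <- as.integer(res$q_pearson <= config$fdr)
  res$sig_spearman <- as.integer(res$q_spearman <= config$fdr)
  res
}
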