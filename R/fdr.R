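# False-discovery-rate machinery: Storey q-values with smoothed pi0
# estimation, the FDR-equivalent p-value threshold, and Bonferroni
# helpers. By default FDR is computed over the pooled set of all
# phenotype x SNP p-values of a scan (one genome-wide threshold for all
# phenotypes); callers wanting per-phenotype FDR simply pass per-phenotype
# slices.

#' Storey q-values
#'
#' pi0 is estimated from the lambda grid 0.05..0.95 (step 0.05) by a
#' cubic smoothing spline evaluated at the largest lambda, clamped to
#' (0, 1]; for small inputs (< 100 p-values) or a failed spline fit the
#' conservative pi0 = 1 is used with a warning. q-values are
#' `pi0 * min_{j: p_j >= p_i} (m * p_j / rank(p_j))`, i.e. pi0 times the
#' Benjamini-Hochberg adjustment.
#'
#' @param pvalues vector of p-values in (0, 1].
#' @param lambda grid for pi0 estimation.
#' @param pi0 optional fixed pi0 (e.g. 1 to reproduce plain BH).
#' @return list of class `qvalue_result`: `pvalues`, `qvalues`, `pi0`,
#'   `lambda`.
#' @export
estimate_qvalues <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05),
                             pi0 = NULL) {
  m <- length(pvalues)
  if (m == 0) stop("empty p-value vector")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) {
    if (m < 100) {
      warning("fewer than 100 p-values; using conservative pi0 = 1")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l), 0)
      pi0 <- tryCatch({
        fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
        stats::predict(fit, x = max(lambda))$y
      }, error = function(e) {
        warning("pi0 spline fit failed; using conservative pi0 = 1")
        1
      })
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  o <- order(pvalues, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- cummin(pi0 * m * pvalues[o] / rank(pvalues, ties.method = "max")[o])
  q <- pmin(q, 1)
  out <- list(pvalues = pvalues, qvalues = q, pi0 = pi0, lambda = lambda)
  class(out) <- "qvalue_result"
  out
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("qvalue_result: %d tests, pi0 = %.3f, %d with q <= 0.05\n",
              length(x$pvalues), x$pi0, sum(x$qvalues <= 0.05)))
  invisible(x)
}

#' P-value threshold equivalent to an FDR level
#'
#' The largest observed p whose q-value is at or below `level` — the
#' "genome-wide p cutoff corresponding to the FDR" that scan reports
#' quote. Returns 0 when nothing is significant.
#'
#' @param pvalues vector of p-values.
#' @param level FDR level in (0, 1).
#' @param pi0 optional fixed pi0 passed to [estimate_qvalues()].
#' @return scalar threshold.
#' @export
pvalue_threshold_at_fdr <- function(pvalues, level, pi0 = NULL) {
  stopifnot(level > 0, level < 1)
  q <- estimate_qvalues(pvalues, pi0 = pi0)$qvalues
  hit <- pvalues[q <= level]
  if (length(hit) == 0) 0 else max(hit)
}

#' Bonferroni p-value threshold
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error level.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Expected false positives among FDR-controlled discoveries
#' @param n_significant number of discoveries.
#' @param fdr_level FDR level they were called at.
#' @return `round(n_significant * fdr_level)` for reporting.
#' @export
expected_false_positives <- function(n_significant, fdr_level) {
  stopifnot(n_significant >= 0, fdr_level >= 0)
  round(n_significant * fdr_level)
}
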