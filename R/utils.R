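#' Derive a labelled random seed from a master seed
#'
#' Each stochastic generator in the package draws its own seed from the
#' master seed plus a purpose label, so adding a new generator does not
#' shift the random stream of the existing ones.
#'
#' @param seed master integer seed.
#' @param label character purpose label (e.g. `"genotypes"`).
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003L
  as.integer((abs(seed) %% 1000003L) * 1009L + h) %% .Machine$integer.max
}

#' Genomic-control inflation factor
#'
#' Median of the 1-df chi-square quantiles implied by a set of p-values,
#' divided by the null median. Values near 1 indicate calibrated tests
#' under the null; values well above 1 indicate inflation, typically from
#' uncorrected population structure.
#'
#' @param p vector of p-values.
#' @return scalar lambda.
#' @export
lambda_gc <- function(p) {
  p <- p[is.finite(p)]
  stopifnot(length(p) > 0)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

# Order index over (chrom, pos[, id]) with numeric-aware chromosome labels
# ("2" before "10", "X" after numbers).
.chrom_order <- function(chrom, pos, id = NULL) {
  cn <- suppressWarnings(as.numeric(chrom))
  cn[is.na(cn)] <- Inf
  if (is.null(id)) order(cn, as.character(chrom), pos)
  else order(cn, as.character(chrom), pos, id)
}

.stop_parse <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' (line %d): %s", path, line, msg),
       call. = FALSE)
}

# p-value floor keeping -log10(p) finite
.P_FLOOR <- 1e-300
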