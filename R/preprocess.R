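# Sample-level metabolite tables -> strain-level standardized z-score
# matrix consumed by the association scan.
#
# Fixed stage order, recorded in provenance:
#   missingness filter -> run-day median registration -> replicate
#   averaging -> per-variable z-scoring.
# Missingness is assessed over profiled samples (before averaging); the
# run-day median pools all nonmissing cells of the run-day across
# variables; the sample standard deviation uses the n-1 denominator; no
# imputation anywhere (downstream analyses use casewise deletion).

#' Drop variables with too many missing samples
#'
#' Removes variables whose missing fraction across samples is strictly
#' greater than `max_frac` (default 20%, so a variable at exactly 20% is
#' retained).
#'
#' @param table sample-level [phenotype_table()].
#' @param max_frac maximum tolerated missing fraction.
#' @return filtered `phenotype_table`; dropped variable ids are recorded
#'   in the `provenance` attribute.
#' @export
filter_by_missingness <- function(table, max_frac = 0.20) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  frac <- colMeans(is.na(table$values))
  drop <- table$variables[frac > max_frac]
  keep <- setdiff(table$variables, drop)
  out <- phenotype_table(table$values[, keep, drop = FALSE],
                         table$strain_of_sample,
                         class_of_variable = table$class_of_variable[keep],
                         runday_of_sample = table$runday_of_sample)
  attr(out, "provenance") <- c(attr(table, "provenance"), list(
    missingness_filter = list(max_frac = max_frac, dropped = drop)))
  out
}

#' Register every run-day median to one
#'
#' Within each run-day, every value is divided by that run-day's median
#' computed over all nonmissing cells of the run-day (pooled across
#' variables), then each data point is carried proportionately. Exactly
#' removes a multiplicative per-run-day batch effect.
#'
#' @param table sample-level [phenotype_table()] with run-day labels.
#' @return normalized `phenotype_table` (each run-day's pooled median
#'   equals 1).
#' @export
normalize_run_days <- function(table) {
  if (is.null(table$runday_of_sample))
    stop("normalize_run_days requires run-day labels")
  v <- table$values
  for (day in unique(table$runday_of_sample)) {
    rows <- which(table$runday_of_sample == day)
    cells <- v[rows, , drop = FALSE]
    if (all(is.na(cells)))
      stop(sprintf("run-day '%s' has no nonmissing cells", day))
    med <- stats::median(cells, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
      stop(sprintf("run-day '%s' has non-positive median (%g)", day, med))
    v[rows, ] <- cells / med
  }
  out <- phenotype_table(v, table$strain_of_sample,
                         class_of_variable = table$class_of_variable,
                         runday_of_sample = table$runday_of_sample)
  attr(out, "provenance") <- c(attr(table, "provenance"),
                               list(runday_normalization = TRUE))
  out
}

#' Average replicate mice within strains
#'
#' Collapses the table to one row per strain; each cell is the mean over
#' nonmissing replicate samples and is missing only if every replicate is
#' missing. Run-day labels do not survive the collapse.
#'
#' @param table sample-level [phenotype_table()].
#' @return strain-level `phenotype_table` (sample ids are strain ids).
#' @export
average_strain_replicates <- function(table) {
  strains <- unique(unname(table$strain_of_sample))
  v <- matrix(NA_real_, length(strains), length(table$variables),
              dimnames = list(strains, table$variables))
  for (s in strains) {
    rows <- table$values[table$strain_of_sample == s, , drop = FALSE]
    m <- colMeans(rows, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    v[s, ] <- m
  }
  out <- phenotype_table(v, strains,
                         class_of_variable = table$class_of_variable)
  attr(out, "provenance") <- c(attr(table, "provenance"),
                               list(replicate_averaging = TRUE))
  out
}

#' Z-score every variable
#'
#' z = (value - mean) / sd with the sample (n-1) standard deviation,
#' computed over nonmissing values; missing stays missing.
#'
#' @param table strain-level [phenotype_table()].
#' @return object of class `standardized_phenotype`: fields `strain_ids`,
#'   `variables`, `zvalues` (strains x variables), `class_of_variable`,
#'   `provenance`.
#' @export
standardize <- function(table) {
  z <- table$values
  for (j in seq_along(table$variables)) {
    x <- z[, j]
    nn <- sum(!is.na(x))
    if (nn < 2)
      stop(sprintf("variable '%s' has fewer than 2 nonmissing values",
                   table$variables[j]))
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop(sprintf("variable '%s' has zero variance", table$variables[j]))
    z[, j] <- (x - mean(x, na.rm = TRUE)) / s
  }
  out <- list(strain_ids = unname(table$strain_of_sample),
              variables = table$variables,
              zvalues = z,
              class_of_variable = table$class_of_variable,
              provenance = c(attr(table, "provenance"),
                             list(standardized = TRUE)))
  rownames(out$zvalues) <- out$strain_ids
  class(out) <- "standardized_phenotype"
  out
}

#' @export
print.standardized_phenotype <- function(x, ...) {
  cat(sprintf("standardized_phenotype: %d strains x %d variables\n",
              length(x$strain_ids), length(x$variables)))
  invisible(x)
}

#' Full preprocessing chain
#'
#' Missingness filter, run-day registration (skipped when the table has no
#' run-day labels), replicate averaging, z-scoring.
#'
#' @param table sample-level [phenotype_table()].
#' @param max_missing maximum missing fraction per variable.
#' @return `standardized_phenotype`.
#' @export
preprocess_phenotypes <- function(table, max_missing = 0.20) {
  t1 <- filter_by_missingness(table, max_missing)
  t2 <- if (is.null(t1$runday_of_sample)) t1 else normalize_run_days(t1)
  standardize(average_strain_replicates(t2))
}

#' Within-replicate versus panel variance summary
#'
#' Compares, per variable, the variance among replicate samples of one
#' designated strain (non-genetic variability) with the variance across
#' strain means in the whole panel (genetic plus non-genetic). Large
#' panel-to-replicate ratios indicate genetic control of the variables.
#'
#' @param table sample-level [phenotype_table()] (typically run-day
#'   normalized).
#' @param replicate_strain strain with >= 2 replicate samples.
#' @return list with `mean_within`, `median_within`, `mean_panel`,
#'   `median_panel`, `ratio_mean`, `ratio_median` and the per-variable
#'   variance vectors.
#' @export
replicate_variance_summary <- function(table, replicate_strain) {
  rows <- which(table$strain_of_sample == replicate_strain)
  if (length(rows) < 2)
    stop("designated replicate strain needs at least 2 samples")
  vw <- apply(table$values[rows, , drop = FALSE], 2, stats::var, na.rm = TRUE)
  panel <- average_strain_replicates(table)
  vp <- apply(panel$values, 2, stats::var, na.rm = TRUE)
  list(mean_within = mean(vw, na.rm = TRUE),
       median_within = stats::median(vw, na.rm = TRUE),
       mean_panel = mean(vp, na.rm = TRUE),
       median_panel = stats::median(vp, na.rm = TRUE),
       ratio_mean = mean(vp, na.rm = TRUE) / mean(vw, na.rm = TRUE),
       ratio_median = stats::median(vp, na.rm = TRUE) /
         stats::median(vw, na.rm = TRUE),
       within = vw, panel = vp)
}

#' Add log-ratio phenotypes to a sample-level table
#'
#' For each requested pair (a, b) adds a variable `a/b` equal to
#' `log(a) - log(b)` of the (positive, run-day-normalized) abundances.
#' Ratio phenotypes then flow through averaging/standardization and the
#' scan like any metabolite.
#'
#' @param table sample-level [phenotype_table()] with positive abundances.
#' @param pairs data.frame with columns `a`, `b` (variable ids).
#' @return `phenotype_table` with the ratio variables appended (class
#'   label `"Ratio"`).
#' @export
add_ratio_phenotypes <- function(table, pairs) {
  stopifnot(all(c("a", "b") %in% colnames(pairs)))
  v <- table$values
  if (any(v <= 0, na.rm = TRUE))
    stop("ratio phenotypes need strictly positive abundances")
  add <- sapply(seq_len(nrow(pairs)), function(i)
    log(v[, pairs$a[i]]) - log(v[, pairs$b[i]]))
  colnames(add) <- paste0(pairs$a, "/", pairs$b)
  cls <- table$class_of_variable
  if (!is.null(cls))
    cls <- c(cls, stats::setNames(rep("Ratio", nrow(pairs)), colnames(add)))
  phenotype_table(cbind(v, add), table$strain_of_sample,
                  class_of_variable = cls,
                  runday_of_sample = table$runday_of_sample)
}
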