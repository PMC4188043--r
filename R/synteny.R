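# Cross-species replication: map a mouse locus through a supplied synteny
# map (synteny is consumed, never computed) and test whether a human GWAS
# summary carries a sub-Bonferroni p-value for the same metabolite inside
# any mapped interval. Metabolite identity across species comes from an
# explicit two-column id map; no name fuzzy-matching.

#' Human intervals syntenic to a mouse interval
#'
#' Returns the whole mapped human interval of every synteny record
#' overlapping (inclusively) the mouse interval; an interval straddling
#' two blocks returns both.
#'
#' @param mouse_interval list or single-row data.frame with `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param synteny_map 6-column synteny data.frame (see
#'   [read_synteny_map()]).
#' @return data.frame `human_chrom, human_start, human_end` (zero rows if
#'   no overlap).
#' @export
map_to_syntenic_intervals <- function(mouse_interval, synteny_map) {
  stopifnot(mouse_interval$start <= mouse_interval$end)
  hit <- synteny_map$mouse_chrom == as.character(mouse_interval$chrom) &
    synteny_map$mouse_start <= mouse_interval$end &
    synteny_map$mouse_end >= mouse_interval$start
  synteny_map[hit, c("human_chrom", "human_start", "human_end"),
              drop = FALSE]
}

#' Replication test of one mouse locus in a human GWAS summary
#'
#' Threshold is `alpha / n_loci_tested` (Bonferroni over the loci carried
#' into the comparison). The minimum p among the metabolite's records
#' falling inside any mapped interval is taken per population; the locus
#' replicates if that minimum is at or below the threshold in at least
#' one population. A metabolite absent from the human table returns
#' `replicated = FALSE` with `measured = FALSE`.
#'
#' @param human_summary data.frame `metabolite_id, human_chrom,
#'   human_pos, p_value, population` (already on the human metabolite
#'   identifier).
#' @param metabolite_id human metabolite identifier of the locus.
#' @param human_intervals data.frame from [map_to_syntenic_intervals()].
#' @param n_loci_tested loci in the comparison (Bonferroni denominator).
#' @param alpha family-wise level (default 0.05).
#' @return list of class `replication_result`: `metabolite_id`,
#'   `threshold`, `measured`, `replicated`, `populations_supporting`,
#'   `min_p_by_population` (named vector, NA when no record falls in an
#'   interval).
#' @export
replication_test <- function(human_summary, metabolite_id, human_intervals,
                             n_loci_tested, alpha = 0.05) {
  threshold <- bonferroni_threshold(n_loci_tested, alpha)
  rec <- human_summary[human_summary$metabolite_id == metabolite_id, ,
                       drop = FALSE]
  if (nrow(rec) == 0) {
    out <- list(metabolite_id = metabolite_id, threshold = threshold,
                measured = FALSE, replicated = FALSE,
                populations_supporting = 0L,
                min_p_by_population = stats::setNames(numeric(0), character(0)))
    class(out) <- "replication_result"
    return(out)
  }
  inside <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(human_intervals)))
    inside <- inside |
      (rec$human_chrom == human_intervals$human_chrom[i] &
         rec$human_pos >= human_intervals$human_start[i] &
         rec$human_pos <= human_intervals$human_end[i])
  pops <- sort(unique(rec$population))
  minp <- vapply(pops, function(pp) {
    v <- rec$p_value[inside & rec$population == pp]
    if (length(v)) min(v) else NA_real_
  }, 0)
  supporting <- sum(!is.na(minp) & minp <= threshold)
  out <- list(metabolite_id = metabolite_id, threshold = threshold,
              measured = TRUE, replicated = supporting >= 1L,
              populations_supporting = supporting,
              min_p_by_population = minp)
  class(out) <- "replication_result"
  out
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("replication_result: %s - %s (threshold %.2e, %d population(s))\n",
              x$metabolite_id,
              if (!x$measured) "not measured in human summary"
              else if (x$replicated) "replicated" else "not replicated",
              x$threshold, x$populations_supporting))
  invisible(x)
}

#' Replication screen over a set of mouse metabolite loci
#'
#' Restricts the peaks to metabolites present in the cross-species id
#' map, maps each peak window through the synteny map, and runs
#' [replication_test()] with the Bonferroni denominator equal to the
#' number of loci carried into the comparison.
#'
#' @param peaks peak data.frame (one row per mouse locus).
#' @param synteny_map 6-column synteny data.frame.
#' @param human_summary human GWAS summary data.frame.
#' @param id_map data.frame `mouse, human` mapping metabolite
#'   identifiers across species; `NULL` treats identifiers as shared.
#' @param half_window mouse locus half-window in bp (default 1 Mb).
#' @param alpha family-wise level.
#' @return data.frame, one row per tested locus: `metabolite_id,
#'   human_id, peak_snp, chrom, pos, measured, replicated,
#'   populations_supporting, min_p, threshold, n_loci_tested`.
#' @export
replicate_loci <- function(peaks, synteny_map, human_summary,
                           id_map = NULL, half_window = 1e6,
                           alpha = 0.05) {
  if (is.null(id_map))
    id_map <- data.frame(mouse = unique(peaks$phenotype),
                         human = unique(peaks$phenotype))
  tested <- peaks[peaks$phenotype %in% id_map$mouse, , drop = FALSE]
  n_loci <- nrow(tested)
  if (n_loci == 0) stop("no loci with a cross-species metabolite id")
  out <- NULL
  for (i in seq_len(n_loci)) {
    human_id <- id_map$human[match(tested$phenotype[i], id_map$mouse)]
    iv <- map_to_syntenic_intervals(
      list(chrom = tested$chrom[i],
           start = max(1, tested$pos[i] - half_window),
           end = tested$pos[i] + half_window), synteny_map)
    rr <- replication_test(human_summary, human_id, iv, n_loci, alpha)
    out <- rbind(out, data.frame(
      metabolite_id = tested$phenotype[i], human_id = human_id,
      peak_snp = tested$peak_snp[i], chrom = tested$chrom[i],
      pos = tested$pos[i], measured = rr$measured,
      replicated = rr$replicated,
      populations_supporting = rr$populations_supporting,
      min_p = if (length(rr$min_p_by_population) &&
                  any(!is.na(rr$min_p_by_population)))
        min(rr$min_p_by_population, na.rm = TRUE) else NA_real_,
      threshold = rr$threshold, n_loci_tested = n_loci,
      stringsAsFactors = FALSE))
  }
  out
}
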