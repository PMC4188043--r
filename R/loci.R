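# Locus definition and candidate-gene prioritization: collapse significant
# SNPs to peak SNPs by LD (R^2 > 0.5 with a stronger SNP absorbs the
# weaker), count distinct loci across phenotypes, call local eQTL (peak
# transcript SNP within a 2 Mb flank of the gene span), and intersect
# metabolite peak windows (+/- 1 Mb) with local-eQTL positions and
# pathway co-annotation pairs. All windows are inclusive of endpoints and
# collapsing is restricted to same-chromosome SNP pairs (cross-chromosome
# correlation in inbred panels reflects strain structure, which the mixed
# model already handles).

#' Squared Pearson correlation between two SNPs' dosages
#'
#' Computed over strains nonmissing for both SNPs (>= 3 required).
#'
#' @param g1,g2 dosage vectors.
#' @return scalar R^2.
#' @export
genotype_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) stop("fewer than 3 strain pairs with both dosages")
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0)
    stop("monomorphic SNP on shared strains")
  stats::cor(g1[ok], g2[ok])^2
}

# Deterministic ranking: ascending p, ties broken by (chrom, pos, snp_id).
.rank_records <- function(records) {
  cn <- suppressWarnings(as.numeric(records$chrom)); cn[is.na(cn)] <- Inf
  order(records$p, cn, as.character(records$chrom), records$pos,
        records$snp_id)
}

#' Collapse significant SNPs of one phenotype to peak SNPs
#'
#' Greedy rule: rank SNPs by ascending p; take the best unabsorbed SNP as
#' a peak; absorb every remaining same-chromosome SNP with R^2 strictly
#' greater than `r2_threshold` against the peak; repeat. Every
#' significant SNP ends in exactly one peak's member set.
#'
#' @param records association data.frame for one phenotype, already
#'   filtered to the significance threshold.
#' @param g `genotype_matrix` supplying dosages for R^2.
#' @param r2_threshold LD threshold (default 0.5).
#' @param half_window half-width of the reported locus window in bp
#'   (default 1 Mb, i.e. a 2 Mb locus).
#' @return data.frame of locus peaks: `phenotype, peak_snp, chrom, pos,
#'   p, window_start, window_end, n_members, member_snps, pve` (pve is NA
#'   until filled by [peak_pve()]).
#' @export
collapse_to_peaks <- function(records, g, r2_threshold = 0.5,
                              half_window = 1e6) {
  if (nrow(records) == 0)
    return(data.frame(phenotype = character(0), peak_snp = character(0),
                      chrom = character(0), pos = numeric(0), p = numeric(0),
                      window_start = numeric(0), window_end = numeric(0),
                      n_members = integer(0), member_snps = character(0),
                      pve = numeric(0)))
  if (length(unique(records$phenotype)) > 1)
    stop("collapse_to_peaks expects records for a single phenotype")
  records <- records[.rank_records(records), , drop = FALSE]
  remaining <- seq_len(nrow(records))
  peaks <- NULL
  while (length(remaining)) {
    i <- remaining[1]
    peak_g <- g$dosage[, records$snp_id[i]]
    members <- records$snp_id[i]
    rest <- remaining[-1]
    absorbed <- integer(0)
    for (j in rest) {
      if (records$chrom[j] != records$chrom[i]) next
      r2 <- tryCatch(genotype_r2(peak_g, g$dosage[, records$snp_id[j]]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_threshold) absorbed <- c(absorbed, j)
    }
    members <- c(members, records$snp_id[absorbed])
    peaks <- rbind(peaks, data.frame(
      phenotype = records$phenotype[i], peak_snp = records$snp_id[i],
      chrom = records$chrom[i], pos = records$pos[i], p = records$p[i],
      window_start = max(1, records$pos[i] - half_window),
      window_end = records$pos[i] + half_window,
      n_members = length(members),
      member_snps = paste(members, collapse = ","),
      pve = NA_real_, stringsAsFactors = FALSE))
    remaining <- setdiff(rest, absorbed)
  }
  peaks
}

#' Collapse significant records of every phenotype
#'
#' @param records pooled significant association records.
#' @inheritParams collapse_to_peaks
#' @return pooled peak data.frame.
#' @export
collapse_all_peaks <- function(records, g, r2_threshold = 0.5,
                               half_window = 1e6) {
  out <- lapply(split(records, records$phenotype), collapse_to_peaks,
                g = g, r2_threshold = r2_threshold,
                half_window = half_window)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fill percent variance explained for each peak
#'
#' @param peaks peak data.frame from [collapse_all_peaks()].
#' @param z strains x phenotypes matrix of standardized values.
#' @param g `genotype_matrix`.
#' @param K kinship matrix.
#' @return `peaks` with the `pve` column filled via [variance_explained()].
#' @export
peak_pve <- function(peaks, z, g, K) {
  for (i in seq_len(nrow(peaks))) {
    y <- z[, peaks$phenotype[i]]
    names(y) <- rownames(z)
    peaks$pve[i] <- as.numeric(
      variance_explained(y, g$dosage[, peaks$peak_snp[i]], K))
  }
  peaks
}

#' Count associations and distinct loci across phenotypes
#'
#' Distinct loci are deduplicated by exact peak-SNP identity: several
#' phenotypes sharing one peak SNP contribute several associations but a
#' single locus.
#'
#' @param all_peaks pooled peak data.frame.
#' @return named vector `c(n_associations, n_distinct)`.
#' @export
count_distinct_loci <- function(all_peaks) {
  c(n_associations = nrow(all_peaks),
    n_distinct = length(unique(all_peaks$peak_snp)))
}

#' Call local eQTL from a transcript association scan
#'
#' Per transcript the peak SNP is the argmin-p record (ties broken as in
#' [collapse_to_peaks()]); the record is kept if its p is at or below
#' `p_threshold` and flagged `is_local` when the peak SNP lies on the
#' gene's chromosome within `[start - flank, end + flank]` (default
#' flank 2 Mb, the 4 Mb local window). Transcripts without annotation are
#' skipped with a message.
#'
#' @param transcript_assoc pooled association records for transcripts
#'   (`phenotype` = transcript id).
#' @param annot gene annotation data.frame `gene_id, chrom, start, end`;
#'   transcript ids are matched to `gene_id`.
#' @param p_threshold significance threshold (a property of each study's
#'   p distribution, so always a parameter).
#' @param flank local-window flank in bp.
#' @return data.frame of eQTL records: `transcript, gene_id, gene_chrom,
#'   gene_start, gene_end, peak_snp, chrom, pos, p, is_local`.
#' @export
call_local_eqtls <- function(transcript_assoc, annot, p_threshold,
                             flank = 2e6) {
  out <- NULL
  for (tx in unique(transcript_assoc$phenotype)) {
    a <- annot[annot$gene_id == tx, , drop = FALSE]
    if (nrow(a) == 0) {
      message("skipping transcript without annotation: ", tx)
      next
    }
    rec <- transcript_assoc[transcript_assoc$phenotype == tx, , drop = FALSE]
    rec <- rec[.rank_records(rec)[1], , drop = FALSE]
    if (rec$p > p_threshold) next
    is_local <- rec$chrom == a$chrom[1] &&
      rec$pos >= a$start[1] - flank && rec$pos <= a$end[1] + flank
    out <- rbind(out, data.frame(
      transcript = tx, gene_id = a$gene_id[1], gene_chrom = a$chrom[1],
      gene_start = a$start[1], gene_end = a$end[1],
      peak_snp = rec$snp_id, chrom = rec$chrom, pos = rec$pos, p = rec$p,
      is_local = is_local, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(transcript = character(0), gene_id = character(0),
                      gene_chrom = character(0), gene_start = numeric(0),
                      gene_end = numeric(0), peak_snp = character(0),
                      chrom = character(0), pos = numeric(0), p = numeric(0),
                      is_local = logical(0))
  out
}

#' Candidate genes for one metabolite locus
#'
#' Candidates are genes whose local-eQTL peak SNP lies on the metabolite
#' peak's chromosome within `half_window` (inclusive) of its position.
#' Optionally intersects the candidates (and all genes provided) with a
#' metabolite-gene co-annotation pair table.
#'
#' @param metabolite_peak single-row peak data.frame.
#' @param local_eqtls eQTL records from [call_local_eqtls()]; only rows
#'   with `is_local = TRUE` are considered.
#' @param half_window candidate search half-window in bp (default 1 Mb).
#' @param annotation_pairs optional two-column data.frame
#'   (`metabolite, gene`).
#' @return list of class `candidate_report`: `metabolite_id`, `locus`,
#'   `candidate_genes` (data.frame gene/eqtl p), `annotation_matches`.
#' @export
find_candidate_genes <- function(metabolite_peak, local_eqtls,
                                 half_window = 1e6,
                                 annotation_pairs = NULL) {
  stopifnot(nrow(metabolite_peak) == 1)
  le <- local_eqtls[local_eqtls$is_local, , drop = FALSE]
  hit <- le$chrom == metabolite_peak$chrom &
    abs(le$pos - metabolite_peak$pos) <= half_window
  cand <- le[hit, c("gene_id", "peak_snp", "pos", "p"), drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  matches <- character(0)
  if (!is.null(annotation_pairs))
    matches <- co_annotation_match(metabolite_peak$phenotype,
                                   cand$gene_id, annotation_pairs)
  out <- list(metabolite_id = metabolite_peak$phenotype,
              locus = metabolite_peak,
              candidate_genes = cand,
              annotation_matches = matches)
  class(out) <- "candidate_report"
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %s @ %s:%.1f Mb - %d candidate gene(s)%s\n",
              x$metabolite_id, x$locus$chrom, x$locus$pos / 1e6,
              nrow(x$candidate_genes),
              if (length(x$annotation_matches))
                paste0(" [co-annotated: ",
                       paste(x$annotation_matches, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Genes at a locus co-annotated with a metabolite
#'
#' @param metabolite_id metabolite identifier.
#' @param genes_in_locus character vector of gene ids at the locus.
#' @param annotation_pairs data.frame with columns `metabolite`, `gene`
#'   (a KEGG/HMDB-style pathway pair table supplied as a file).
#' @return character vector: the intersection of `genes_in_locus` with
#'   the metabolite's annotated genes.
#' @export
co_annotation_match <- function(metabolite_id, genes_in_locus,
                                annotation_pairs) {
  stopifnot(all(c("metabolite", "gene") %in% colnames(annotation_pairs)))
  ann <- annotation_pairs$gene[annotation_pairs$metabolite == metabolite_id]
  intersect(genes_in_locus, ann)
}
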