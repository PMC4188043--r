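#!/usr/bin/env Rscript
# Stage 4 -- loci, variance explained, local eQTL and candidate genes.
#
# Collapses significant SNPs to peak SNPs (R^2 > 0.5), reports distinct
# loci and per-peak percent variance explained, scans the transcripts,
# calls local eQTL (2 Mb flanks), searches the +/- 1 Mb window around
# every metabolite peak for local-eQTL candidate genes, and checks the
# pathway co-annotation pairs. Finally scores recovery of the planted
# ground truth.

library(metaboqtl)

g <- read_genotype_table("results/data/genotypes.tsv")
K <- read_kinship("results/kinship.tsv")
ztab <- read_phenotype_table("results/metabolite_z.tsv")
assoc <- read_association_results("results/associations.tsv")
truth <- utils::read.delim("results/data/ground_truth.tsv",
                           colClasses = "character")
truth$pos <- as.numeric(truth$pos)

sig <- assoc[assoc$q <= 0.05, ]
peaks <- collapse_all_peaks(sig, g)
peaks <- peak_pve(peaks, ztab$values, g, K)
cnt <- count_distinct_loci(peaks)
message(sprintf(
  "%d significant associations -> %d peaks at %d distinct loci for %d metabolites; mean peak PVE %.0f%%",
  nrow(sig), cnt["n_associations"], cnt["n_distinct"],
  length(unique(peaks$phenotype)), 100 * mean(peaks$pve)))
utils::write.table(peaks, "results/peaks.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

# transcript scan and local eQTL
txn <- read_phenotype_table("results/data/transcripts.tsv")
annot <- read_gene_annotation("results/data/gene_annotation.tsv")
tz <- standardize(txn)
tassoc <- scan_phenotypes(tz$zvalues, g, K, mode = "exact")
eqtl_cut <- pvalue_threshold_at_fdr(tassoc$p, 0.05)
eqtls <- call_local_eqtls(tassoc, annot, eqtl_cut)
message(sprintf("eQTL: FDR-5%% p threshold %.3g, %d transcripts with a QTL, %d local",
                eqtl_cut, nrow(eqtls), sum(eqtls$is_local)))
utils::write.table(eqtls, "results/eqtls.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

# candidate genes per metabolite locus, with co-annotation support
pairs <- utils::read.delim("results/data/annotation_pairs.tsv",
                           colClasses = "character")
cand_rows <- NULL
for (i in seq_len(nrow(peaks))) {
  rep_ <- find_candidate_genes(peaks[i, ], eqtls, annotation_pairs = pairs)
  if (nrow(rep_$candidate_genes))
    cand_rows <- rbind(cand_rows, data.frame(
      metabolite = rep_$metabolite_id, peak_snp = rep_$locus$peak_snp,
      rep_$candidate_genes,
      co_annotated = rep_$candidate_genes$gene_id %in%
        rep_$annotation_matches))
}
message(sprintf("candidate genes: %d of %d loci have >= 1 local-eQTL candidate (%d co-annotated pairs)",
                length(unique(cand_rows$peak_snp)), nrow(peaks),
                sum(cand_rows$co_annotated)))
utils::write.table(cand_rows, "results/candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# ground-truth recovery
recovered <- vapply(seq_len(nrow(truth)), function(i) {
  pk <- peaks[peaks$phenotype == truth$phenotype[i], , drop = FALSE]
  any(pk$chrom == truth$chrom[i] & abs(pk$pos - truth$pos[i]) <= 1e6)
}, TRUE)
message(sprintf("recovery: %d / %d planted QTL found (%d / %d of those with PVE >= 0.4)",
                sum(recovered), nrow(truth),
                sum(recovered[as.numeric(truth$target_pve) >= 0.4]),
                sum(as.numeric(truth$target_pve) >= 0.4)))
message("stage 4 done")
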