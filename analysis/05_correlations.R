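#!/usr/bin/env Rscript
# Stage 5 -- robust correlation structure across data layers.
#
# All metabolite pairs under Bonferroni with within/between-class
# accounting, then FDR-5% biweight-midcorrelation screens of metabolites
# against transcripts and against clinical traits.

library(metaboqtl)

ztab <- read_phenotype_table("results/metabolite_z.tsv",
                             "results/metabolite_z_classes.tsv")
z <- ztab$values

rec <- pairwise_matrix(z, ztab$class_of_variable)
cls <- class_pair_summary(rec)
message(sprintf(
  "metabolite pairs: %d evaluated, Bonferroni p < %.3g, %d significant (%d%% within class, %d%% between)",
  nrow(rec), attr(rec, "threshold"), cls$n_significant, cls$pct_within,
  cls$pct_between))
utils::write.table(rec, "results/metabolite_correlations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

txn <- read_phenotype_table("results/data/transcripts.tsv")
tz <- standardize(txn)
mt <- cross_correlate(z, tz$zvalues, 0.05)
hits <- mt[mt$significant, ]
message(sprintf(
  "metabolite-transcript: %d pairs, FDR-5%% p threshold %.3g, %d significant (%d%% positive, %d%% negative)",
  nrow(mt), attr(mt, "threshold"), nrow(hits),
  round(100 * mean(hits$sign == "positive")),
  round(100 * mean(hits$sign == "negative"))))
utils::write.table(hits, "results/metabolite_transcript_hits.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

trt <- read_phenotype_table("results/data/clinical_traits.tsv")
ct <- cross_correlate(z, trt$values, 0.05)
message(sprintf("metabolite-trait: %d pairs, %d significant at FDR 5%%",
                nrow(ct), sum(ct$significant)))
utils::write.table(ct[ct$significant, ], "results/metabolite_trait_hits.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("stage 5 done")
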