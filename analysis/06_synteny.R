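#!/usr/bin/env Rscript
# Stage 6 -- cross-species syntenic replication.
#
# Maps every metabolite peak (+/- 1 Mb) through the synteny map and asks
# whether the human GWAS summary carries a record for the same
# metabolite below the Bonferroni threshold 0.05 / n_loci inside any
# mapped interval.

library(metaboqtl)

peaks <- utils::read.delim("results/peaks.tsv", colClasses = "character")
peaks$pos <- as.numeric(peaks$pos)
smap <- read_synteny_map("results/data/synteny_map.tsv")
human <- read_human_gwas("results/data/human_gwas.tsv")

rep_tab <- replicate_loci(peaks, smap, human)
message(sprintf(
  "replication: %d loci tested at threshold %.3g; %d measured in human, %d replicated (%.0f%%), %d in both populations",
  nrow(rep_tab), rep_tab$threshold[1], sum(rep_tab$measured),
  sum(rep_tab$replicated), 100 * mean(rep_tab$replicated),
  sum(rep_tab$populations_supporting >= 2)))
utils::write.table(rep_tab, "results/replication.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("stage 6 done")
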