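#!/usr/bin/env Rscript
# Stage 1 -- build the synthetic study panel.
#
# Generates an HMDP-like panel under the default study conditions (100
# strains in 8 families, ~2,000 SNPs in LD blocks after the MAF > 5%
# filter, 40 metabolites in 8 classes with 12 planted QTL at PVE
# 0.3/0.5/0.7, 60 transcripts with 12 planted local eQTL, clinical
# traits with 5 planted metabolite correlations, a synteny map and a
# human GWAS summary replicating 39% of planted loci) and writes every
# input table under results/data/.

library(metaboqtl)

seed <- 20260924L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)

g <- simulate_genotypes(cfg)
message(sprintf("genotypes: %d strains x %d SNPs (MAF > 5%%)",
                length(g$strains), length(g$snp_ids)))
write_genotype_table(g, "results/data/genotypes.tsv")

met <- simulate_metabolome(g, cfg)
message(sprintf("metabolome: %d samples x %d metabolites, %d planted QTL",
                length(met$table$sample_ids), length(met$table$variables),
                nrow(met$truth$qtl_map)))
write_phenotype_table(met$table, "results/data/metabolites.tsv",
                      "results/data/metabolite_classes.tsv")
utils::write.table(met$truth$qtl_map, "results/data/ground_truth.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

ann <- simulate_gene_annotation(g, cfg)
txn <- simulate_transcriptome(g, ann$annot, cfg)
write_phenotype_table(txn$table, "results/data/transcripts.tsv")
utils::write.table(ann$annot, "results/data/gene_annotation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

trt <- simulate_clinical_traits(met$table, cfg)
write_phenotype_table(trt$table, "results/data/clinical_traits.tsv")
utils::write.table(trt$targets, "results/data/trait_targets.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

smap <- simulate_synteny_map(g, cfg)
utils::write.table(smap, "results/data/synteny_map.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
human <- simulate_human_summary(met$truth$qtl_map, smap, cfg)
utils::write.table(human, "results/data/human_gwas.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# a small co-annotation pair table: each planted metabolite is
# co-annotated with its planted eQTL gene when both sit on the same SNP
pairs <- merge(met$truth$qtl_map[, c("phenotype", "snp_id")],
               data.frame(gene = ann$annot$gene_id[ann$planted$phenotype],
                          snp_id = g$snp_ids[ann$planted$snp]))
utils::write.table(data.frame(metabolite = pairs$phenotype,
                              gene = pairs$gene),
                   "results/data/annotation_pairs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("co-annotation pairs: %d", nrow(pairs)))
message("stage 1 done: inputs under results/data/")
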