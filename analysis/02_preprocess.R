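#!/usr/bin/env Rscript
# Stage 2 -- preprocess the metabolite table.
#
# Missingness filter (> 20% dropped), run-day median registration,
# replicate-mouse averaging, per-metabolite z-scoring; also compares the
# within-replicate variance of the 5-mouse reference strain against the
# panel variance (the genetic-variability argument).

library(metaboqtl)

met <- read_phenotype_table("results/data/metabolites.tsv",
                            "results/data/metabolite_classes.tsv")

filt <- filter_by_missingness(met, 0.20)
dropped <- attr(filt, "provenance")$missingness_filter$dropped
message(sprintf("missingness filter: %d of %d metabolites dropped, %d kept",
                length(dropped), length(met$variables),
                length(filt$variables)))

norm <- normalize_run_days(filt)
rep_strain <- names(which.max(table(norm$strain_of_sample)))
# variance comparison on the sample-level z scale, so "panel variance"
# is ~1 by construction and the replicate variance reads as the
# non-genetic share
zsamp <- phenotype_table(scale(norm$values), norm$strain_of_sample,
                         runday_of_sample = norm$runday_of_sample)
rv <- replicate_variance_summary(zsamp, rep_strain)
message(sprintf(
  "variance, replicate strain %s vs panel: mean %.2f vs %.2f, median %.2f vs %.2f",
  rep_strain, rv$mean_within, rv$mean_panel, rv$median_within,
  rv$median_panel))

z <- standardize(average_strain_replicates(norm))
ztab <- phenotype_table(z$zvalues, z$strain_ids,
                        class_of_variable = z$class_of_variable)
write_phenotype_table(ztab, "results/metabolite_z.tsv",
                      "results/metabolite_z_classes.tsv")
message(sprintf("stage 2 done: %d strains x %d standardized metabolites",
                length(z$strain_ids), length(z$variables)))
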