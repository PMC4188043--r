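Package: metaboqtl
Title: Mixed-Model Mapping and Multi-Omic Integration of Liver Metabolite QTL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association analysis of metabolite levels in inbred
    mouse strain panels. Implements an exact restricted-maximum-likelihood
    linear mixed model with identity-by-state kinship correction for
    population structure, Storey q-value false discovery rate control,
    linkage-disequilibrium-based collapsing of significant SNPs to peak
    SNPs, per-locus percent-variance-explained estimation, local expression
    QTL co-localization for candidate gene prioritization, robust
    (biweight midcorrelation) integration of metabolites with transcripts
    and clinical traits, and cross-species syntenic replication against
    human GWAS summary statistics. Includes a synthetic panel generator
    emulating a hybrid mouse diversity panel with planted quantitative
    trait loci so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
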