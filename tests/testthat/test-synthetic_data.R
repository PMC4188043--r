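# Synthetic panel generators: determinism, structural properties, and
# parameter recovery against planted ground truth.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, n_strains = 30, n_snps = 200,
                    n_metabolites = 8, n_transcripts = 8)
  g1 <- simulate_genotypes(cfg); g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  m1 <- simulate_metabolome(g1, cfg); m2 <- simulate_metabolome(g2, cfg)
  expect_identical(m1$table$values, m2$table$values)
  a1 <- simulate_gene_annotation(g1, cfg)
  t1 <- simulate_transcriptome(g1, a1$annot, cfg)
  t2 <- simulate_transcriptome(g1, a1$annot, cfg)
  expect_identical(t1$table$values, t2$table$values)
  c1 <- simulate_clinical_traits(m1$table, cfg)
  c2 <- simulate_clinical_traits(m1$table, cfg)
  expect_identical(c1$table$values, c2$table$values)
  # changing the seed changes the draw
  cfgb <- sim_config(seed = 6, n_strains = 30, n_snps = 200,
                     n_metabolites = 8, n_transcripts = 8)
  expect_false(identical(simulate_genotypes(cfgb)$dosage, g1$dosage))
})

test_that("unstructured independent SNPs give the closed-form mean IBS", {
  # with family_mixing = 0 and single-SNP blocks, strains are iid draws
  # at each SNP with allele frequency p ~ U(0.1, 0.5): the match
  # probability is E[p^2 + (1-p)^2] = 0.60667, and the Monte Carlo sd of
  # the panel mean is dominated by SNP-level sampling of p,
  # sqrt(Var[m(p)]/S)
  cfg <- sim_config(seed = 21, n_strains = 200, n_snps = 1000,
                    ld_block_size = 1, family_mixing = 0)
  g <- simulate_genotypes(cfg)
  K <- compute_ibs_kinship(g)
  expected <- integrate(function(p) (p^2 + (1 - p)^2) / 0.4, 0.1, 0.5)$value
  vm <- integrate(function(p) (p^2 + (1 - p)^2)^2 / 0.4, 0.1, 0.5)$value -
    expected^2
  mc_sd <- sqrt(vm / length(g$snp_ids))
  expect_lt(abs(mean(K[upper.tri(K)]) - expected), 3 * mc_sd)
})

test_that("LD blocks with flip probability zero are exact copies", {
  cfg <- sim_config(seed = 3, n_strains = 40, n_snps = 200,
                    ld_block_size = 50, ld_r_within = 1)
  g <- simulate_genotypes(cfg)
  # within each chromosome-block all retained SNPs are identical columns
  blocks <- split(seq_along(g$snp_ids),
                  paste(g$chrom, ceiling((g$pos / cfg$snp_spacing) / 50)))
  for (b in blocks) {
    if (length(b) < 2) next
    for (j in b[-1])
      expect_equal(genotype_r2(g$dosage[, b[1]], g$dosage[, j]), 1)
  }
})

test_that("null metabolome yields uniform mixed-model p-values", {
  cfg <- sim_config(seed = 33, n_snps = 500, ld_block_size = 1,
                    n_metabolites = 10,
                    planted_qtls = data.frame(phenotype = integer(0),
                                              snp = integer(0),
                                              pve = numeric(0)))
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  expect_equal(met$truth$null_set, met$table$variables)
  z <- preprocess_phenotypes(met$table)
  K <- compute_ibs_kinship(g)
  p <- unlist(lapply(z$variables, function(v) {
    y <- z$zvalues[, v]; names(y) <- rownames(z$zvalues)
    association_scan(y, g, K, mode = "null_approx")$p
  }))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("planted QTL effect sizes are realized near their targets", {
  pan <- default_panel()
  truth <- pan$met$truth$qtl_map
  expect_true(all(abs(truth$realized_pve - truth$target_pve) < 0.15))
  # realized PVE tightens towards the target as the panel grows
  cfg <- sim_config(seed = 8, n_strains = 500, n_snps = 300,
                    n_metabolites = 6,
                    planted_qtls = data.frame(phenotype = 1:3, snp = c(20, 150, 280),
                                              pve = c(0.3, 0.5, 0.7)))
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  expect_true(all(abs(met$truth$qtl_map$realized_pve -
                        met$truth$qtl_map$target_pve) < 0.05))
})

test_that("infeasible planted PVE and out-of-range indices error", {
  cfg <- sim_config(seed = 4, n_strains = 30, n_snps = 100, n_metabolites = 4)
  g <- simulate_genotypes(cfg)
  bad <- sim_config(seed = 4, n_strains = 30, n_snps = 100, n_metabolites = 4,
                    planted_qtls = data.frame(phenotype = c(1, 1), snp = c(5, 9),
                                              pve = c(0.6, 0.5)))
  expect_error(simulate_metabolome(g, bad), "infeasible")
  expect_error(sim_config(planted_qtls = data.frame(phenotype = 1, snp = 1,
                                                    pve = 1.2)),
               "\\(0, 1\\)")
  bad2 <- sim_config(seed = 4, n_strains = 30, n_snps = 100, n_metabolites = 4,
                     planted_qtls = data.frame(phenotype = 1, snp = 10^6,
                                               pve = 0.5))
  expect_error(simulate_metabolome(g, bad2), "out of range")
})

test_that("planted local eQTL are recovered and misplaced plants error", {
  cfg <- sim_config(seed = 13, n_strains = 80, n_snps = 600,
                    n_transcripts = 20,
                    planted_eqtls = data.frame(phenotype = 1:4,
                                               snp = c(50, 200, 350, 500),
                                               pve = 0.6))
  g <- simulate_genotypes(cfg)
  ann <- simulate_gene_annotation(g, cfg)
  txn <- simulate_transcriptome(g, ann$annot, cfg)
  K <- compute_ibs_kinship(g)
  tz <- standardize(txn$table)
  assoc <- scan_phenotypes(tz$zvalues, g, K, mode = "null_approx")
  cut <- pvalue_threshold_at_fdr(assoc$p, 0.05)
  eq <- call_local_eqtls(assoc, ann$annot, cut)
  planted_genes <- ann$annot$gene_id[1:4]
  hit <- eq$gene_id[eq$is_local]
  expect_gte(sum(planted_genes %in% hit), 3)  # >= 3/4 recovered locally
  # a planted SNP outside the 2 Mb window of its gene must error
  ann_bad <- ann$annot
  far <- which(ann_bad$chrom != g$chrom[50])[1]
  ann_bad[1, c("chrom", "start", "end")] <- ann_bad[far, c("chrom", "start", "end")]
  expect_error(simulate_transcriptome(g, ann_bad, cfg), "outside the 2 Mb")
})

test_that("clinical traits realize their target correlations", {
  cfg <- sim_config(seed = 17, n_strains = 100, n_snps = 200,
                    n_metabolites = 10,
                    trait_targets = data.frame(trait = "trait01",
                                               metabolite = 1, rho = 0.8))
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  trt <- simulate_clinical_traits(met$table, cfg)
  z <- preprocess_phenotypes(met$table)
  r <- bicor(z$zvalues[, "met001"], trt$table$values[rownames(z$zvalues), "trait01"])
  expect_lt(abs(r - 0.8), 0.15)
  # |rho| >= 1 is rejected
  bad <- sim_config(trait_targets = data.frame(trait = "t", metabolite = 1,
                                               rho = 1))
  gsm <- simulate_genotypes(sim_config(seed = 1, n_strains = 20, n_snps = 50,
                                       n_metabolites = 4))
  mm <- simulate_metabolome(gsm, sim_config(seed = 1, n_strains = 20,
                                            n_snps = 50, n_metabolites = 4))
  bad$n_strains <- 20
  expect_error(simulate_clinical_traits(mm$table, bad), "rho")
})

test_that("human summary replication fraction behaves as configured", {
  cfg <- sim_config(seed = 23, n_strains = 30, n_snps = 400)
  g <- simulate_genotypes(cfg)
  smap <- simulate_synteny_map(g, cfg)
  # constructed truth table: 100 loci spread along the simulated genome
  idx <- round(seq(1, length(g$snp_ids), length.out = 100))
  truth <- data.frame(phenotype = sprintf("met%03d", 1:100),
                      snp_id = g$snp_ids[idx], chrom = g$chrom[idx],
                      pos = g$pos[idx])
  # fraction 1: every locus replicates at the Bonferroni threshold
  cfg$replicate_fraction <- 1
  hs <- simulate_human_summary(truth, smap, cfg)
  rep_all <- sapply(1:100, function(i) {
    iv <- map_to_syntenic_intervals(list(chrom = truth$chrom[i],
                                         start = max(1, truth$pos[i] - 1e6),
                                         end = truth$pos[i] + 1e6), smap)
    replication_test(hs, truth$phenotype[i], iv, 100)$replicated
  })
  expect_true(all(rep_all))
  # fraction 0.39: observed rate within the exact binomial 95% interval
  cfg$replicate_fraction <- 0.39
  hs2 <- simulate_human_summary(truth, smap, cfg)
  rep_frac <- mean(sapply(1:100, function(i) {
    iv <- map_to_syntenic_intervals(list(chrom = truth$chrom[i],
                                         start = max(1, truth$pos[i] - 1e6),
                                         end = truth$pos[i] + 1e6), smap)
    replication_test(hs2, truth$phenotype[i], iv, 100)$replicated
  }))
  ci <- stats::binom.test(39, 100)$conf.int
  expect_gte(rep_frac, ci[1]); expect_lte(rep_frac, ci[2])
  # fraction 0: no locus replicates
  cfg$replicate_fraction <- 0
  hs3 <- simulate_human_summary(truth, smap, cfg)
  expect_false(any(sapply(1:20, function(i) {
    iv <- map_to_syntenic_intervals(list(chrom = truth$chrom[i],
                                         start = max(1, truth$pos[i] - 1e6),
                                         end = truth$pos[i] + 1e6), smap)
    replication_test(hs3, truth$phenotype[i], iv, 100)$replicated
  })))
})
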