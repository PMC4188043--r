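# End-to-end orchestration: simulate (or load) -> preprocess -> kinship ->
# metabolite scan -> FDR -> peaks/PVE -> transcript scan -> local eQTL ->
# candidates -> correlations -> synteny. Every stage writes its table
# under the output directory and logs its row counts into a JSON run
# manifest, so a run is a pure function of (inputs, config, seed).

#' Pipeline configuration
#'
#' Every analysis parameter is surfaced with its conventional default:
#' minor-allele frequency > 5%, metabolite missingness <= 20%, FDR 5%,
#' peak collapsing at R^2 > 0.5, 2 Mb locus windows (1 Mb per side), 2 Mb
#' local-eQTL flanks, and a 1 Mb candidate search half-window.
#'
#' @param maf_min minor-allele-frequency cutoff (SNPs kept strictly
#'   above).
#' @param missing_max maximum metabolite missing fraction.
#' @param fdr_level genome-wide FDR level for the metabolite and
#'   transcript scans.
#' @param r2_threshold LD threshold for peak collapsing.
#' @param locus_half_window locus half-window in bp.
#' @param eqtl_flank local-eQTL flank in bp.
#' @param candidate_half_window candidate-gene search half-window in bp.
#' @param scan_mode `"exact"` or `"null_approx"` (see
#'   [association_scan()]).
#' @param replication_alpha family-wise level for the synteny comparison.
#' @param seed master seed for the simulation stage.
#' @param sim a [sim_config()] used when the run simulates its inputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(maf_min = 0.05, missing_max = 0.20,
                            fdr_level = 0.05, r2_threshold = 0.5,
                            locus_half_window = 1e6, eqtl_flank = 2e6,
                            candidate_half_window = 1e6,
                            scan_mode = c("exact", "null_approx"),
                            replication_alpha = 0.05, seed = 1L,
                            sim = NULL) {
  scan_mode <- match.arg(scan_mode)
  stopifnot(maf_min >= 0, maf_min < 0.5, missing_max >= 0, missing_max <= 1,
            fdr_level > 0, fdr_level < 1, r2_threshold >= 0,
            r2_threshold <= 1)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic panel
#'
#' Simulates the panel described by `config$sim`, then runs every stage in
#' order, writing each intermediate table plus a JSON run manifest (config
#' echo, seed, per-stage row counts) under `out_dir`. Returns the
#' artifacts invisibly for programmatic use.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` keeps
#'   everything in memory and writes nothing.
#' @return (invisibly) list with every stage product: `genotypes`,
#'   `kinship`, `metab_z`, `assoc`, `fdr`, `significant`, `peaks`,
#'   `counts`, `eqtls`, `candidates`, `metab_cor`, `trait_cor`,
#'   `replication`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stages <- list()
  note <- function(stage, ...) {
    stages[[stage]] <<- list(...)
  }
  emit <- function(obj, name, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  wt <- function(d, path) utils::write.table(d, path, sep = "\t",
                                             quote = FALSE, row.names = FALSE)

  # --- simulate ---------------------------------------------------------
  sim <- config$sim
  g <- simulate_genotypes(sim)
  g <- filter_maf(g, config$maf_min)
  met <- simulate_metabolome(g, sim)
  has_txn <- sim$n_transcripts > 0
  if (has_txn) {
    ann <- simulate_gene_annotation(g, sim)
    txn <- simulate_transcriptome(g, ann$annot, sim)
  } else ann <- txn <- NULL
  trt <- simulate_clinical_traits(met$table, sim)
  smap <- simulate_synteny_map(g, sim)
  human <- simulate_human_summary(met$truth$qtl_map, smap, sim)
  emit(g, "genotypes.tsv", write_genotype_table)
  if (!is.null(out_dir)) {
    write_phenotype_table(met$table, file.path(out_dir, "metabolites.tsv"),
                          file.path(out_dir, "metabolite_classes.tsv"))
    wt(met$truth$qtl_map, file.path(out_dir, "ground_truth.tsv"))
    wt(ann$annot, file.path(out_dir, "gene_annotation.tsv"))
    wt(smap, file.path(out_dir, "synteny_map.tsv"))
    wt(human, file.path(out_dir, "human_gwas.tsv"))
  }
  note("simulate", n_strains = length(g$strains),
       n_snps_after_maf = length(g$snp_ids),
       n_metabolites = length(met$table$variables),
       n_transcripts = if (has_txn) length(txn$table$variables) else 0L,
       n_planted_qtls = nrow(met$truth$qtl_map))

  # --- preprocess -------------------------------------------------------
  metab_z <- preprocess_phenotypes(met$table, config$missing_max)
  note("preprocess",
       n_metabolites_kept = length(metab_z$variables),
       n_dropped_missingness =
         length(met$table$variables) - length(metab_z$variables))

  # --- kinship ----------------------------------------------------------
  K <- compute_ibs_kinship(g)
  if (!is.null(out_dir)) write_kinship(K, file.path(out_dir, "kinship.tsv"))
  note("kinship", n_strains = nrow(K))

  # --- metabolite scan + FDR -------------------------------------------
  assoc <- scan_phenotypes(metab_z$zvalues, g, K, mode = config$scan_mode)
  qres <- estimate_qvalues(assoc$p)
  assoc$q <- qres$qvalues
  p_cut <- pvalue_threshold_at_fdr(assoc$p, config$fdr_level)
  sig <- assoc[assoc$q <= config$fdr_level, , drop = FALSE]
  if (!is.null(out_dir))
    write_association_results(assoc, file.path(out_dir, "associations.tsv"))
  note("scan", n_tests = nrow(assoc), pi0 = qres$pi0,
       p_threshold = p_cut, n_significant = nrow(sig),
       expected_false_positives =
         expected_false_positives(nrow(sig), config$fdr_level))

  # --- peaks + PVE ------------------------------------------------------
  peaks <- collapse_all_peaks(sig, g, config$r2_threshold,
                              config$locus_half_window)
  if (nrow(peaks))
    peaks <- peak_pve(peaks, metab_z$zvalues, g, K)
  counts <- count_distinct_loci(peaks)
  if (!is.null(out_dir)) wt(peaks, file.path(out_dir, "peaks.tsv"))
  note("peaks", n_associations = unname(counts["n_associations"]),
       n_distinct_loci = unname(counts["n_distinct"]),
       n_metabolites_mapped = length(unique(peaks$phenotype)),
       mean_pve = if (nrow(peaks)) mean(peaks$pve) else NA_real_)

  # --- transcript scan + local eQTL ------------------------------------
  if (has_txn) {
    tz <- standardize(txn$table)
    tassoc <- scan_phenotypes(tz$zvalues, g, K, mode = config$scan_mode)
    eqtl_cut <- pvalue_threshold_at_fdr(tassoc$p, config$fdr_level)
    eqtls <- call_local_eqtls(tassoc, ann$annot, eqtl_cut, config$eqtl_flank)
    if (!is.null(out_dir)) wt(eqtls, file.path(out_dir, "eqtls.tsv"))
    note("eqtl", p_threshold = eqtl_cut, n_eqtls = nrow(eqtls),
         n_local = sum(eqtls$is_local))

    # --- candidates -----------------------------------------------------
    candidates <- lapply(seq_len(nrow(peaks)), function(i)
      find_candidate_genes(peaks[i, , drop = FALSE], eqtls,
                           config$candidate_half_window))
    n_with_cand <- sum(vapply(candidates, function(x)
      nrow(x$candidate_genes) > 0, TRUE))
    if (!is.null(out_dir) && length(candidates)) {
      cand_tab <- do.call(rbind, lapply(candidates, function(x)
        if (nrow(x$candidate_genes))
          cbind(metabolite = x$metabolite_id, peak_snp = x$locus$peak_snp,
                x$candidate_genes) else NULL))
      if (!is.null(cand_tab)) wt(cand_tab, file.path(out_dir, "candidates.tsv"))
    }
    note("candidates", n_loci = nrow(peaks),
         n_loci_with_candidate = n_with_cand)
  } else {
    tz <- NULL; eqtls <- NULL; eqtl_cut <- NA_real_; candidates <- list()
    note("eqtl", skipped = TRUE)
    note("candidates", skipped = TRUE)
  }

  # --- correlations -----------------------------------------------------
  metab_cor <- pairwise_matrix(metab_z$zvalues, metab_z$class_of_variable)
  cls <- class_pair_summary(metab_cor)
  trait_cor <- cross_correlate(metab_z$zvalues, trt$table$values,
                               config$fdr_level)
  txn_cor <- if (has_txn)
    cross_correlate(metab_z$zvalues, tz$zvalues, config$fdr_level) else NULL
  if (!is.null(out_dir)) {
    wt(metab_cor, file.path(out_dir, "metabolite_correlations.tsv"))
    wt(trait_cor, file.path(out_dir, "trait_correlations.tsv"))
  }
  note("correlation", n_pairs = nrow(metab_cor),
       n_significant = cls$n_significant, pct_within = cls$pct_within,
       n_trait_hits = sum(trait_cor$significant),
       n_transcript_hits = if (has_txn) sum(txn_cor$significant) else NA)

  # --- synteny ----------------------------------------------------------
  replication <- if (nrow(peaks))
    replicate_loci(peaks, smap, human, alpha = config$replication_alpha)
  else NULL
  if (!is.null(out_dir) && !is.null(replication))
    wt(replication, file.path(out_dir, "replication.tsv"))
  note("synteny",
       n_loci_tested = if (is.null(replication)) 0L else nrow(replication),
       n_replicated = if (is.null(replication)) 0L
       else sum(replication$replicated))

  # --- ground-truth recovery accounting --------------------------------
  truth <- met$truth$qtl_map
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    pk <- peaks[peaks$phenotype == truth$phenotype[i], , drop = FALSE]
    any(pk$chrom == truth$chrom[i] &
          abs(pk$pos - truth$pos[i]) <= config$locus_half_window)
  }, TRUE)
  note("recovery", n_planted = nrow(truth), n_recovered = sum(recovered),
       n_recovered_pve_ge_0.4 = sum(recovered[truth$target_pve >= 0.4]),
       n_planted_pve_ge_0.4 = sum(truth$target_pve >= 0.4))

  manifest <- list(seed = config$seed, scan_mode = config$scan_mode,
                   parameters = list(
                     maf_min = config$maf_min,
                     missing_max = config$missing_max,
                     fdr_level = config$fdr_level,
                     r2_threshold = config$r2_threshold,
                     locus_half_window = config$locus_half_window,
                     eqtl_flank = config$eqtl_flank,
                     candidate_half_window = config$candidate_half_window),
                   stages = stages)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genotypes = g, kinship = K, metab_z = metab_z,
                 truth = met$truth, assoc = assoc, p_threshold = p_cut,
                 significant = sig, peaks = peaks, counts = counts,
                 annot = if (has_txn) ann$annot else NULL,
                 eqtls = eqtls, eqtl_threshold = eqtl_cut,
                 candidates = candidates, metab_cor = metab_cor,
                 class_summary = cls, trait_cor = trait_cor,
                 txn_cor = txn_cor, replication = replication,
                 human = human, synteny_map = smap, manifest = manifest))
}
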