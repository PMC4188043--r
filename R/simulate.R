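# Synthetic panel generator.
#
# Emulates the shape of a hybrid mouse diversity panel study: ~100 inbred
# strains in discrete strain families (the population structure a mixed
# model must correct), SNPs in linkage-disequilibrium blocks, metabolites
# in eight classes with planted QTL of known variance explained,
# run-day multiplicative batch effects, replicate mice for some strains,
# transcripts with planted local eQTL, clinical traits with planted
# metabolite correlations, and a human GWAS summary with a configured
# replication fraction. Every generator is a pure function of
# (config, seed); each draws its own stream via derive_seed().

.METABOLITE_CLASSES <- c("Lipids", "Amino Acids", "Carbohydrates",
                         "Nucleotides", "Peptides", "Xenobiotics",
                         "Cofactors", "Energy")

#' Simulation configuration for a synthetic strain panel
#'
#' Defaults describe the study conditions the package is exercised under:
#' 100 strains in 8 families, 2,000 SNPs in 10-SNP LD blocks across 10
#' chromosomes at 25 kb spacing (a scaled-down dense panel), 40 metabolites
#' in the eight canonical classes with 12 planted QTL, one strain with five
#' replicate mice and twenty with two, six profiling run-days with a
#' multiplicative batch effect, and 5% missing cells.
#'
#' @param n_strains number of inbred strains.
#' @param n_snps SNPs before the minor-allele-frequency filter.
#' @param n_chromosomes autosomes the SNPs are spread over.
#' @param snp_spacing base pairs between adjacent SNPs.
#' @param ld_block_size SNPs per linkage-disequilibrium block.
#' @param ld_r_within target correlation between a block founder SNP and
#'   its copies; copies flip with probability `(1 - ld_r_within)/2`.
#' @param n_families strain families inducing population structure.
#' @param family_mixing probability that a strain carries its family
#'   haplotype at a founder SNP (0 = unstructured panel).
#' @param family_var,resid_var variance of the family random effect and of
#'   the residual in every latent phenotype (phenotypes are built on a
#'   unit-free latent scale).
#' @param class_var variance of a per-class shared factor added to every
#'   metabolite (metabolites of one class share pathway variance, which
#'   is what makes within-class correlations dominate the significant
#'   pairs); transcripts and null-structure checks are unaffected because
#'   the factor is independent of the genotypes.
#' @param n_metabolites,n_classes metabolite panel size and class count
#'   (classes cycle through the eight canonical class names).
#' @param planted_qtls data.frame with columns `phenotype` (metabolite
#'   index), `snp` (SNP index into the filtered genotype matrix) and `pve`
#'   (target variance explained in (0,1)); `NULL` plants the default set of
#'   12 QTL at PVE 0.3/0.5/0.7 on evenly spaced SNPs.
#' @param n_transcripts transcript panel size.
#' @param planted_eqtls like `planted_qtls` for transcripts; `NULL` plants
#'   12 local eQTL at PVE 0.6.
#' @param n_rundays,runday_effect_sd profiling run-days and the standard
#'   deviation of the log multiplicative run-day effect.
#' @param sample_sd within-strain (replicate mouse) standard deviation.
#' @param abundance_shift constant added to latent values so raw
#'   abundances are positive before the multiplicative batch effect.
#' @param missing_frac fraction of cells set missing at random.
#' @param replicate_strains named integer vector of replicate mouse counts
#'   for selected strains; `NULL` gives the default (one strain with 5,
#'   twenty strains with 2).
#' @param trait_targets data.frame `trait`, `metabolite` (index), `rho`
#'   for planted clinical-trait correlations; `NULL` gives 5 correlated
#'   plus 5 null traits.
#' @param replicate_fraction fraction of planted mouse loci carrying a
#'   sub-threshold signal in the synthetic human GWAS summary.
#' @param human_populations population labels for the human summary.
#' @param seed master seed; all generators derive labelled streams.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_strains = 100, n_snps = 2000, n_chromosomes = 10,
                       snp_spacing = 25000, ld_block_size = 10,
                       ld_r_within = 0.9, n_families = 8,
                       family_mixing = 0.75, family_var = 0.4,
                       resid_var = 0.6, class_var = 0.8,
                       n_metabolites = 40, n_classes = 8,
                       planted_qtls = NULL, n_transcripts = 60,
                       planted_eqtls = NULL, n_rundays = 6,
                       runday_effect_sd = 0.15, sample_sd = 0.25,
                       abundance_shift = 10, missing_frac = 0.05,
                       replicate_strains = NULL, trait_targets = NULL,
                       replicate_fraction = 0.39,
                       human_populations = c("KORA", "TwinsUK"),
                       seed = 1L) {
  stopifnot(n_strains >= 4, n_snps >= 1, n_chromosomes >= 1,
            ld_block_size >= 1, n_families >= 1,
            family_mixing >= 0, family_mixing < 1,
            missing_frac >= 0, missing_frac < 1,
            ld_r_within > 0, ld_r_within <= 1)
  if (!is.null(planted_qtls))
    .check_planted(planted_qtls, n_metabolites)
  if (!is.null(planted_eqtls))
    .check_planted(planted_eqtls, n_transcripts)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.check_planted <- function(pl, n_pheno) {
  stopifnot(is.data.frame(pl),
            all(c("phenotype", "snp", "pve") %in% colnames(pl)))
  if (any(pl$pve <= 0 | pl$pve >= 1))
    stop("planted target_pve must lie in (0, 1)")
  if (any(pl$phenotype < 1 | pl$phenotype > n_pheno))
    stop("planted phenotype index out of range")
}

.strain_names <- function(n) sprintf("strain%03d", seq_len(n))

#' Simulate panel genotypes with LD blocks and strain families
#'
#' Dosages are homozygous \{0, 2\}. Within an LD block every SNP is a copy
#' of the block founder with per-strain flip probability
#' `(1 - ld_r_within)/2`; strains within a family carry a shared family
#' haplotype at each founder SNP with probability `family_mixing`. SNPs
#' with minor-allele frequency <= 5% are removed before return (the
#' standard informative-SNP filter).
#'
#' @param config a [sim_config()].
#' @return `genotype_matrix` with a `family` attribute (named strain
#'   family assignment).
#' @export
simulate_genotypes <- function(config) {
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_strains
  strains <- .strain_names(n)
  fam <- stats::setNames(sample(rep_len(seq_len(config$n_families), n)),
                         strains)
  eps <- (1 - config$ld_r_within) / 2
  per_chr <- diff(floor(seq(0, config$n_snps,
                            length.out = config$n_chromosomes + 1L)))
  cols <- list(); chrom <- character(0); pos <- numeric(0)
  for (c_i in seq_len(config$n_chromosomes)) {
    nc <- per_chr[c_i]
    if (nc == 0) next
    block <- ceiling(seq_len(nc) / config$ld_block_size)
    for (b in unique(block)) {
      idx <- which(block == b)
      p <- stats::runif(1, 0.1, 0.5)
      fam_allele <- stats::rbinom(config$n_families, 1, p)
      own <- stats::rbinom(n, 1, p)
      founder <- ifelse(stats::runif(n) < config$family_mixing,
                        fam_allele[fam], own)
      for (j in seq_along(idx)) {
        hap <- if (j == 1L) founder else {
          flip <- stats::runif(n) < eps
          ifelse(flip, 1L - founder, founder)
        }
        cols[[length(cols) + 1L]] <- hap * 2
      }
    }
    chrom <- c(chrom, rep(as.character(c_i), nc))
    pos <- c(pos, seq_len(nc) * config$snp_spacing)
  }
  dosage <- do.call(cbind, cols)
  rownames(dosage) <- strains
  ids <- sprintf("snp%05d", seq_len(ncol(dosage)))
  g <- genotype_matrix(ids, chrom, pos, dosage)
  g <- filter_maf(g, 0.05)
  if (length(g$snp_ids) == 0L)
    stop("configuration yielded zero polymorphic SNPs after the MAF filter")
  attr(g, "family") <- fam
  g
}

# Default planted set: 12 phenotypes on SNPs evenly spaced through the
# filtered panel, target PVE cycling 0.3 / 0.5 / 0.7.
.default_plant <- function(g, n_pheno, n_plant = 12, pve = c(0.3, 0.5, 0.7)) {
  n_plant <- min(n_plant, n_pheno)
  snps <- round(seq(1, length(g$snp_ids), length.out = n_plant + 2))[
    seq_len(n_plant) + 1L]
  data.frame(phenotype = seq_len(n_plant), snp = snps,
             pve = rep_len(pve, n_plant))
}

# Latent strain-level phenotypes: planted SNP effects + family random
# effect + iid noise, with beta sized so var(beta*g)/var(y) hits the
# target PVE. For planted phenotypes the combined noise (family effect +
# residual) is residualized in-sample against the planted genotypes: with
# a handful of strain families the sample correlation between a
# family-structured SNP and the family effect draw does not vanish with
# panel size, so without this the planted "variance explained" would not
# be a well-defined ground truth. Null phenotypes keep the full family
# structure (which is what makes the uncorrected scan anti-conservative).
.simulate_latent <- function(g, planted, n_pheno, pheno_names, config,
                             extra_noise = NULL) {
  n <- length(g$strains)
  fam <- attr(g, "family")
  if (is.null(fam)) fam <- stats::setNames(seq_len(n), g$strains)
  lat <- matrix(0, n, n_pheno, dimnames = list(g$strains, pheno_names))
  truth <- NULL
  for (m in seq_len(n_pheno)) {
    fe <- stats::rnorm(max(fam), 0, sqrt(config$family_var))[fam]
    noise <- fe + stats::rnorm(n, 0, sqrt(config$resid_var))
    if (!is.null(extra_noise)) noise <- noise + extra_noise[, m]
    rows <- planted[planted$phenotype == m, , drop = FALSE]
    if (nrow(rows) == 0) { lat[, m] <- noise; next }
    H <- sum(rows$pve)
    if (H >= 0.95)
      stop(sprintf("planted PVE for phenotype %d infeasible given the noise floor", m))
    G_pl <- g$dosage[, rows$snp, drop = FALSE]
    if (any(!is.finite(apply(G_pl, 2, stats::var))) ||
        any(apply(G_pl, 2, stats::var) == 0))
      stop("planted SNP is monomorphic in the simulated panel")
    noise <- stats::lm.fit(cbind(1, G_pl), noise)$residuals
    base_var <- stats::var(noise)
    y <- noise
    for (r in seq_len(nrow(rows))) {
      gdose <- G_pl[, r]
      vg <- stats::var(gdose)
      beta <- sqrt(rows$pve[r] / (1 - H) * base_var / vg)
      y <- y + beta * gdose
      truth <- rbind(truth, data.frame(
        phenotype = pheno_names[m], snp_id = g$snp_ids[rows$snp[r]],
        chrom = g$chrom[rows$snp[r]], pos = g$pos[rows$snp[r]],
        target_pve = rows$pve[r],
        realized_pve = NA_real_, beta = beta))
    }
    # realized sample PVE of each planted SNP against the final latent y
    for (r in which(truth$phenotype == pheno_names[m])) {
      gdose <- g$dosage[, truth$snp_id[r]]
      fit <- stats::lm.fit(cbind(1, gdose), y)
      truth$realized_pve[r] <- 1 - stats::var(fit$residuals) / stats::var(y)
    }
    lat[, m] <- y
  }
  list(latent = lat, truth = truth)
}

# Expand strain-level latent values into replicate mouse samples with
# run-day multiplicative batch effects, a positivity shift and missing
# cells.
.expand_samples <- function(lat, config) {
  strains <- rownames(lat)
  reps <- config$replicate_strains
  if (is.null(reps)) {
    reps <- stats::setNames(rep(1L, length(strains)), strains)
    reps[1] <- 5L
    if (length(strains) >= 21) reps[2:21] <- 2L
  } else {
    full <- stats::setNames(rep(1L, length(strains)), strains)
    full[names(reps)] <- reps
    reps <- full
  }
  sample_strain <- rep(strains, times = reps[strains])
  sample_ids <- unlist(lapply(strains, function(s)
    if (reps[s] == 1L) s else paste0(s, "_m", seq_len(reps[s]))))
  vals <- lat[sample_strain, , drop = FALSE] +
    matrix(stats::rnorm(length(sample_strain) * ncol(lat), 0,
                        config$sample_sd),
           length(sample_strain), ncol(lat))
  runday <- sprintf("day%d", sample(config$n_rundays,
                                    length(sample_ids), replace = TRUE))
  mult <- exp(stats::rnorm(config$n_rundays, 0, config$runday_effect_sd))
  abund <- (vals + config$abundance_shift) * mult[as.integer(sub("day", "", runday))]
  if (config$missing_frac > 0)
    abund[matrix(stats::runif(length(abund)) < config$missing_frac,
                 nrow(abund), ncol(abund))] <- NA_real_
  rownames(abund) <- sample_ids
  list(values = abund, strain = sample_strain, runday = runday)
}

#' Simulate a sample-level metabolite table with planted QTL
#'
#' For each planted (metabolite, SNP, target PVE) the strain-level latent
#' value is `beta * g + family effect + N(0, resid_var)` with `beta` sized
#' so `var(beta*g)/var(y)` equals the target in expectation. Replicate
#' mouse samples add within-strain noise; raw abundances are shifted
#' positive and scaled by a per-run-day multiplicative batch effect
#' (which run-day median registration removes exactly); cells go missing
#' uniformly at `missing_frac`.
#'
#' @param g `genotype_matrix` from [simulate_genotypes()].
#' @param config a [sim_config()].
#' @return list with `table` (a sample-level [phenotype_table()]) and
#'   `truth` (list `qtl_map`, `null_set`).
#' @export
simulate_metabolome <- function(g, config) {
  set.seed(derive_seed(config$seed, "metabolome"))
  planted <- config$planted_qtls
  if (is.null(planted)) planted <- .default_plant(g, config$n_metabolites)
  .check_planted(planted, config$n_metabolites)
  if (any(planted$snp < 1 | planted$snp > length(g$snp_ids)))
    stop("planted SNP index out of range for this genotype matrix")
  mets <- sprintf("met%03d", seq_len(config$n_metabolites))
  class_idx <- rep_len(seq_len(config$n_classes), config$n_metabolites)
  # shared per-class pathway factor: within-class metabolite pairs
  # correlate at roughly class_var / total noise variance
  f_class <- matrix(stats::rnorm(length(g$strains) * config$n_classes),
                    length(g$strains), config$n_classes)
  extra <- sqrt(config$class_var) * f_class[, class_idx, drop = FALSE]
  sim <- .simulate_latent(g, planted, config$n_metabolites, mets, config,
                          extra_noise = extra)
  smp <- .expand_samples(sim$latent, config)
  classes <- stats::setNames(
    .METABOLITE_CLASSES[seq_len(config$n_classes)][class_idx], mets)
  tab <- phenotype_table(smp$values, smp$strain,
                         class_of_variable = classes,
                         runday_of_sample = smp$runday)
  truth <- list(qtl_map = sim$truth,
                null_set = setdiff(mets, sim$truth$phenotype),
                latent = sim$latent)
  list(table = tab, truth = truth)
}

#' Simulate gene annotation compatible with a planted eQTL set
#'
#' Planted transcripts get a gene span starting 500 kb proximal of their
#' planted SNP (well inside the 2 Mb local window); the rest are placed
#' uniformly along the simulated chromosomes.
#'
#' @param g `genotype_matrix`.
#' @param config a [sim_config()]; uses `planted_eqtls` (or the default
#'   plant) and `n_transcripts`.
#' @return list with `annot` (gene annotation data.frame) and `planted`
#'   (the resolved planted-eQTL data.frame).
#' @export
simulate_gene_annotation <- function(g, config) {
  set.seed(derive_seed(config$seed, "annotation"))
  planted <- config$planted_eqtls
  if (is.null(planted))
    planted <- .default_plant(g, config$n_transcripts, pve = 0.6)
  .check_planted(planted, config$n_transcripts)
  genes <- sprintf("gene%03d", seq_len(config$n_transcripts))
  chr_len <- tapply(g$pos, g$chrom, max)
  chrom <- sample(names(chr_len), config$n_transcripts, replace = TRUE)
  start <- floor(stats::runif(config$n_transcripts) *
                   pmax(1, chr_len[chrom] - 1e5)) + 1
  end <- start + 5e4
  for (r in seq_len(nrow(planted))) {
    i <- planted$phenotype[r]
    chrom[i] <- g$chrom[planted$snp[r]]
    start[i] <- max(1, g$pos[planted$snp[r]] - 5e5)
    end[i] <- start[i] + 5e4
  }
  list(annot = data.frame(gene_id = genes, chrom = chrom,
                          start = as.numeric(start), end = as.numeric(end)),
       planted = planted)
}

#' Simulate a strain-level transcript table with planted local eQTL
#'
#' Transcripts use the same latent model as metabolites (family effect +
#' noise + planted SNP effects) and are delivered strain-level, emulating
#' an already-normalized expression matrix. Errors if a planted SNP lies
#' outside the 2 Mb local window of its gene, which would silently break
#' co-localization tests downstream.
#'
#' @param g `genotype_matrix`.
#' @param annot gene annotation data.frame (`gene_id, chrom, start, end`);
#'   transcript i is annotated by row i.
#' @param config a [sim_config()].
#' @return list with `table` ([phenotype_table()], one sample per strain)
#'   and `truth` (list `eqtl_map`, `null_set`).
#' @export
simulate_transcriptome <- function(g, annot, config) {
  set.seed(derive_seed(config$seed, "transcriptome"))
  planted <- config$planted_eqtls
  if (is.null(planted))
    planted <- .default_plant(g, config$n_transcripts, pve = 0.6)
  .check_planted(planted, config$n_transcripts)
  for (r in seq_len(nrow(planted))) {
    i <- planted$phenotype[r]; s <- planted$snp[r]
    if (g$chrom[s] != annot$chrom[i] ||
        g$pos[s] < annot$start[i] - 2e6 || g$pos[s] > annot$end[i] + 2e6)
      stop(sprintf("planted eQTL SNP %s outside the 2 Mb local window of gene %s",
                   g$snp_ids[s], annot$gene_id[i]))
  }
  txs <- annot$gene_id[seq_len(config$n_transcripts)]
  sim <- .simulate_latent(g, planted, config$n_transcripts, txs, config)
  tab <- phenotype_table(sim$latent, rownames(sim$latent))
  truth <- list(eqtl_map = sim$truth,
                null_set = setdiff(txs, sim$truth$phenotype))
  list(table = tab, truth = truth)
}

#' Simulate clinical traits with planted metabolite correlations
#'
#' Traits are built at strain level as `rho * z(metabolite) +
#' sqrt(1 - rho^2) * noise` from the strain-averaged metabolite table, so
#' the realized robust correlation is the target up to sampling error.
#'
#' @param metabolome sample-level metabolite [phenotype_table()].
#' @param config a [sim_config()]; uses `trait_targets` (default: 5 traits
#'   correlated at rho 0.5-0.8 with the first metabolites plus 5 null
#'   traits).
#' @return list with `table` (strain-level [phenotype_table()]) and
#'   `targets` (the resolved target data.frame).
#' @export
simulate_clinical_traits <- function(metabolome, config) {
  set.seed(derive_seed(config$seed, "traits"))
  targets <- config$trait_targets
  if (is.null(targets))
    targets <- data.frame(trait = sprintf("trait%02d", 1:5),
                          metabolite = 1:5,
                          rho = c(0.8, 0.7, 0.6, 0.5, 0.5))
  if (any(abs(targets$rho) >= 1)) stop("|rho| must be < 1")
  n_traits <- max(10, nrow(targets) + 5)
  traits <- sprintf("trait%02d", seq_len(n_traits))
  if (!is.null(metabolome$runday_of_sample))
    metabolome <- normalize_run_days(metabolome)
  strain_tab <- average_strain_replicates(metabolome)
  zv <- scale(strain_tab$values)
  n <- nrow(zv)
  tv <- matrix(stats::rnorm(n * n_traits), n, n_traits,
               dimnames = list(rownames(zv), traits))
  for (r in seq_len(nrow(targets))) {
    zm <- zv[, targets$metabolite[r]]
    zm[is.na(zm)] <- 0
    tv[, targets$trait[r]] <- targets$rho[r] * zm +
      sqrt(1 - targets$rho[r]^2) * stats::rnorm(n)
  }
  list(table = phenotype_table(tv, rownames(zv)),
       targets = data.frame(trait = targets$trait,
                            metabolite = sprintf("met%03d", targets$metabolite),
                            rho = targets$rho))
}

#' Simulate a synteny map covering the simulated mouse genome
#'
#' Each simulated mouse chromosome is split into two blocks, each mapped
#' to an interval of a (deterministic) human chromosome with a fixed
#' offset, so every mouse locus has a syntenic human interval.
#'
#' @param g `genotype_matrix`.
#' @param config a [sim_config()].
#' @return synteny map data.frame (6 columns, 1-based inclusive).
#' @export
simulate_synteny_map <- function(g, config) {
  chr <- unique(g$chrom)
  out <- NULL
  for (c_i in chr) {
    len <- max(g$pos[g$chrom == c_i]) + config$snp_spacing
    half <- floor(len / 2)
    hchr <- as.character(((as.integer(c_i) * 7L) %% 22L) + 1L)
    out <- rbind(out,
      data.frame(mouse_chrom = c_i, mouse_start = 1, mouse_end = half,
                 human_chrom = hchr, human_start = 1e6,
                 human_end = 1e6 + half - 1),
      data.frame(mouse_chrom = c_i, mouse_start = half + 1, mouse_end = len,
                 human_chrom = hchr, human_start = 5e7,
                 human_end = 5e7 + (len - half) - 1))
  }
  out
}

#' Simulate a human GWAS summary with a configured replication fraction
#'
#' For each planted mouse locus, the mouse interval (peak +/- 1 Mb) is
#' mapped through the synteny map; with probability `replicate_fraction`
#' the locus is "replicated" and a record with p well below the Bonferroni
#' threshold `0.05 / n_loci` is placed inside a mapped human interval (in
#' one or both populations); otherwise its records carry p uniform on
#' (2 x threshold, 1], kept clear of the threshold so the realized
#' replication status equals the drawn flag by construction.
#'
#' @param truth the `qtl_map` data.frame from [simulate_metabolome()]
#'   (columns `phenotype, chrom, pos` are used; one locus per row).
#' @param synteny_map 6-column synteny data.frame.
#' @param config a [sim_config()].
#' @return data.frame `metabolite_id, human_chrom, human_pos, p_value,
#'   population` with attribute `replicated` (logical per locus, named by
#'   phenotype).
#' @export
simulate_human_summary <- function(truth, synteny_map, config) {
  set.seed(derive_seed(config$seed, "human"))
  n_loci <- nrow(truth)
  stopifnot(n_loci >= 1)
  rep_flag <- stats::runif(n_loci) < config$replicate_fraction
  thr <- 0.05 / n_loci
  pops <- config$human_populations
  out <- NULL
  for (i in seq_len(n_loci)) {
    iv <- map_to_syntenic_intervals(
      list(chrom = truth$chrom[i],
           start = max(1, truth$pos[i] - 1e6), end = truth$pos[i] + 1e6),
      synteny_map)
    if (nrow(iv) == 0) {
      if (rep_flag[i])
        stop("planted locus with no syntenic mapping cannot replicate")
      next
    }
    for (pop in pops) {
      inside <- stats::runif(1, iv$human_start[1], iv$human_end[1])
      if (rep_flag[i] && (pop == pops[1] || stats::runif(1) < 0.5)) {
        p <- 10^(-stats::runif(1, 5, 12))
      } else {
        p <- stats::runif(1, min(2 * thr, 0.5), 1)
      }
      out <- rbind(out, data.frame(
        metabolite_id = truth$phenotype[i],
        human_chrom = iv$human_chrom[1],
        human_pos = round(inside), p_value = p, population = pop))
    }
  }
  attr(out, "replicated") <- stats::setNames(rep_flag, truth$phenotype)
  out
}
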