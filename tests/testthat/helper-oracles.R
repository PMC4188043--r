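# Independent brute-force oracles and shared fixtures. The oracles here
# transcribe each definition directly (double loops, no shared code with
# the implementation under test).

# identity-by-state kinship by double loop over strain pairs and SNPs
ibs_kinship_ref <- function(dosage) {
  n <- nrow(dosage)
  K <- matrix(NA_real_, n, n, dimnames = list(rownames(dosage), rownames(dosage)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(dosage[i, ]) & !is.na(dosage[j, ])
    K[i, j] <- mean(1 - abs(dosage[i, ok] - dosage[j, ok]) / 2)
  }
  diag(K) <- 1
  K
}

# biweight midcorrelation transcribed from the defining formula
bicor_ref <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  part <- function(v) {
    med <- median(v); mad0 <- median(abs(v - med))
    if (mad0 == 0) return(list(c = v - mean(v), w = rep(1, length(v))))
    u <- (v - med) / (9 * mad0)
    list(c = v - med, w = (1 - u^2)^2 * (abs(u) < 1))
  }
  a <- part(x); b <- part(y)
  sum(a$w * b$w * a$c * b$c) /
    sqrt(sum((a$w * a$c)^2) * sum((b$w * b$c)^2))
}

# squared Pearson correlation from first principles
r2_ref <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  num <- sum((a - mean(a)) * (b - mean(b)))
  (num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
}

# exhaustive "best SNP per connected R^2 > thr component" locus collapsing
collapse_components_ref <- function(records, g, thr = 0.5) {
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    if (records$chrom[i] != records$chrom[j]) next
    r2 <- tryCatch(genotype_r2(g$dosage[, records$snp_id[i]],
                               g$dosage[, records$snp_id[j]]),
                   error = function(e) 0)
    adj[i, j] <- r2 > thr
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    if (!changed) break
  }
  sapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    records$snp_id[idx[which.min(records$p[idx])]]
  })
}

# is every R^2>thr component a clique? (where greedy and component
# collapsing provably coincide)
components_are_cliques <- function(records, g, thr = 0.5) {
  n <- nrow(records)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    if (records$chrom[i] != records$chrom[j]) next
    r2 <- tryCatch(genotype_r2(g$dosage[, records$snp_id[i]],
                               g$dosage[, records$snp_id[j]]),
                   error = function(e) 0)
    adj[i, j] <- r2 > thr
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n))
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    if (!changed) break
  }
  all(sapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    all(adj[idx, idx])
  }))
}

# tiny genotype fixture wrapper
make_geno <- function(dosage, chrom = NULL, pos = NULL) {
  S <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("s%03d", seq_len(S))
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("st%02d", seq_len(nrow(dosage)))
  if (is.null(chrom)) chrom <- rep("1", S)
  if (is.null(pos)) pos <- seq_len(S) * 1e5
  genotype_matrix(colnames(dosage), chrom, pos, dosage)
}

# ---- memoised shared panels (built once per test run) ------------------
.panel_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .panel_cache))
    assign(key, builder(), envir = .panel_cache)
  get(key, envir = .panel_cache)
}

# default study panel: 100 strains, ~2000 SNPs, 40 metabolites with 12
# planted QTL at PVE 0.3/0.5/0.7
default_panel <- function() memo("default", function() {
  cfg <- sim_config(seed = 2024)
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  z <- preprocess_phenotypes(met$table)
  K <- compute_ibs_kinship(g)
  list(cfg = cfg, g = g, met = met, z = z, K = K)
})

# structured null panel: 100 strains, 2000 SNPs, 50 metabolites with no
# planted signal; mixed-model and naive OLS scans of every metabolite
null_panel <- function() memo("null", function() {
  cfg <- sim_config(seed = 11, n_metabolites = 50,
                    planted_qtls = data.frame(phenotype = integer(0),
                                              snp = integer(0),
                                              pve = numeric(0)))
  g <- simulate_genotypes(cfg)
  met <- simulate_metabolome(g, cfg)
  z <- preprocess_phenotypes(met$table)
  K <- compute_ibs_kinship(g)
  p_mixed <- c(); p_ols <- c()
  for (v in z$variables) {
    y <- z$zvalues[, v]; names(y) <- rownames(z$zvalues)
    p_mixed <- c(p_mixed, association_scan(y, g, K, mode = "null_approx")$p)
    p_ols <- c(p_ols, naive_ols_scan(y, g)$p)
  }
  list(cfg = cfg, g = g, z = z, K = K, p_mixed = p_mixed, p_ols = p_ols)
})
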