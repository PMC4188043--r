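# Shared data containers and the TSV dialects every stage consumes.
#
# Conventions used throughout the package:
#   * coordinates are 1-based, intervals inclusive on both ends;
#   * the missing sentinel in TSV files is the literal "NA" (empty cells
#     are rejected rather than guessed at);
#   * strains are the unit of analysis; sample-level tables are collapsed
#     to strains in preprocessing, never inside the model code;
#   * dosages are 0/2 homozygous codings; a heterozygous 1 (interpolated
#     recombinant-inbred genotypes) is accepted and used as-is.

#' Construct a genotype matrix
#'
#' @param snp_ids character SNP identifiers.
#' @param chrom chromosome label per SNP.
#' @param pos 1-based base-pair position per SNP.
#' @param dosage strains x SNPs numeric matrix with values in
#'   \{0, 1, 2, NA\}; rownames are strain identifiers.
#' @return an object of class `genotype_matrix` with fields `snp_ids`,
#'   `chrom`, `pos`, `strains`, `dosage` (strains x SNPs) and `maf`
#'   (minor-allele frequency over nonmissing strains), sorted by
#'   (chrom, pos).
#' @export
genotype_matrix <- function(snp_ids, chrom, pos, dosage) {
  stopifnot(is.matrix(dosage), ncol(dosage) == length(snp_ids),
            length(chrom) == length(snp_ids), length(pos) == length(snp_ids))
  if (any(pos <= 0)) stop("SNP positions must be strictly positive")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage values must be in {0, 1, 2, NA}")
  if (is.null(rownames(dosage))) stop("dosage must carry strain rownames")
  o <- .chrom_order(chrom, pos, snp_ids)
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- snp_ids[o]
  g <- list(snp_ids = as.character(snp_ids[o]),
            chrom = as.character(chrom[o]),
            pos = as.numeric(pos[o]),
            strains = rownames(dosage),
            dosage = dosage,
            maf = compute_maf(dosage))
  class(g) <- "genotype_matrix"
  g
}

#' Minor-allele frequency per SNP
#'
#' Allele frequency of the reference (dosage-2) allele over nonmissing
#' strains, folded to the minor allele. Heterozygous dosage 1 contributes
#' half an allele.
#'
#' @param dosage strains x SNPs dosage matrix.
#' @return numeric vector in [0, 0.5].
#' @export
compute_maf <- function(dosage) {
  f <- colMeans(dosage / 2, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- NA_real_
  maf
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d SNPs on %d chromosome(s)\n",
              length(x$strains), length(x$snp_ids),
              length(unique(x$chrom))))
  invisible(x)
}

#' Subset a genotype matrix to SNPs above a minor-allele-frequency cutoff
#'
#' @param g `genotype_matrix`.
#' @param maf_min frequency cutoff; SNPs with maf strictly greater are kept
#'   (default 0.05, the conventional >5% panel filter).
#' @return filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, maf_min = 0.05) {
  keep <- !is.na(g$maf) & g$maf > maf_min
  subset_snps(g, which(keep))
}

#' @keywords internal
subset_snps <- function(g, idx) {
  out <- list(snp_ids = g$snp_ids[idx], chrom = g$chrom[idx],
              pos = g$pos[idx], strains = g$strains,
              dosage = g$dosage[, idx, drop = FALSE], maf = g$maf[idx])
  for (a in setdiff(names(attributes(g)), c("names", "class")))
    attr(out, a) <- attr(g, a)
  class(out) <- "genotype_matrix"
  out
}

#' Construct a sample-level phenotype table
#'
#' @param values samples x variables numeric matrix; rownames are sample
#'   ids, colnames variable ids. NA allowed.
#' @param strain_of_sample strain label per sample.
#' @param class_of_variable named character vector mapping every variable
#'   to its class (e.g. the eight metabolite classes); optional for
#'   transcript/trait tables.
#' @param runday_of_sample optional run-day (batch) label per sample.
#' @return object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, strain_of_sample,
                            class_of_variable = NULL,
                            runday_of_sample = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            length(strain_of_sample) == nrow(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample_id in phenotype table")
  if (!is.null(class_of_variable)) {
    missing_cls <- setdiff(colnames(values), names(class_of_variable))
    if (length(missing_cls))
      stop("variables absent from class map: ",
           paste(utils::head(missing_cls, 5), collapse = ", "))
    class_of_variable <- class_of_variable[colnames(values)]
  }
  if (!is.null(runday_of_sample))
    stopifnot(length(runday_of_sample) == nrow(values))
  t <- list(sample_ids = rownames(values),
            strain_of_sample = stats::setNames(as.character(strain_of_sample),
                                               rownames(values)),
            runday_of_sample = if (is.null(runday_of_sample)) NULL else
              stats::setNames(as.character(runday_of_sample), rownames(values)),
            variables = colnames(values),
            class_of_variable = class_of_variable,
            values = values)
  class(t) <- "phenotype_table"
  t
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples (%d strains) x %d variables\n",
              length(x$sample_ids), length(unique(x$strain_of_sample)),
              length(x$variables)))
  invisible(x)
}

#' Read a genotype TSV
#'
#' Expected header: `snp_id`, `chrom`, `pos`, then one column per strain.
#' Dosages are 0/1/2 with `NA` for missing; anything else is a parse error
#' naming the offending line.
#'
#' @param path file path.
#' @return `genotype_matrix` sorted by (chrom, pos) with maf computed.
#' @export
read_genotype_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  need <- c("snp_id", "chrom", "pos")
  if (!identical(colnames(d)[1:3], need))
    .stop_parse(path, 1L, paste0("header must start with '",
                                 paste(need, collapse = "\t"), "'"))
  if (ncol(d) < 4L) .stop_parse(path, 1L, "no strain columns")
  strains <- colnames(d)[-(1:3)]
  pos <- suppressWarnings(as.numeric(d$pos))
  if (anyNA(pos))
    .stop_parse(path, which(is.na(pos))[1] + 1L, "non-numeric pos")
  raw <- as.matrix(d[, -(1:3), drop = FALSE])
  if (any(raw == "" | is.na(raw))) {
    i <- which(raw == "" | is.na(raw), arr.ind = TRUE)[1, 1]
    .stop_parse(path, i + 1L, "empty dosage cell (missing must be 'NA')")
  }
  dm <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  dm[raw == "NA"] <- NA_real_
  bad <- which(!(dm %in% c(0, 1, 2)) & raw != "NA")
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(raw))[1, 1]
    .stop_parse(path, i + 1L,
                sprintf("dosage '%s' outside {0,1,2,NA}", raw[bad[1]]))
  }
  dosage <- t(dm)
  rownames(dosage) <- strains
  genotype_matrix(d$snp_id, d$chrom, pos, dosage)
}

#' Write a genotype TSV (inverse of [read_genotype_table()])
#' @param g `genotype_matrix`.
#' @param path output path.
#' @export
write_genotype_table <- function(g, path) {
  d <- data.frame(snp_id = g$snp_ids, chrom = g$chrom,
                  pos = format(g$pos, scientific = FALSE, trim = TRUE),
                  t(g$dosage), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-level phenotype TSV plus its variable-class map
#'
#' The phenotype file has columns `sample_id`, `strain`, optionally
#' `runday`, then one column per variable. The companion class file is a
#' two-column TSV `variable`, `class`; every data variable must appear in
#' it.
#'
#' @param path phenotype TSV.
#' @param class_path optional two-column class-map TSV.
#' @return `phenotype_table`.
#' @export
read_phenotype_table <- function(path, class_path = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (colnames(d)[1] != "sample_id" || colnames(d)[2] != "strain")
    .stop_parse(path, 1L, "header must start with 'sample_id\tstrain'")
  has_runday <- ncol(d) >= 3 && colnames(d)[3] == "runday"
  meta_n <- if (has_runday) 3L else 2L
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id in '", path, "'")
  vars <- colnames(d)[-(1:meta_n)]
  raw <- as.matrix(d[, -(1:meta_n), drop = FALSE])
  if (any(raw == "")) {
    i <- which(raw == "", arr.ind = TRUE)[1, 1]
    .stop_parse(path, i + 1L, "empty cell (missing must be 'NA')")
  }
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                  dimnames = list(d$sample_id, vars)))
  nonnum <- which(is.na(vals) & raw != "NA")
  if (length(nonnum)) {
    i <- arrayInd(nonnum[1], dim(raw))[1, 1]
    .stop_parse(path, i + 1L, sprintf("non-numeric value '%s'", raw[nonnum[1]]))
  }
  cls <- NULL
  if (!is.null(class_path)) {
    cm <- utils::read.delim(class_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("variable", "class") %in% colnames(cm)))
      .stop_parse(class_path, 1L, "class map needs columns variable, class")
    cls <- stats::setNames(cm$class, cm$variable)
  }
  phenotype_table(vals, d$strain, class_of_variable = cls,
                  runday_of_sample = if (has_runday) d$runday else NULL)
}

#' Write a phenotype table and (optionally) its class map
#' @param t `phenotype_table`.
#' @param path output TSV.
#' @param class_path optional path for the variable-class map.
#' @export
write_phenotype_table <- function(t, path, class_path = NULL) {
  d <- data.frame(sample_id = t$sample_ids,
                  strain = unname(t$strain_of_sample),
                  check.names = FALSE)
  if (!is.null(t$runday_of_sample)) d$runday <- unname(t$runday_of_sample)
  d <- cbind(d, as.data.frame(t$values, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(class_path) && !is.null(t$class_of_variable))
    utils::write.table(
      data.frame(variable = names(t$class_of_variable),
                 class = unname(t$class_of_variable)),
      class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association records
#'
#' Stable column order `phenotype, snp_id, chrom, pos, beta, f_stat, p[, q]`,
#' rows sorted by (phenotype, chrom, pos), full float precision.
#'
#' @param records association data.frame (see [association_scan()]).
#' @param path output TSV.
#' @export
write_association_results <- function(records, path) {
  cols <- c("phenotype", "snp_id", "chrom", "pos", "beta", "f_stat", "p")
  if ("q" %in% colnames(records)) cols <- c(cols, "q")
  if (nrow(records)) {
    o <- order(records$phenotype,
               xtfrm(factor(records$chrom,
                            unique(records$chrom[.chrom_order(records$chrom,
                                                              records$pos)]))),
               records$pos)
    records <- records[o, cols, drop = FALSE]
  } else records <- records[, cols, drop = FALSE]
  num <- vapply(records, is.numeric, TRUE)
  records[num] <- lapply(records[num], function(x)
    format(x, digits = 17, scientific = TRUE, trim = TRUE))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read association records written by [write_association_results()]
#' @param path TSV path.
#' @return data.frame of association records.
#' @export
read_association_results <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  for (col in intersect(c("pos", "beta", "f_stat", "p", "q"), colnames(d)))
    d[[col]] <- as.numeric(d[[col]])
  d
}

#' Read a gene annotation table (4-column BED-like TSV)
#'
#' Columns `gene_id, chrom, start, end`, 1-based inclusive.
#' @param path TSV path.
#' @return data.frame with validated start <= end.
#' @export
read_gene_annotation <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (!all(c("gene_id", "chrom", "start", "end") %in% colnames(d)))
    .stop_parse(path, 1L, "annotation needs gene_id, chrom, start, end")
  d$start <- as.numeric(d$start); d$end <- as.numeric(d$end)
  if (any(d$start > d$end)) stop("gene annotation with start > end")
  d
}

#' Read a 6-column synteny map TSV
#'
#' Columns `mouse_chrom, mouse_start, mouse_end, human_chrom, human_start,
#' human_end`; intervals 1-based inclusive.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_synteny_map <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  need <- c("mouse_chrom", "mouse_start", "mouse_end",
            "human_chrom", "human_start", "human_end")
  if (!all(need %in% colnames(d)))
    .stop_parse(path, 1L, paste("synteny map needs", paste(need, collapse = ", ")))
  for (col in grep("start|end", need, value = TRUE)) d[[col]] <- as.numeric(d[[col]])
  if (any(d$mouse_start > d$mouse_end) || any(d$human_start > d$human_end))
    stop("synteny map with start > end")
  d
}

#' Read a human GWAS summary table
#'
#' Columns `metabolite_id, human_chrom, human_pos, p_value, population`.
#' @param path TSV path.
#' @return data.frame with p validated in (0, 1].
#' @export
read_human_gwas <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  need <- c("metabolite_id", "human_chrom", "human_pos", "p_value", "population")
  if (!all(need %in% colnames(d)))
    .stop_parse(path, 1L, paste("human summary needs", paste(need, collapse = ", ")))
  d$human_pos <- as.numeric(d$human_pos)
  d$p_value <- as.numeric(d$p_value)
  if (any(!is.finite(d$p_value) | d$p_value <= 0 | d$p_value > 1))
    stop("human GWAS p-values must lie in (0, 1]")
  d
}

#' Write / read a kinship matrix as a square TSV with a strain header
#' @param K square kinship matrix with strain dimnames.
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  d <- data.frame(strain = rownames(K), K, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d$strain
  K
}
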