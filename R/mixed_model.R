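# Linear mixed model for association mapping on inbred strain panels.
#
# Model: y = mu + x*beta + u + e, with Var(u) = sigma_g^2 * K (K the
# identity-by-state kinship across all genotypes) and Var(e) = sigma_e^2.
# The variance ratio delta = sigma_e^2 / sigma_g^2 is estimated by REML
# using a one-time spectral decomposition of K: the restricted
# log-likelihood is evaluated on a 100-point log-spaced grid over
# 10^-5..10^5 and every sign-change bracket is refined by derivative-free
# scalar optimization. Association per SNP is generalized least squares
# under Sigma = sigma_g^2 K + sigma_e^2 I with a standard F-test (1, n-2)
# of beta != 0; the default "exact" mode refits REML for every SNP design
# [1, g], the "null_approx" mode estimates delta once under the
# intercept-only design and reuses it.

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean, over SNPs nonmissing in both strains, of
#' `1 - |g_i - g_j| / 2`; identical homozygous genotypes score 1, opposite
#' homozygotes 0, and a heterozygous dosage 1 half-matches either
#' homozygote. The diagonal is exactly 1.
#'
#' @param g `genotype_matrix`.
#' @return symmetric strains x strains matrix in [0, 1] with strain
#'   dimnames.
#' @export
compute_ibs_kinship <- function(g) {
  X <- g$dosage
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  M <- !is.na(X)
  A0 <- (X == 0 & M); A0[is.na(A0)] <- FALSE; storage.mode(A0) <- "double"
  A1 <- (X == 1 & M); A1[is.na(A1)] <- FALSE; storage.mode(A1) <- "double"
  A2 <- (X == 2 & M); A2[is.na(A2)] <- FALSE; storage.mode(A2) <- "double"
  Mm <- M; storage.mode(Mm) <- "double"
  N <- tcrossprod(Mm)
  if (any(N[upper.tri(N)] == 0))
    stop("strain pair with zero shared nonmissing SNPs")
  D01 <- tcrossprod(A0, A1); D12 <- tcrossprod(A1, A2)
  D02 <- tcrossprod(A0, A2)
  D <- (D01 + t(D01) + D12 + t(D12)) + 2 * (D02 + t(D02))
  K <- 1 - D / (2 * N)
  diag(K) <- 1
  dimnames(K) <- list(g$strains, g$strains)
  K
}

# Spectral precomputation shared by all REML evaluations on one strain
# subset. K is stabilized by shifting all eigenvalues up by 1e-6 when the
# smallest is below 1e-8 (equivalent to adding 1e-6 to the diagonal).
.kinship_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  d <- e$values
  if (min(d) < 1e-8) d <- d + 1e-6
  if (min(d) <= 0)
    stop("kinship matrix is not positive semi-definite after stabilization")
  list(U = e$vectors, d = d)
}

.DELTA_GRID <- 10^seq(-5, 5, length.out = 100)

# Restricted log-likelihood profile in delta for rotated data.
# ty = U'y, tX = U'X, d = eigenvalues, ldXtX = log det(X'X).
.rll <- function(delta, ty, tX, d, ldXtX) {
  n <- length(ty); q <- ncol(tX); nq <- n - q
  w <- 1 / (d + delta)
  A <- crossprod(tX, tX * w)
  b <- crossprod(tX, ty * w)
  Ai <- solve(A, b)
  yPy <- max(sum(w * ty^2) - sum(b * Ai), .P_FLOOR)
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(yPy) -
           sum(log(d + delta)) - determinant(A)$modulus[1] + ldXtX)
}

#' REML variance components for the mixed model
#'
#' Maximizes the restricted likelihood over `delta = sigma_e^2/sigma_g^2`
#' on a log grid (10^-5..10^5, 100 points) using a one-time spectral
#' decomposition of the kinship, then refines each local maximum by
#' derivative-free scalar optimization to |d log10 delta| < 1e-6.
#' Boundary solutions (grid ends) are returned with `converged = TRUE`
#' and `boundary = TRUE`.
#'
#' @param y phenotype vector (no missing values; align and subset first).
#' @param X fixed-effect design matrix, full column rank (include the
#'   intercept column).
#' @param K kinship matrix aligned with `y`.
#' @param eig optional precomputed [.kinship_eigen()] result.
#' @return list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `reml_loglik`, `converged`, `boundary`.
#' @export
reml_fit <- function(y, X, K, eig = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(K) == n, !anyNA(y), !anyNA(X))
  if (n <= ncol(X) + 1) stop("too few observations for REML")
  if (qr(X)$rank < ncol(X)) stop("design matrix X is rank deficient")
  if (is.null(eig)) eig <- .kinship_eigen(K)
  ty <- drop(crossprod(eig$U, y))
  tX <- crossprod(eig$U, X)
  ldXtX <- determinant(crossprod(X))$modulus[1]
  f <- function(l10) .rll(10^l10, ty, tX, eig$d, ldXtX)
  lg <- log10(.DELTA_GRID)
  vals <- vapply(lg, f, 0)
  best_l <- lg[which.max(vals)]; best_v <- max(vals)
  boundary <- which.max(vals) %in% c(1L, length(lg))
  # refine every interior local maximum of the grid profile
  loc <- which(diff(sign(diff(vals))) < 0) + 1L
  for (i in loc) {
    o <- stats::optimize(f, lower = lg[i - 1L], upper = lg[i + 1L],
                         maximum = TRUE, tol = 1e-6)
    if (isTRUE(o$objective > best_v)) {
      best_v <- o$objective; best_l <- o$maximum; boundary <- FALSE
    }
  }
  delta <- 10^best_l
  q <- ncol(tX); w <- 1 / (eig$d + delta)
  A <- crossprod(tX, tX * w)
  b <- crossprod(tX, ty * w)
  yPy <- max(sum(w * ty^2) - sum(b * solve(A, b)), .P_FLOOR)
  sigma_g2 <- drop(yPy) / (n - q)
  out <- list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
              delta = delta, reml_loglik = best_v, converged = TRUE,
              boundary = boundary)
  class(out) <- "variance_components"
  out
}

# Generalized-least-squares fit of X = [1, g] at a fixed delta, vectorized
# across the SNP columns of tG (rotated dosages). Returns per-SNP beta,
# F and p with (1, n-2) degrees of freedom.
.gls_scan_at_delta <- function(delta, ty, t1, tG, d, n) {
  w <- 1 / (outer(d, delta, "+"))            # n x S when delta varies
  if (is.null(dim(w))) w <- matrix(w, length(d), ncol(tG))
  if (ncol(w) == 1L) w <- w[, rep(1L, ncol(tG)), drop = FALSE]
  a11 <- colSums(w * t1^2)
  a1g <- colSums(w * t1 * tG)
  agg <- colSums(w * tG^2)
  a1y <- colSums(w * t1 * ty)
  agy <- colSums(w * ty * tG)
  ayy <- colSums(w * ty^2)
  detA <- a11 * agg - a1g^2
  yPy <- pmax(ayy - (agg * a1y^2 - 2 * a1g * a1y * agy + a11 * agy^2) / detA,
              .P_FLOOR)
  beta <- (a11 * agy - a1g * a1y) / detA
  sigma_g2 <- yPy / (n - 2)
  varb <- sigma_g2 * a11 / detA
  fstat <- beta^2 / varb
  p <- pmax(stats::pf(fstat, 1, n - 2, lower.tail = FALSE), .P_FLOOR)
  list(beta = beta, f_stat = fstat, p = p, sigma_g2 = sigma_g2,
       intercept = (agg * a1y - a1g * agy) / detA)
}

# Per-SNP exact REML profile, vectorized over SNPs: rll matrix over the
# delta grid, then per-SNP refinement of the grid argmax bracket.
.exact_deltas <- function(ty, t1, tG, d, n) {
  S <- ncol(tG); nq <- n - 2
  lg <- log10(.DELTA_GRID)
  sum_g <- colSums((t1 * tG)) # note: t1 = U'1; Sum g = 1'g = (U'1)'(U'g)
  sum_gg <- colSums(tG^2)
  ldXtX <- log(pmax(n * sum_gg - sum_g^2, .Machine$double.eps))
  rllm <- matrix(NA_real_, S, length(lg))
  for (k in seq_along(lg)) {
    delta <- 10^lg[k]
    w <- 1 / (d + delta)
    a11 <- sum(w * t1^2)
    a1g <- colSums(w * t1 * tG)
    agg <- colSums(w * tG^2)
    a1y <- sum(w * t1 * ty)
    agy <- colSums(w * ty * tG)
    ayy <- sum(w * ty^2)
    detA <- a11 * agg - a1g^2
    yPy <- pmax(ayy - (agg * a1y^2 - 2 * a1g * a1y * agy + a11 * agy^2) / detA,
                .P_FLOOR)
    rllm[, k] <- 0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(yPy) -
                          sum(log(d + delta)) - log(detA) + ldXtX)
  }
  deltas <- numeric(S)
  for (s in seq_len(S)) {
    v <- rllm[s, ]
    i <- which.max(v)
    if (i == 1L || i == length(lg)) { deltas[s] <- 10^lg[i]; next }
    tg_s <- tG[, s]; ld_s <- ldXtX[s]
    fs <- function(l10) {
      delta <- 10^l10; w <- 1 / (d + delta)
      a11 <- sum(w * t1^2); a1g <- sum(w * t1 * tg_s)
      agg <- sum(w * tg_s^2); a1y <- sum(w * t1 * ty)
      agy <- sum(w * ty * tg_s); ayy <- sum(w * ty^2)
      detA <- a11 * agg - a1g^2
      yPy <- max(ayy - (agg * a1y^2 - 2 * a1g * a1y * agy + a11 * agy^2) / detA,
                 .P_FLOOR)
      0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(yPy) -
               sum(log(d + delta)) - log(detA) + ld_s)
    }
    o <- stats::optimize(fs, lower = lg[i - 1L], upper = lg[i + 1L],
                         maximum = TRUE, tol = 1e-6)
    deltas[s] <- if (isTRUE(o$objective >= v[i])) 10^o$maximum else 10^lg[i]
  }
  deltas
}

#' Mixed-model association scan of one phenotype against all SNPs
#'
#' Strains missing the phenotype are dropped once; SNPs missing genotypes
#' in the remaining strains are handled per missingness pattern (kinship
#' is computed once on all strains and subset per test). SNPs monomorphic
#' after casewise deletion are skipped with a message. P-values are
#' floored at 1e-300.
#'
#' @param y named phenotype vector (names are strains) or a single-column
#'   matrix.
#' @param g `genotype_matrix` (minor-allele-frequency filter assumed
#'   applied).
#' @param K kinship matrix over at least the strains of `y`.
#' @param mode `"exact"` refits REML per SNP design (the default);
#'   `"null_approx"` estimates delta once under the intercept-only model
#'   and reuses it (documented approximation, much faster).
#' @param phenotype_id label stored in the output records.
#' @return data.frame of association records: `phenotype, snp_id, chrom,
#'   pos, beta, f_stat, p, n_used`.
#' @export
association_scan <- function(y, g, K, mode = c("exact", "null_approx"),
                             phenotype_id = "phenotype") {
  mode <- match.arg(mode)
  if (is.matrix(y)) y <- y[, 1]
  stopifnot(!is.null(names(y)))
  keep <- names(y)[!is.na(y)]
  keep <- intersect(keep, g$strains)
  n <- length(keep)
  if (n < 3) stop("fewer than 3 strains with nonmissing phenotype")
  yv <- y[keep]
  Ks <- K[keep, keep]
  G <- g$dosage[keep, , drop = FALSE]
  eig <- .kinship_eigen(Ks)
  ty <- drop(crossprod(eig$U, yv))
  t1 <- drop(crossprod(eig$U, rep(1, n)))
  miss_pattern <- apply(is.na(G), 2, function(z) paste(which(z), collapse = ","))
  out <- vector("list", 0L)
  delta0 <- if (mode == "null_approx")
    reml_fit(yv, matrix(1, n, 1), Ks, eig = eig)$delta else NA_real_
  for (pat in unique(miss_pattern)) {
    idx <- which(miss_pattern == pat)
    if (pat == "") {
      rows <- seq_len(n); eig_p <- eig; ty_p <- ty; t1_p <- t1
      Kp <- NULL; yp <- yv
    } else {
      rows <- setdiff(seq_len(n), as.integer(strsplit(pat, ",")[[1]]))
      if (length(rows) < 3) {
        message(sprintf("skipping %d SNP(s): fewer than 3 strains after casewise deletion",
                        length(idx)))
        next
      }
      Kp <- Ks[rows, rows]
      eig_p <- .kinship_eigen(Kp)
      yp <- yv[rows]
      ty_p <- drop(crossprod(eig_p$U, yp))
      t1_p <- drop(crossprod(eig_p$U, rep(1, length(rows))))
    }
    Gp <- G[rows, idx, drop = FALSE]
    mono <- apply(Gp, 2, function(x) stats::var(x) == 0)
    if (any(mono)) {
      message(sprintf("skipping %d monomorphic SNP(s) after casewise deletion",
                      sum(mono)))
      idx <- idx[!mono]; Gp <- Gp[, !mono, drop = FALSE]
    }
    if (!length(idx)) next
    tG <- crossprod(eig_p$U, Gp)
    np <- length(rows)
    deltas <- if (mode == "exact")
      .exact_deltas(ty_p, t1_p, tG, eig_p$d, np)
    else rep(delta0, ncol(tG))
    fit <- .gls_scan_at_delta(deltas, ty_p, t1_p, tG, eig_p$d, np)
    out[[length(out) + 1L]] <- data.frame(
      phenotype = phenotype_id, snp_id = g$snp_ids[idx],
      chrom = g$chrom[idx], pos = g$pos[idx],
      beta = fit$beta, f_stat = fit$f_stat, p = fit$p,
      n_used = np, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(phenotype = character(0), snp_id = character(0),
                      chrom = character(0), pos = numeric(0),
                      beta = numeric(0), f_stat = numeric(0),
                      p = numeric(0), n_used = integer(0)))
  res[.chrom_order(res$chrom, res$pos, res$snp_id), , drop = FALSE]
}

#' Scan many phenotypes and pool the records
#'
#' @param z strains x phenotypes matrix (e.g. `zvalues` of a
#'   [standardize()] result) with strain rownames.
#' @inheritParams association_scan
#' @return pooled association data.frame.
#' @export
scan_phenotypes <- function(z, g, K, mode = c("exact", "null_approx")) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(colnames(z), function(v)
    association_scan(z[, v], g, K, mode = mode, phenotype_id = v)))
}

#' Naive ordinary-least-squares scan (no kinship correction)
#'
#' The uncorrected comparator: per-SNP simple regression F-test. Used to
#' demonstrate the inflation that population structure induces and that
#' the mixed model removes.
#'
#' @inheritParams association_scan
#' @return data.frame `snp_id, chrom, pos, beta, f_stat, p, n_used`.
#' @export
naive_ols_scan <- function(y, g, phenotype_id = "phenotype") {
  if (is.matrix(y)) y <- y[, 1]
  keep <- intersect(names(y)[!is.na(y)], g$strains)
  yv <- y[keep]
  G <- g$dosage[keep, , drop = FALSE]
  n_used <- colSums(!is.na(G))
  r <- suppressWarnings(stats::cor(yv, G, use = "pairwise.complete.obs"))[1, ]
  ok <- is.finite(r) & n_used >= 3
  fstat <- r^2 * (n_used - 2) / pmax(1 - r^2, .Machine$double.eps)
  p <- pmax(stats::pf(fstat, 1, n_used - 2, lower.tail = FALSE), .P_FLOOR)
  sdg <- apply(G, 2, stats::sd, na.rm = TRUE)
  data.frame(phenotype = phenotype_id, snp_id = g$snp_ids[ok],
             chrom = g$chrom[ok], pos = g$pos[ok],
             beta = (r * stats::sd(yv) / sdg)[ok],
             f_stat = fstat[ok], p = p[ok], n_used = n_used[ok],
             stringsAsFactors = FALSE)
}

#' Percent variance explained by one SNP
#'
#' Fits the mixed model for the single-SNP design `[1, g]`, forms
#' fixed-effects-only residuals `y - X beta_hat` (the random-effect BLUP
#' is deliberately not subtracted, which would conflate kinship signal
#' with the SNP effect) and returns `1 - var(residuals)/var(y)`. May be
#' negative for null SNPs; negative values are kept and flagged via the
#' `"negative"` attribute.
#'
#' @param y named phenotype vector.
#' @param gdose named dosage vector for one SNP.
#' @param K kinship matrix.
#' @return scalar PVE.
#' @export
variance_explained <- function(y, gdose, K) {
  keep <- names(y)[!is.na(y) & !is.na(gdose[names(y)])]
  yv <- y[keep]; gv <- gdose[keep]
  if (stats::var(yv) == 0) stop("phenotype has zero variance")
  Ks <- K[keep, keep]
  eig <- .kinship_eigen(Ks)
  fit <- reml_fit(yv, cbind(1, gv), Ks, eig = eig)
  w <- 1 / (eig$d + fit$delta)
  tX <- crossprod(eig$U, cbind(1, gv))
  ty <- drop(crossprod(eig$U, yv))
  A <- crossprod(tX, tX * w)
  beta <- solve(A, crossprod(tX, ty * w))
  resid <- yv - drop(cbind(1, gv) %*% beta)
  pve <- 1 - stats::var(resid) / stats::var(yv)
  attr(pve, "negative") <- pve < 0
  pve
}
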