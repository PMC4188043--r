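# Robust pairwise correlation across metabolites, transcripts and
# clinical traits: biweight midcorrelation with median/MAD soft weights
# (resistant to outliers), a t-approximation p-value, all-pairs matrices
# with within/between-class accounting, and FDR-controlled cross-table
# screens.

#' Biweight midcorrelation
#'
#' `u_i = (x_i - median(x)) / (9 * MAD(x))` with MAD the unscaled median
#' absolute deviation (no 1.4826 consistency factor); weights
#' `w_i = (1 - u_i^2)^2` for |u| < 1 and 0 otherwise; the correlation is
#' formed from the weighted median-centered values. If a variable's MAD
#' is 0 the computation falls back to mean/sd standardization for that
#' variable with a warning. Invariant to positive affine rescaling of
#' either variable.
#'
#' @param x,y numeric vectors; pairs with a missing value in either are
#'   dropped (>= 3 shared observations required).
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("bicor needs at least 3 shared nonmissing observations")
  x <- x[ok]; y <- y[ok]
  bw <- function(v, nm) {
    med <- stats::median(v)
    mad0 <- stats::median(abs(v - med))
    if (mad0 == 0) {
      warning(sprintf("MAD of %s is zero; falling back to mean/sd weights", nm))
      s <- stats::sd(v)
      if (s == 0) stop(sprintf("%s is constant", nm))
      return(list(c = v - mean(v), w = rep(1, length(v))))
    }
    u <- (v - med) / (9 * mad0)
    list(c = v - med, w = (1 - u^2)^2 * (abs(u) < 1))
  }
  a <- bw(x, "x"); b <- bw(y, "y")
  num <- sum(a$w * b$w * a$c * b$c)
  den <- sqrt(sum((a$w * a$c)^2) * sum((b$w * b$c)^2))
  if (den == 0) stop("all weights vanished; cannot form bicor")
  max(-1, min(1, num / den))
}

#' T-approximation p-value for a correlation
#'
#' Two-sided p from `t = r * sqrt((n - 2)/(1 - r^2))` on n - 2 degrees of
#' freedom; |r| = 1 (and underflow) floors at 1e-300.
#'
#' @param r correlation in [-1, 1].
#' @param n number of observation pairs (>= 3).
#' @return p-value in (0, 1].
#' @export
correlation_pvalue <- function(r, n) {
  if (n < 3) stop("n must be >= 3")
  stopifnot(abs(r) <= 1)
  if (abs(r) >= 1) return(.P_FLOOR)
  t <- r * sqrt((n - 2) / (1 - r^2))
  max(2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE), .P_FLOOR)
}

#' All-pairs robust correlation matrix with significance calls
#'
#' Evaluates every unordered pair of variables with per-pair casewise
#' deletion, labels each pair within- or between-class from the single
#' class assigned to each variable, and calls significance under the
#' requested policy.
#'
#' @param z strains x variables matrix (standardized values).
#' @param classes named class label per variable (required for
#'   within/between accounting; pass NULL to label all pairs
#'   `"unclassified"`).
#' @param policy list: `list(type = "bonferroni", alpha = 0.05)` or
#'   `list(type = "fdr", level = 0.05)`.
#' @return data.frame of correlation records: `var_a, var_b, r, n, p,
#'   pair_kind, significant` (plus `q` under the fdr policy); the
#'   significance threshold used is stored in the `"threshold"`
#'   attribute.
#' @export
pairwise_matrix <- function(z, classes = NULL,
                            policy = list(type = "bonferroni", alpha = 0.05)) {
  vars <- colnames(z)
  m <- length(vars)
  pairs <- utils::combn(m, 2)
  n_pairs <- ncol(pairs)
  r <- n <- p <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    r[k] <- bicor(z[, i], z[, j])
    n[k] <- sum(!is.na(z[, i]) & !is.na(z[, j]))
    p[k] <- correlation_pvalue(r[k], n[k])
  }
  kind <- if (is.null(classes)) rep("unclassified", n_pairs) else
    ifelse(classes[vars[pairs[1, ]]] == classes[vars[pairs[2, ]]],
           "within_class", "between_class")
  rec <- data.frame(var_a = vars[pairs[1, ]], var_b = vars[pairs[2, ]],
                    r = r, n = n, p = p, pair_kind = kind,
                    stringsAsFactors = FALSE)
  if (policy$type == "bonferroni") {
    thr <- bonferroni_threshold(n_pairs, policy$alpha)
    rec$significant <- rec$p < thr
  } else if (policy$type == "fdr") {
    qr <- estimate_qvalues(rec$p)
    rec$q <- qr$qvalues
    rec$significant <- rec$q <= policy$level
    thr <- if (any(rec$significant)) max(rec$p[rec$significant]) else 0
  } else stop("unknown threshold policy: ", policy$type)
  attr(rec, "threshold") <- thr
  rec
}

#' Within- versus between-class share of significant pairs
#'
#' @param records correlation records carrying `pair_kind` and
#'   `significant`.
#' @return list: counts `n_significant`, `n_within`, `n_between` and
#'   percentages (within rounded to nearest integer, between its
#'   complement so the two always sum to 100).
#' @export
class_pair_summary <- function(records) {
  if (is.null(records$pair_kind) ||
      any(!records$pair_kind %in% c("within_class", "between_class")))
    stop("records must carry within/between class labels")
  sig <- records[records$significant, , drop = FALSE]
  nw <- sum(sig$pair_kind == "within_class")
  ns <- nrow(sig)
  pw <- if (ns == 0) NA_real_ else round(100 * nw / ns)
  list(n_significant = ns, n_within = nw, n_between = ns - nw,
       pct_within = pw, pct_between = if (is.na(pw)) NA_real_ else 100 - pw)
}

#' FDR-controlled robust correlation screen between two tables
#'
#' Evaluates every (metabolite, other-variable) pair over the shared
#' strains with per-pair casewise deletion, pools the p-values into one
#' q-value fit, and returns the records with their significance call and
#' sign. The FDR-equivalent p threshold is stored in the `"threshold"`
#' attribute.
#'
#' @param metab strains x metabolites matrix.
#' @param other strains x variables matrix (transcripts or clinical
#'   traits); rownames are matched to `metab`.
#' @param fdr_level FDR level (default 0.05).
#' @return data.frame `var_a, var_b, r, n, p, q, significant, sign`.
#' @export
cross_correlate <- function(metab, other, fdr_level = 0.05) {
  shared <- intersect(rownames(metab), rownames(other))
  if (length(shared) < 3) stop("fewer than 3 shared strains")
  A <- metab[shared, , drop = FALSE]
  B <- other[shared, , drop = FALSE]
  grid <- expand.grid(a = colnames(A), b = colnames(B),
                      stringsAsFactors = FALSE)
  r <- n <- p <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    x <- A[, grid$a[k]]; y <- B[, grid$b[k]]
    r[k] <- bicor(x, y)
    n[k] <- sum(!is.na(x) & !is.na(y))
    p[k] <- correlation_pvalue(r[k], n[k])
  }
  qr <- estimate_qvalues(p)
  rec <- data.frame(var_a = grid$a, var_b = grid$b, r = r, n = n, p = p,
                    q = qr$qvalues, significant = qr$qvalues <= fdr_level,
                    sign = ifelse(r >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  attr(rec, "threshold") <-
    if (any(rec$significant)) max(rec$p[rec$significant]) else 0
  attr(rec, "pi0") <- qr$pi0
  rec
}
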