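# Preprocessing chain: missingness filter, run-day median registration,
# replicate averaging, z-scoring.

mk_table <- function(vals, strains, runday = NULL, classes = NULL)
  phenotype_table(vals, strains, classes, runday)

test_that("missingness filter drops strictly above the threshold", {
  # 342 variables, 59 of them above 20% missing -> 283 retained
  set.seed(1)
  n <- 50
  vals <- matrix(rnorm(n * 342), n, 342,
                 dimnames = list(sprintf("m%03d", 1:n), sprintf("v%03d", 1:342)))
  for (j in 1:59) vals[sample(n, ceiling(0.21 * n)), j] <- NA
  t <- mk_table(vals, sprintf("S%03d", 1:n))
  out <- filter_by_missingness(t, 0.20)
  expect_equal(length(out$variables), 283L)
  expect_equal(attr(out, "provenance")$missingness_filter$dropped,
               sprintf("v%03d", 1:59))
  # exactly 20% missing is retained (strict inequality)
  v2 <- matrix(rnorm(10 * 2), 10, 2,
               dimnames = list(letters[1:10], c("keep", "drop")))
  v2[1:2, "keep"] <- NA   # 20%
  v2[1:3, "drop"] <- NA   # 30%
  out2 <- filter_by_missingness(mk_table(v2, LETTERS[1:10]), 0.20)
  expect_equal(out2$variables, "keep")
  # all-complete table unchanged
  out3 <- filter_by_missingness(mk_table(vals[, 60:70], sprintf("S%03d", 1:n)))
  expect_equal(length(out3$variables), 11L)
})

test_that("run-day registration sets every pooled median to one", {
  v <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  t <- mk_table(v, c("A", "B", "C"), runday = rep("d1", 3))
  out <- normalize_run_days(t)
  expect_equal(unname(out$values[, 1]), c(0.5, 1, 1.5))
  # scale invariance: per-day rescaling is exactly removed
  set.seed(2)
  v2 <- matrix(abs(rnorm(60, 10)), 20, 3,
               dimnames = list(sprintf("s%02d", 1:20), c("x", "y", "z")))
  v2[sample(60, 6)] <- NA
  days <- rep(c("d1", "d2"), each = 10)
  clean <- mk_table(v2, sprintf("S%02d", 1:20), runday = days)
  scaled_vals <- v2
  scaled_vals[days == "d1", ] <- v2[days == "d1", ] * 3.7
  scaled_vals[days == "d2", ] <- v2[days == "d2", ] * 0.2
  scaled <- mk_table(scaled_vals, sprintf("S%02d", 1:20), runday = days)
  expect_equal(normalize_run_days(scaled)$values,
               normalize_run_days(clean)$values, tolerance = 1e-12)
  # all output run-day medians equal 1
  out2 <- normalize_run_days(scaled)
  for (d in c("d1", "d2"))
    expect_equal(median(out2$values[days == d, ], na.rm = TRUE), 1)
  # non-positive median errors
  vneg <- matrix(c(-5, -4, -3), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  expect_error(normalize_run_days(mk_table(vneg, LETTERS[1:3],
                                           runday = rep("d1", 3))),
               "non-positive median")
})

test_that("run-day registration exactly removes the planted batch effect", {
  cfg0 <- sim_config(seed = 30, n_strains = 40, n_snps = 100,
                     n_metabolites = 6, runday_effect_sd = 0,
                     missing_frac = 0)
  cfg1 <- sim_config(seed = 30, n_strains = 40, n_snps = 100,
                     n_metabolites = 6, runday_effect_sd = 0.4,
                     missing_frac = 0)
  g <- simulate_genotypes(cfg0)
  clean <- simulate_metabolome(g, cfg0)$table
  batched <- simulate_metabolome(g, cfg1)$table
  expect_equal(normalize_run_days(batched)$values,
               normalize_run_days(clean)$values, tolerance = 1e-12)
})

test_that("replicate averaging takes nonmissing means per strain", {
  v <- matrix(c(1, 3, 5, 1, NA, 2), 3, 2,
              dimnames = list(c("m1", "m2", "m3"), c("a", "b")))
  t <- mk_table(v, c("S1", "S1", "S2"))
  out <- average_strain_replicates(t)
  expect_equal(out$values["S1", ], c(a = 2, b = 1))
  expect_equal(out$values["S2", ], c(a = 5, b = 2))
  # single-sample strains pass through unchanged
  t1 <- mk_table(v, c("S1", "S2", "S3"))
  expect_equal(unname(average_strain_replicates(t1)$values), unname(v))
  # all replicates missing stays missing
  v2 <- matrix(c(NA, NA, 1), 3, 1, dimnames = list(c("m1", "m2", "m3"), "a"))
  out2 <- average_strain_replicates(mk_table(v2, c("S1", "S1", "S2")))
  expect_true(is.na(out2$values["S1", "a"]))
})

test_that("z-scoring uses the sample sd and rejects degenerate columns", {
  v <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  z <- standardize(mk_table(v, c("S1", "S2", "S3")))
  expect_equal(unname(z$zvalues[, 1]), c(-1, 0, 1))
  vc <- matrix(rep(2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  expect_error(standardize(mk_table(vc, c("S1", "S2", "S3"))),
               "zero variance")
  # every column has mean 0 and sample sd 1 within 1e-10, NA preserved
  set.seed(3)
  v3 <- matrix(rnorm(200), 20, 10,
               dimnames = list(sprintf("s%02d", 1:20), sprintf("v%02d", 1:10)))
  v3[sample(200, 20)] <- NA
  z3 <- standardize(mk_table(v3, rownames(v3)))
  expect_equal(unname(colMeans(z3$zvalues, na.rm = TRUE)), rep(0, 10),
               tolerance = 1e-10)
  expect_equal(unname(apply(z3$zvalues, 2, sd, na.rm = TRUE)), rep(1, 10),
               tolerance = 1e-10)
  expect_identical(is.na(z3$zvalues), is.na(v3))
})

test_that("the chain is idempotent after the first pass", {
  set.seed(4)
  v <- matrix(abs(rnorm(80, 10)), 20, 4,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("v%02d", 1:4)))
  days <- rep(c("d1", "d2"), 10)
  t <- mk_table(v, sprintf("S%02d", c(1:19, 19)), runday = days)
  n1 <- normalize_run_days(t)
  expect_equal(normalize_run_days(n1)$values, n1$values, tolerance = 1e-12)
  a1 <- average_strain_replicates(n1)
  expect_equal(average_strain_replicates(a1)$values, a1$values)
  z1 <- standardize(a1)
  z2 <- standardize(mk_table(z1$zvalues, z1$strain_ids))
  expect_equal(z2$zvalues, z1$zvalues, tolerance = 1e-12)
})

test_that("replicate variance summary separates genetic from noise", {
  # identical replicates: within-strain variance is exactly zero
  v <- matrix(rep(c(1, 5, 9), each = 3), 3, 3,
              dimnames = list(c("m1", "m2", "m3"), c("a", "b", "c")))
  t <- mk_table(v, c("B6", "B6", "B6"))
  expect_error(replicate_variance_summary(t, "DBA"), "at least 2")
  s <- replicate_variance_summary(t, "B6")
  expect_equal(s$mean_within, 0)
  # planted genetic variance: panel variance exceeds replicate variance
  cfg <- sim_config(seed = 31, n_strains = 60, n_snps = 300,
                    n_metabolites = 12, missing_frac = 0)
  g <- simulate_genotypes(cfg)
  tab <- simulate_metabolome(g, cfg)$table
  tab <- normalize_run_days(tab)
  rep_strain <- names(which.max(table(tab$strain_of_sample)))
  s2 <- replicate_variance_summary(tab, rep_strain)
  planted <- sprintf("met%03d", 1:12)[1:12]
  expect_gt(mean(s2$panel[intersect(planted, names(s2$panel))]),
            mean(s2$within[intersect(planted, names(s2$within))]))
})

test_that("ratio phenotypes are log-ratios of positive abundances", {
  v <- matrix(c(1, 2, 4, 8, 2, 2, 2, 2), 4, 2,
              dimnames = list(letters[1:4], c("x", "y")))
  t <- mk_table(v, LETTERS[1:4])
  out <- add_ratio_phenotypes(t, data.frame(a = "x", b = "y"))
  expect_equal(unname(out$values[, "x/y"]), log(c(1, 2, 4, 8) / 2))
  vneg <- v; vneg[1, 1] <- -1
  expect_error(add_ratio_phenotypes(mk_table(vneg, LETTERS[1:4]),
                                    data.frame(a = "x", b = "y")),
               "positive")
})
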