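---
title: "Mapping metabolite QTL in inbred strain panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping metabolite QTL in inbred strain panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Liver metabolite levels in a panel of inbred mouse strains are heritable
quantitative traits: strains differ far more than replicate mice of one
strain, and a single locus can control a large share of a metabolite's
variation. Mapping those loci by genome-wide association faces one
dominant obstacle — inbred panels are strongly structured. Classical and
recombinant-inbred strains fall into families with correlated genomes,
so a naive per-SNP regression associates every family-tagging SNP with
every family-structured phenotype and the test statistics inflate
genome-wide. `metaboqtl` implements the standard remedy, a linear mixed
model with a genomic relatedness matrix, together with the downstream
stages such a study needs: false-discovery-rate control, collapsing of
correlated significant SNPs into loci, variance-explained estimation,
candidate-gene prioritization through local expression QTL, robust
correlation with transcripts and clinical traits, and cross-species
syntenic replication.

# The mixed model

For one phenotype `y` (one value per strain) and one SNP dosage `g` the
model is

    y = mu + g * beta + u + e,   Var(u) = sigma_g^2 K,   Var(e) = sigma_e^2 I

where `K` is the identity-by-state kinship matrix: `K[i, j]` is the mean
over SNPs of `1 - |g_i - g_j| / 2`, i.e. the fraction of genotyped
positions at which two strains carry the same alleles (a heterozygous
dosage, possible for interpolated recombinant-inbred genotypes,
half-matches either homozygote). The variance components are estimated
by restricted maximum likelihood (REML), profiled over the single ratio
`delta = sigma_e^2 / sigma_g^2`. One spectral decomposition of `K` makes
each likelihood evaluation O(n): the restricted log-likelihood is

    l_R(delta) = 1/2 [ (n-q) log((n-q)/(2 pi)) - (n-q) - (n-q) log(y' P y)
                       - log|H| - log|X' H^-1 X| + log|X' X| ]

with `H = K + delta I` and `P` the usual REML projection. The profile is
evaluated on a 100-point log-spaced grid over `delta` in `10^-5..10^5`
and every interior local maximum of the grid is refined by
derivative-free scalar optimization (`stats::optimize`) to
`|d log10 delta| < 1e-6`; a maximum at a grid end is reported with a
boundary flag. At the optimum the SNP effect is tested by generalized
least squares under `Sigma = sigma_g^2 K + sigma_e^2 I` with a standard
F-test on (1, n-2) degrees of freedom (one tested coefficient, the
intercept absorbed).

Two scan modes are provided. The default `exact` mode refits REML for
every SNP design `[1, g]`, vectorized across SNPs so the grid cost is
shared; `null_approx` estimates `delta` once under the intercept-only
model and reuses it for every SNP. The approximation's quality on the
default synthetic panel is part of the test suite: top associations are
concordant between modes for strongly planted signals, and the median
relative deviation on the -log10 p scale among strong SNPs (p < 1e-4)
is below 15%. It is *not* a uniform 15% bound — for a phenotype with one
large, structure-aligned QTL the intercept-only `delta` is overestimated
(the unmodeled QTL variance loads onto `sigma_g^2`) and borderline SNPs
can deviate by a factor of ~2 on the log scale, always in the
conservative direction.

A genuine limitation of exact per-SNP REML is worth knowing: for a
weakly heritable phenotype, a null SNP that happens to align with the
family structure can drive the per-SNP REML to the boundary
`sigma_g^2 -> 0`, at which point the test degenerates to ordinary least
squares at exactly the SNP where correction matters most. This is the
global optimum of the restricted likelihood as the method defines it,
not an implementation artifact; `null_approx` is immune because its
`delta` never moves. Both modes are exposed so users can cross-check
suspicious isolated hits.

Percent variance explained (PVE) for a fitted SNP is
`1 - var(y - X beta_hat) / var(y)` with fixed-effects-only residuals.
The random-effect BLUP is deliberately not subtracted: including it
would move kinship-explained variance into the "explained" part and
conflate structure with the SNP effect. PVE can be slightly negative
for null SNPs; values are kept and flagged rather than clamped.

Numerical choices: `K` gains `1e-6` on the diagonal when its smallest
eigenvalue falls below `1e-8` (factorization stability); p-values are
floored at `1e-300` to keep logs finite; casewise deletion is applied
per SNP, with kinship computed once on all strains and subset per test.

# FDR and locus definition

Genome-wide significance uses Storey q-values computed on the pooled
p-values of all metabolite-SNP tests (the study design implies one
genome-wide threshold across metabolites; per-phenotype FDR is available
by slicing). `pi0` is estimated on the lambda grid 0.05..0.95 (step
0.05) with a cubic smoothing spline evaluated at the last grid point and
clamped to (0, 1]; with fewer than 100 p-values, or when the spline
fails, the conservative `pi0 = 1` is used with a warning, which makes
the q-values plain Benjamini-Hochberg. The reported "p threshold at FDR
5%" is the largest observed p with q at or below the level.

Significant SNPs are collapsed to peak SNPs greedily: rank by ascending
p (ties by chromosome, position, then SNP id — the data give no
guidance, so the tie-break is a fixed convention), keep the best
unabsorbed SNP as a peak, absorb every remaining same-chromosome SNP
with dosage R^2 > 0.5 against it, repeat. Collapsing is restricted to
same-chromosome pairs: cross-chromosome dosage correlation in an inbred
panel reflects strain structure, which the mixed model already handles,
not linkage. The greedy rule and the alternative "best SNP per connected
R^2 component" definition coincide whenever the R^2 graph is transitive
within components; the tests compare the two on random fixtures and
assert equality exactly on those clique-structured cases. Distinct loci
are deduplicated by exact peak-SNP identity; a locus is reported with a
2 Mb window (1 Mb per side of the peak).

Local eQTL follow the same scan; a transcript's record is "local" when
its peak SNP lies within 2 Mb of either end of the gene span. Candidate
genes for a metabolite locus are genes whose local-eQTL peak falls
within 1 Mb (inclusive) of the metabolite peak; pathway co-annotation
pairs (a user-supplied two-column table in place of live database
queries) independently corroborate candidates. All genomic coordinates
are 1-based with intervals inclusive on both ends.

# Preprocessing

The metabolite pipeline order is fixed and recorded in provenance:
variables with more than 20% missing samples are dropped (strict
inequality, assessed before replicate averaging because profiling
quality is a property of samples); every value is divided by its
run-day's pooled median (multiplicative batch effects are exactly
removed — this is why the synthetic generator makes its batch effect
multiplicative); replicate mice are averaged within strains; each
variable is z-scored with the n-1 standard deviation. Standardization
happens after averaging because the strain is the unit of analysis; the
alternative (z-scoring samples first) changes nothing material since
averaging followed by an affine map commutes with the scan. No value is
ever imputed; every downstream analysis deletes casewise.

# Robust correlation

Associations between metabolites, transcripts and clinical traits use
the biweight midcorrelation: values are centered at the median, scaled
by nine times the unscaled median absolute deviation (no 1.4826
consistency factor — the construction follows the biweight literature,
and variants exist, hence the explicit statement), and weighted by
`(1 - u^2)^2` inside `|u| < 1`, which smoothly zeroes out observations
more than nine MADs from the median. A variable with zero MAD falls
back to mean/sd weighting with a warning. No outlier-fraction cap is
applied. P-values use the t approximation
`t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom (the underlying
study does not state its correlation p-value method; the t form is the
standard choice and is documented as such). Metabolite-metabolite pairs
are thresholded by Bonferroni over all pairs; cross-layer screens
(transcripts, traits) use pooled q-values at FDR 5%.

# Cross-species replication

Synteny is consumed, never computed: a six-column map file gives
mouse-interval to human-interval correspondences. A mouse locus
(peak +/- 1 Mb) maps to the whole human interval of every overlapping
synteny block — the delimitation of a "syntenic region" around a hit is
a convention, and whole-block mapping is the package's. Metabolite
identity across species comes from an explicit two-column id map (no
name matching). The locus replicates when the human summary holds a
record for that metabolite inside any mapped interval with p at or below
`alpha / n_loci`, Bonferroni over the loci carried into the comparison;
support is counted per population. Metabolite-ratio phenotypes are
supported as `log(a/b)` of the run-day-normalized positive abundances,
standardized and scanned like any metabolite (a log-ratio of z-scores
would be ill-defined, z-scores being signed).

# The synthetic panel generator

Every stage is tested against panels with known ground truth, generated
by pure functions of a configuration and a master seed (each generator
derives a labelled sub-seed, so adding one generator never shifts the
draws of another). The default configuration is the package's study
condition: 100 strains in 8 families, 2,000 SNPs before filtering in
10-SNP linkage blocks on 10 chromosomes at 25 kb spacing, 40 metabolites
in the eight canonical classes with 12 planted QTL at PVE 0.3/0.5/0.7,
60 transcripts with 12 planted local eQTL at PVE 0.6, one strain with
five replicate mice and twenty with two, six profiling run-days with a
log-normal multiplicative batch effect (sd 0.15), and 5% missing cells.

Population structure is deliberately the simplest mechanism that makes
the uncorrected scan anti-conservative: strains carry their family's
haplotype at each LD-block founder SNP with probability 0.75, and every
phenotype receives a family random effect (variance 0.4 against residual
variance 0.6). Block members are copies of the founder flipped with
probability `(1 - r)/2` (default r = 0.9), giving within-block dosage
correlation around r^2 — above the 0.5 collapsing threshold, so peak
collapsing has real work to do. Metabolites of one class share a
"pathway" factor (variance 0.8) drawn independently of the genotypes, so
within-class pairs dominate the significant correlations without
touching scan calibration.

One generator choice deserves its own paragraph. With a handful of
discrete families, the in-sample correlation between a family-structured
SNP and a family-effect draw does not shrink as the panel grows — it is
governed by the number of families, not of strains. Planted "variance
explained" would therefore not converge to its target and would not be a
well-defined ground truth. The generator consequently residualizes each
planted phenotype's noise (family effect + class factor + residual)
against its planted genotypes before sizing `beta`, making the realized
latent-scale PVE equal the target by construction; sampling noise then
enters only through replicate expansion, batch effects, missingness and
standardization. Null phenotypes keep the full family structure — they
are what the calibration and inflation demonstrations rest on.

The synthetic human GWAS summary places a deeply sub-threshold record
inside the mapped interval for a configured fraction of planted loci
(default 0.39) and keeps all other records above twice the Bonferroni
threshold, so the realized replication rate equals the drawn fraction up
to binomial sampling.

What passing tests on these panels do and do not show: they verify the
estimators against their definitions (brute-force oracles for kinship,
R^2, collapsing, bicor, BH), calibration under the planted null, and
end-to-end recovery of planted effects through the full pipeline. They
do not certify behavior on real panels, whose LD is block-irregular,
whose missingness is not uniform, whose metabolite distributions are
heavy-tailed beyond a shared-factor model, and whose family structure is
a continuum rather than eight discrete groups.

# Problem sizes

The test suite and the acceptance script run everything at the scales
above: calibration on 100 strains x ~2,000 SNPs x 50 null metabolites,
empirical FDR over 20 replicate panels of 100 strains x 300 SNPs x 16
metabolites, parameter recovery on the default panel with exact per-SNP
REML, and the analytic threshold values at their printed precision.
These sizes were chosen as the smallest panels on which the structured
effects under test (inflation, absorption, recovery) are unambiguous.

# Known limitations

* Exact per-SNP REML can collapse to the no-correction boundary at
  structured null SNPs (see above); isolated hits for weakly heritable
  phenotypes deserve a cross-check in `null_approx` mode.
* Storey q-values on pooled scan p-values inherit the dependence of
  LD-linked tests; the empirical-FDR test covers the default panel's
  dependence, not arbitrary LD structures.
* The candidate-gene search is strictly positional and
  expression-mediated; genes regulated at the protein level are
  invisible to it, and the co-annotation table is only as complete as
  its source.
* Single-marker models only: no multi-locus fits, no dominance, no
  covariates beyond the intercept, no fine-mapping.
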