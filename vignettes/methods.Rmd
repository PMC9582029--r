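---
title: "Methods: two-stage microbiome GWAS, meta-analysis, fine-mapping and MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage microbiome GWAS, meta-analysis, fine-mapping and MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgwas)
```

# Scope and model

`mgwas` implements a host-genetics association analysis for amplicon-based
microbiome surveys across cohorts and body-site microenvironments. The
analysis treats each *microbial feature* — an ASV, a taxonomic clade from
genus to phylum, or the community composition as a whole — as a trait and
tests it against SNP dosages while adjusting for the major known confounders
of skin microbiota (age, sex, BMI) and for population structure (ten genetic
principal components).

Two statistical routes are used, mirroring how the field separates univariate
and multivariate community analysis:

* **Univariate features.** Counts are modeled as negative binomial,
  `y_i ~ NB(mu_i, theta)` with
  `log mu_i = x_i' beta + log(total counts_i)`, where the design holds the
  covariates only — never the SNP. The variance function is
  `Var(y) = mu + mu^2/theta`. Randomized-quantile (Dunn–Smyth) residuals of
  this fit are standard normal when the model is correct, and each SNP is then
  tested by ordinary least squares of these residuals on dosage (two-sided
  t-test). This two-stage design costs one GLM per feature rather than one per
  feature-SNP pair, which is what makes a genome-wide scan tractable.
* **Community composition.** Bray-Curtis dissimilarities of the rarefied ASV
  table are decomposed by principal-coordinates analysis; covariate effects
  are removed by projecting the coordinate matrix onto the orthogonal
  complement of the covariate design (distance-based redundancy analysis).
  Each SNP is tested with a pseudo-F statistic on the residual coordinates,
  with the permutation null handled analytically (below).

## Zero truncation and outliers

Following standard practice for overdispersed amplicon counts, each
univariate feature model uses zero-truncated, non-rarefied counts (samples
with a zero count for that feature are excluded; fewer than 50 remaining
samples skips the feature), while outliers are flagged on *rarefied* counts
to avoid conflating sequencing depth with abundance: samples more than 5
interquartile ranges from the feature's median are masked, and when the IQR
is zero only samples at the median are kept. "Zero-truncated" is implemented
as sample exclusion rather than a zero-truncated NB likelihood; the two
readings differ, and exclusion matches the per-sample subsetting the
pipeline's sample counts report.

# The moment-matched distance F-test

For a SNP dosage vector `x` and residual coordinates `R`, the pseudo-F is

```
F = SS_explained / (SS_residual / (n - 2)),   SS_explained = x~' G x~ / x~'x~
```

with `G = R R'` and `x~` the centered dosage. Because the total sum of
squares is fixed under permutation of `x`, the permutation p-value of `F`
equals the upper tail of the quadratic form `Q = z' G z` over random
permutations `z` of `x~`.

`mgwas` computes the first **four exact permutation moments** of `Q`
analytically. Expanding `E[Q^r]` over the `2r` index slots of the `r` copies
of `G` and grouping terms by the set partition of coincident indices gives

```
E[Q^r] = sum over partitions P of  S_G(P) * D_x(m(P)) / n_(d)
```

where `S_G(P)` is a distinct-index contraction of `G` (obtained from
unrestricted trace-like contractions by Mobius inversion on the partition
lattice — double centering annihilates every contraction with a singleton
block, so at most `r` free indices survive), `D_x(m)` is the distinct-index
power-product sum of `x~` for block-size multiset `m`, and `n_(d)` a falling
factorial. All data-independent combinatorics are cached; per-SNP cost is a
handful of power sums. The engine is validated in the unit tests against
exhaustive enumeration of all `7!` permutations.

The p-value comes from a **Pearson type III** (shifted gamma) distribution
matching the first three moments. Two adequacy guards route a test to an
explicit permutation p-value (seeded, with add-one correction) instead:

* `|skewness| > 1` (matched gamma shape below 4): with this much asymmetry a
  three-moment fit is not pointwise accurate to ~0.01 anywhere in the
  distribution, regardless of higher moments;
* exact excess kurtosis differing from the Pearson III implied value
  (`1.5 * skew^2`) by more than 0.25. The threshold comes from the Edgeworth
  expansion of the CDF, whose kurtosis term is bounded by
  `max_z |He3(z) phi(z)| / 24 ~ 0.023` per unit of kurtosis mismatch, i.e.
  about 0.006 of CDF error at the threshold.

In practice, community ordinations dominated by one or two axes (common for
skin communities, where a couple of taxa hold most of the mass) produce
permutation nulls with skewness near 2 and go to the exact permutation route,
while well-spread ordinations use the closed form. Both guards are exposed as
arguments (`skew_max`, `kurt_tol`) and `Inf` disables them. Negative PCoA
eigenvalues are dropped (no Lingoes/Cailliez correction), matching the default
behavior of the standard dbRDA implementations.

# Feature construction

Candidate features are the ASVs plus their aggregations at genus, family,
order, class and phylum (exact sums of member-ASV counts; ASVs unclassified
at a rank are excluded from that rank's aggregation but stay as ASV-level
features). A feature is retained for a microenvironment only if, at *both* of
its sites, the median count exceeds 50 (strict) and the feature is present
(count > 0) in more than 100 participants (strict). Whether the presence
filter preceded the both-sites rule in the original design is ambiguous; the
implementation applies per-site filters first, then intersects. Redundant
features are collapsed per microenvironment by single-linkage clustering at
Spearman correlation > 0.985, keeping the deepest-rank member (ASV before
genus before family, ...; alphabetical tie-break — the original work does not
state its choice). Spearman ties use average ranks.

# Meta-analysis and significance rules

Per-site results from the same microenvironment are combined with
fixed-effect meta-analysis: inverse-variance weighting on beta/SE for
univariate features, and sample-size (Stouffer) weighting on one-sided
z-scores for the direction-free pseudo-F (all z taken positive, the
convention used for direction-free statistics in METAL-style software).
Verdicts follow the published rules exactly:

* moist/sebaceous (two cohorts): genome-wide iff `P_meta < 5e-8` and both
  per-site `p < 0.05`;
* dry (two sites of one cohort): `P_meta := min(p)`; genome-wide iff
  `min(p) < 5e-8` and `max(p) < 0.05`;
* study-wide additionally requires `P_meta < 5e-8 / 80 = 6.25e-10` (80 tested
  features: 79 univariate plus beta diversity). The threshold is stored as
  the exact ratio and only printed as the familiar rounded `6.3e-10`.

The dry rule lets a single site's p-value cross the study-wide line; such
rows are flagged (`dry_min_p_study_wide`) rather than silently resolved,
since the published account of this corner case is self-contradictory.
Genomic inflation is estimated by the regression method: ordered observed
1-df chi-square quantiles regressed through the origin on expected quantiles.
At desk scale (a few thousand SNPs) this estimator has Monte-Carlo sd around
0.02, so single-run values slightly above 1 do not indicate miscalibration —
the tests check a fixed-seed run and the type-I error directly.

# Fine-mapping

Significant loci (±500 kb around each lead; leads chosen by smallest p, ties
by position) are fine-mapped under a single causal variant: each variant's
approximate Bayes factor is
`ABF = sqrt(V/(V+W)) * exp(W z^2 / (2(V+W)))` with `V = se^2`, `z = beta/se`
and prior effect variance `W = 0.04` (prior sd 0.2 on the residual-trait
scale, a conventional default; the original analysis defers to its tool's
unstated default). Posterior inclusion probabilities are proportional to ABF
under a uniform prior across the locus; the 95% credible set is the smallest
posterior-sorted prefix reaching 0.95. A set of 50 or more variants is
deemed invalid, and invalid sets — and all beta-diversity loci, whose
statistic has no beta/SE — fall back to reporting the lead plus all variants
with `r^2 > 0.6` to it ("LD > 0.6" is read as r-squared; the r reading is
noted as the alternative). Dry-microenvironment fine-mapping uses the
volar-forearm effect estimates.

# Mendelian randomization

Exposures are microbial-feature summary statistics; outcomes are disease
GWAS. Instruments: exposure `p < 1e-5`, greedy clumping by p-value with
window 10,000 kb and `r^2 < 0.001` against a genotype reference (the cited
tool's defaults), and instrument strength `F = (beta/se)^2 >= 10`.
Harmonization flips outcome effects when alleles are swapped and drops
palindromic variants whose allele frequencies fall in [0.42, 0.58] on either
side (a conventional ambiguity band). With more than two instruments the
primary estimate is IVW (weighted regression through the origin, with a
multiplicative random-effects floor at scale 1); with one or two, the Wald
ratio of the strongest instrument. Sensitivity: MR-Egger (intercept =
directional pleiotropy; t-reference with k-2 df) and the weighted median
(bootstrap SE). A result is *supporting* iff the Egger slope is
non-significant (p > 0.05) and the weighted median is significant (p < 0.1)
with the same direction as the primary estimate. Primary p-values receive
Benjamini-Hochberg correction per outcome trait and globally. Where the
original Methods once say "weighted mean", the sensitivity rule and results
name the weighted median; the weighted median is implemented.

# Synthetic data: what it emulates and what it does not

The generator inverts the analysis model so that parameter recovery is
well-posed:

* **Genotypes.** Per-variant allele frequencies uniform on a configured MAF
  range; HWE genotypes from two haplotypes; within LD blocks, haplotypes
  follow a Gaussian AR(1) copula with parameter `ld_rho` (adjacent-variant
  r^2 is monotone in `ld_rho`, attenuated by dichotomization: latent 0.95
  gives dosage r^2 near 0.45).
* **Covariates.** Age uniform on 39-48 y (the younger cohort's stated band),
  sex Bernoulli(0.5), BMI lognormal with median 26 and log-sd 0.15 — chosen
  once as a realistic adult profile.
* **Counts.** Baseline relative abundances from a stick-breaking profile
  (a few dominant taxa, a long tail), NB dispersion log-uniform on [0.5, 5],
  per-sample depth lognormal with median 20,000 reads (the source text's
  rarefaction depth is corrupted, so depth and the default rarefaction depth
  of 10,000 are free, documented choices). Confounder coefficients default to
  centered normals with sd 0.01/y (age), 0.2 (sex), 0.02 per unit (BMI).
  Planted SNP effects add `beta * dosage` to the log-mean of a named ASV.
* **Seeds.** One master seed; every sub-generator (per cohort, per site, per
  rarefied sample, per residual randomization, per bootstrap) derives its own
  child stream, so outputs are byte-identical across runs and insensitive to
  reordering of other components.

Not emulated: amplicon/PCR bias, chimeras, strain-level variation,
imputation uncertainty, relatedness, and real LD structure beyond AR(1)
blocks. A green test therefore establishes internal statistical correctness
(calibration, recovery, rule logic), not robustness to those artifacts.

One modeling consequence worth knowing: because the offset is the log of the
*realized* total count, planting a large effect on a dominant taxon moves the
totals with dosage and attenuates the recoverable coefficient (a
compositional effect, not a bug). The parameter-recovery tests therefore
plant effects on mid-abundance taxa, and recovery is assessed on the NB GLM
with the dosage included in the design — the model the generator inverts.
The residual-stage OLS slope lives on the residual scale and is attenuated
by construction; its contract is calibration (type-I error, lambda_GC), which
the acceptance suite checks directly.

# Numerical choices and degenerate inputs

* NB fits: `MASS::glm.nb` (profile ML for theta), 200 IRLS iterations;
  non-convergence flags the feature rather than erroring.
* Dunn-Smyth randomization clamps the uniform draw to `[1e-12, 1 - 1e-12]`
  before the normal quantile, keeping residuals finite at zero counts and at
  extreme tails.
* HWE: exact conditional test (probability-mass ordering with a `1 + 1e-12`
  tie tolerance); the two source cohorts used different HWE rules, so the
  threshold is a plain parameter (default 1e-5).
* PCoA axes with eigenvalues below `max(eig) * 1e-10` are treated as null
  space; PCA signs follow the largest-magnitude-loading convention.
* Bray-Curtis on a sample with zero total is an error (the dissimilarity is
  undefined), not a silent drop.
* Credible-set prefix uses a `1e-12` tolerance on the cumulative posterior;
  weighted-median interpolation uses cumulative weights minus half the
  current weight.
* Rarefaction subsamples read positions without replacement via cumulative
  counts, so zero counts can never gain mass and totals are exact.

# Known limitations

* The multivariate scan's permutation fallback floors p-values at
  `1/(n_perm + 1)`; genome-wide claims through the fallback route need
  `n_perm` raised accordingly (the closed form has no floor).
* Clumping uses sample r^2 from the supplied reference; with small references
  the default `r^2 < 0.001` threshold sits below the null expectation `1/n`,
  clumping aggressively within the window — as the real tools do.
* The pipeline's MR stage demonstrates the full path on synthetic null
  outcomes; real outcome GWAS are supplied as summary-statistics TSVs.
* `lambda_gc` warns below 100 tests and flags the estimate unstable.
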