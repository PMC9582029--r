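#' Exact conditional test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, enumerates the distribution of
#' the heterozygote count and returns the probability of configurations no
#' more probable than the observed one (the standard exact HWE test).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped sample is required")
  n_a <- 2 * n_aa + n_Aa # minor-ish allele count (either orientation works)
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  # attainable heterozygote counts share parity with the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized P(n_het) via the standard recurrence
  lp <- numeric(length(hets))
  for (i in seq_along(hets)) {
    h <- hets[i]
    hom_r <- (rare - h) / 2
    hom_c <- (n - h - hom_r)
    lp[i] <- lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
      lfactorial(hom_c) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Variant-level quality-control filters
#'
#' Retains variants that are biallelic (distinct single-nucleotide alleles),
#' non-monomorphic, with minor allele frequency >= `maf_min`, missingness
#' <= `miss_max`, and exact HWE p >= `hwe_alpha`. EAF and HWE use non-missing
#' dosages only. A per-rule removal log is attached as attribute `"log"`.
#'
#' @param G a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param miss_max maximum missing fraction (default 0.1).
#' @param hwe_alpha HWE p-value threshold (default 1e-5).
#' @return filtered `genotype_matrix`.
#' @export
variant_filters <- function(G, maf_min = 0.05, miss_max = 0.1,
                            hwe_alpha = 1e-5) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  m <- ncol(d)
  miss <- colMeans(is.na(d))
  eaf <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(eaf, 1 - eaf)
  mono <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) < 2)
  bial <- G$variants$ea != G$variants$oa &
    nchar(G$variants$ea) == 1 & nchar(G$variants$oa) == 1
  hwe_p <- vapply(seq_len(m), function(j) {
    x <- d[, j][!is.na(d[, j])]
    if (length(x) == 0 || length(unique(x)) < 2) return(1)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  rules <- list(
    non_biallelic = !bial,
    monomorphic = mono,
    low_maf = maf < maf_min,
    missingness = miss > miss_max,
    hwe = hwe_p < hwe_alpha
  )
  removed <- Reduce(`|`, rules)
  log <- data.frame(snp = G$variants$snp,
                    reason = vapply(seq_len(m), function(j) {
                      r <- names(rules)[vapply(rules, `[`, logical(1), j)]
                      if (length(r)) paste(r, collapse = ";") else ""
                    }, character(1)))
  out <- genotype_matrix(d[, !removed, drop = FALSE],
                         G$variants[!removed, , drop = FALSE],
                         G$samples)
  attr(out, "log") <- log[removed, , drop = FALSE]
  out
}

#' Genetic principal components
#'
#' PCA of the column-standardized dosage matrix (missing dosages mean-imputed
#' per variant first). Signs follow a deterministic convention: the loading of
#' largest magnitude on each component is positive.
#'
#' @param G a post-QC `genotype_matrix`.
#' @param k number of components (default 10).
#' @return list with `scores` (samples x k, columns `PC1..PCk`), `eigenvalues`
#'   and the proportion of `variance_explained`.
#' @export
genetic_pcs <- function(G, k = 10) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  if (k > min(dim(d))) stop("k exceeds min(n_samples, n_variants)")
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  sds <- apply(d, 2, sd)
  keep <- sds > 0
  z <- scale(d[, keep, drop = FALSE])
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(i) {
    v <- pc$rotation[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- G$samples$sample_id
  ev <- pc$sdev^2
  list(scores = scores, eigenvalues = ev[seq_len(k)],
       variance_explained = ev[seq_len(k)] / sum(ev))
}
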