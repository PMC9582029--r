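#' Log approximate Bayes factor for a single variant
#'
#' Wakefield-style closed form under a normal prior N(0, W) on the effect:
#' `ABF = sqrt(V/(V+W)) * exp(W z^2 / (2 (V+W)))` with `V = se^2`,
#' `z = beta/se`, returned on the log scale (evidence for association).
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param prior_w prior effect-size variance W (>= 0); default 0.04
#'   (prior sd 0.2 on the residual-trait scale).
#' @return log ABF.
#' @export
abf <- function(beta, se, prior_w = 0.04) {
  if (any(se <= 0)) stop("standard errors must be positive")
  stopifnot(prior_w >= 0)
  v <- se^2
  z <- beta / se
  0.5 * log(v / (v + prior_w)) + prior_w * z^2 / (2 * (v + prior_w))
}

#' 95% credible set under a single causal variant
#'
#' Posterior inclusion probability of variant i is `ABF_i / sum_j ABF_j`
#' (uniform prior over the locus variants). The credible set is the smallest
#' prefix of the posterior-sorted variants whose cumulative posterior reaches
#' `coverage`; it is flagged invalid when its size reaches `max_size`
#' (default 50), triggering the LD fallback downstream.
#'
#' @param snp variant identifiers.
#' @param beta,se per-variant effects and standard errors.
#' @param prior_w prior effect variance (see [abf()]).
#' @param coverage credible-set coverage (default 0.95).
#' @param max_size validity bound on the set size (default 50).
#' @return list of class `credible_set`: `variants` data.frame (snp, log_abf,
#'   posterior, in_cs) sorted by posterior, `size`, `valid`.
#' @export
credible_set <- function(snp, beta, se, prior_w = 0.04, coverage = 0.95,
                         max_size = 50) {
  stopifnot(length(snp) == length(beta), length(beta) == length(se),
            length(snp) >= 1)
  la <- abf(beta, se, prior_w)
  post <- exp(la - max(la))
  post <- post / sum(post)
  ord <- order(-post, snp)
  cum <- cumsum(post[ord])
  k <- which(cum >= coverage - 1e-12)[1]
  in_cs <- seq_along(ord) <= k
  vars <- data.frame(snp = snp[ord], log_abf = la[ord], posterior = post[ord],
                     in_cs = in_cs, stringsAsFactors = FALSE)
  structure(list(variants = vars, size = k, valid = k < max_size),
            class = "credible_set")
}

#' Squared-correlation linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of the dosage vectors over samples non-missing
#' at both variants.
#'
#' @param G a `genotype_matrix`.
#' @param i,j variant indices or SNP ids.
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(G, i, j) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.character(i)) i <- match(i, G$variants$snp)
  if (is.character(j)) j <- match(j, G$variants$snp)
  x <- G$dosage[, i]; y <- G$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) stop("monomorphic variant in ld_r2")
  cor(x, y)^2
}

#' Define loci around significant lead variants
#'
#' Greedy construction: the remaining variant with the lowest p (ties broken
#' by smaller position) becomes a lead; all variants within `window` bp join
#' its locus and are removed from the pool.
#'
#' @param meta data.frame with SNP, CHR, POS, P_META (and BETA/SE if present).
#' @param window half-width of the locus window in bp (default 5e5).
#' @return list of data.frames, one per locus, lead variant first.
#' @export
define_loci <- function(meta, window = 5e5) {
  stopifnot(all(c("SNP", "CHR", "POS", "P_META") %in% names(meta)))
  pool <- meta[order(meta$P_META, meta$POS), , drop = FALSE]
  loci <- list()
  while (nrow(pool) > 0) {
    lead <- pool[1, ]
    in_window <- pool$CHR == lead$CHR & abs(pool$POS - lead$POS) <= window
    loci[[length(loci) + 1L]] <- pool[in_window, , drop = FALSE]
    pool <- pool[!in_window, , drop = FALSE]
  }
  loci
}

#' Credible set with LD fallback for one locus
#'
#' Runs [credible_set()] on the locus summary statistics; if the set is
#' invalid (size >= `max_size`) or the locus statistic is direction-free
#' (beta diversity), returns instead the lead variant plus all variants with
#' `r^2 >` `ld_cut` to the lead.
#'
#' @param locus data.frame with SNP, BETA, SE ordered with the lead first.
#' @param G `genotype_matrix` providing LD.
#' @param prior_w,coverage,max_size passed to [credible_set()].
#' @param ld_cut LD threshold (default 0.6, strict `>`).
#' @param multivariate TRUE for beta-diversity loci (always LD fallback).
#' @return data.frame SNP, POS, BETA, SE, LOG_ABF, POSTERIOR, IN_CS,
#'   R2_TO_LEAD, METHOD (`"credible_set"` or `"ld_fallback"`).
#' @export
locus_fallback <- function(locus, G, prior_w = 0.04, coverage = 0.95,
                           max_size = 50, ld_cut = 0.6, multivariate = FALSE) {
  lead <- locus$SNP[1]
  r2 <- vapply(locus$SNP, function(s) {
    if (s == lead) return(1)
    tryCatch(ld_r2(G, s, lead), error = function(e) NA_real_)
  }, numeric(1))
  cs <- NULL
  if (!multivariate && all(is.finite(locus$SE)) && all(locus$SE > 0)) {
    cs <- credible_set(locus$SNP, locus$BETA, locus$SE, prior_w, coverage,
                       max_size)
  }
  if (!is.null(cs) && cs$valid) {
    v <- cs$variants
    idx <- match(v$snp, locus$SNP)
    return(data.frame(SNP = v$snp, POS = locus$POS[idx],
                      BETA = locus$BETA[idx], SE = locus$SE[idx],
                      LOG_ABF = v$log_abf, POSTERIOR = v$posterior,
                      IN_CS = v$in_cs, R2_TO_LEAD = r2[idx],
                      METHOD = "credible_set", stringsAsFactors = FALSE))
  }
  keep <- which(r2 > ld_cut | locus$SNP == lead)
  data.frame(SNP = locus$SNP[keep], POS = locus$POS[keep],
             BETA = if ("BETA" %in% names(locus)) locus$BETA[keep] else NA_real_,
             SE = if ("SE" %in% names(locus)) locus$SE[keep] else NA_real_,
             LOG_ABF = NA_real_, POSTERIOR = NA_real_, IN_CS = NA,
             R2_TO_LEAD = r2[keep], METHOD = "ld_fallback",
             stringsAsFactors = FALSE)
}
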