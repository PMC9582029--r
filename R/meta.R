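#' Significance thresholds for the microenvironment-wise meta-analysis
#'
#' @param genome_wide genome-wide threshold (default 5e-8).
#' @param nominal per-site nominal threshold (default 0.05).
#' @param n_features number of tested microbial features (default 80: 79
#'   univariate clades plus beta diversity).
#' @return list with the thresholds; `study_wide` is stored as the exact ratio
#'   `genome_wide / n_features` (6.25e-10 at the defaults; printed rounded as
#'   6.3e-10) and comparisons always use the exact value.
#' @export
threshold_config <- function(genome_wide = 5e-8, nominal = 0.05,
                             n_features = 80) {
  list(genome_wide = genome_wide, nominal = nominal, n_features = n_features,
       study_wide = genome_wide / n_features)
}

#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' `beta = sum(w_i b_i)/sum(w_i)` with `w_i = 1/se_i^2`;
#' `se = 1/sqrt(sum(w_i))`; two-sided normal p. Effect alleles must already be
#' aligned; a single study is returned unchanged. Cochran's Q is attached for
#' logging but plays no role in any verdict.
#'
#' @param beta,se numeric vectors of per-site effects and standard errors.
#' @return list `beta, se, p, q_het`.
#' @export
ivw_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1, all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  qh <- sum(w * (beta - b)^2)
  list(beta = b, se = s, p = 2 * pnorm(-abs(b / s)), q_het = qh)
}

#' Sample-size weighted (Stouffer) meta-analysis
#'
#' Combines per-site z-scores weighted by the square root of the sample size,
#' as METAL does. For direction-free statistics (the multivariate pseudo-F)
#' pass `directions = NULL`: upper-tail z-scores are combined with positive
#' sign and a one-sided combined p is returned; otherwise z-scores are signed
#' and the combined p is two-sided.
#'
#' @param p per-site p-values (one-sided upper-tail when `directions` is
#'   NULL, two-sided otherwise).
#' @param n per-site sample sizes.
#' @param directions per-site effect signs, or NULL for direction-free input.
#' @return list `z, p`.
#' @export
samplesize_meta <- function(p, n, directions = NULL) {
  stopifnot(length(p) == length(n), length(p) >= 1)
  if (is.null(directions)) {
    z <- qnorm(p, lower.tail = FALSE)
    Z <- sum(z * sqrt(n)) / sqrt(sum(n))
    list(z = Z, p = pnorm(Z, lower.tail = FALSE))
  } else {
    stopifnot(length(directions) == length(p))
    z <- sign(directions) * qnorm(p / 2, lower.tail = FALSE)
    Z <- sum(z * sqrt(n)) / sqrt(sum(n))
    list(z = Z, p = 2 * pnorm(-abs(Z)))
  }
}

#' Apply the microenvironment significance decision rules
#'
#' Moist/sebaceous (two cohorts): genome-wide significant iff the combined
#' `p_meta < genome_wide` AND both per-site p < nominal. Dry (two sites of one
#' cohort): `p_meta` is the smaller per-site p; genome-wide iff
#' `min(p) < genome_wide` and `max(p) < nominal`. Study-wide additionally
#' requires `p_meta < study_wide` (exact ratio). The dry rule can label rows
#' study-wide through a single site; such rows are flagged rather than
#' silently demoted.
#'
#' @param p_meta combined p-value (ignored for dry; pass NA).
#' @param site_p numeric vector of the two per-site p-values.
#' @param microenv one of `"moist"`, `"sebaceous"`, `"dry"`.
#' @param thresholds a [threshold_config()].
#' @return list `verdict` (`"not_significant"`, `"genome_wide"`,
#'   `"study_wide"`), `p_meta` (the reported value), `rule`, `flag`.
#' @export
apply_decision_rules <- function(p_meta, site_p, microenv,
                                 thresholds = threshold_config()) {
  microenv <- match.arg(microenv, c("moist", "sebaceous", "dry"))
  if (length(site_p) != 2)
    stop("exactly two site p-values are required for a microenvironment")
  flag <- ""
  if (microenv == "dry") {
    p_rep <- min(site_p)
    gw <- min(site_p) < thresholds$genome_wide &&
      max(site_p) < thresholds$nominal
    rule <- "dry_single_cohort"
  } else {
    if (is.na(p_meta)) stop("p_meta required for two-cohort microenvironments")
    p_rep <- p_meta
    gw <- p_meta < thresholds$genome_wide && all(site_p < thresholds$nominal)
    rule <- "two_cohort"
  }
  verdict <- "not_significant"
  if (gw) {
    verdict <- "genome_wide"
    if (p_rep < thresholds$study_wide) {
      verdict <- "study_wide"
      if (microenv == "dry")
        flag <- "dry_min_p_study_wide" # single-site p drives the call
    }
  }
  list(verdict = verdict, p_meta = p_rep, rule = rule, flag = flag)
}

#' Meta-analyze two per-site association tables for one microenvironment
#'
#' Univariate rows (BETA/SE present) are combined by inverse-variance
#' weighting; direction-free rows (pseudo-F) by sample-size weighting on
#' one-sided p-values. For dry microenvironments the reported `P_META` is the
#' smaller per-site p and the effect estimate is taken from `dry_effect_site`
#' (the paper uses the volar forearm).
#'
#' @param site_a,site_b data.frames from [associate_univariate_site()] or
#'   [associate_beta_site()] for the two sites.
#' @param microenv microenvironment label.
#' @param thresholds a [threshold_config()].
#' @param dry_effect_site site name whose beta/SE are reported for dry loci.
#' @return data.frame with combined estimates, per-site p, verdicts, rule and
#'   flag columns.
#' @export
meta_analyze <- function(site_a, site_b, microenv,
                         thresholds = threshold_config(),
                         dry_effect_site = "volar_forearm") {
  key <- c("FEATURE", "SNP")
  m <- merge(site_a, site_b, by = key, suffixes = c(".a", ".b"))
  m <- m[!is.na(m$P.a) & !is.na(m$P.b), , drop = FALSE]
  n_out <- nrow(m)
  res <- vector("list", n_out)
  univar <- "BETA.a" %in% names(m)
  for (i in seq_len(n_out)) {
    site_p <- c(m$P.a[i], m$P.b[i])
    nn <- c(m$N.a[i], m$N.b[i])
    if (univar) {
      if (m$EA.a[i] != m$EA.b[i]) stop("effect alleles not harmonized")
      mv <- ivw_meta(c(m$BETA.a[i], m$BETA.b[i]), c(m$SE.a[i], m$SE.b[i]))
      p_meta <- mv$p; beta <- mv$beta; se <- mv$se
    } else {
      mv <- samplesize_meta(site_p, nn) # upper-tail one-sided for pseudo-F
      p_meta <- mv$p; beta <- NA_real_; se <- NA_real_
    }
    dec <- apply_decision_rules(p_meta, site_p, microenv, thresholds)
    if (microenv == "dry" && univar) {
      pick <- if (m$SITE.a[i] == dry_effect_site) "a" else "b"
      beta <- m[[paste0("BETA.", pick)]][i]
      se <- m[[paste0("SE.", pick)]][i]
    }
    res[[i]] <- data.frame(
      FEATURE = m$FEATURE[i], SNP = m$SNP[i], CHR = m$CHR.a[i],
      POS = m$POS.a[i], EA = m$EA.a[i], OA = m$OA.a[i],
      MICROENV = microenv, BETA = beta, SE = se, P_META = dec$p_meta,
      P_SITE_A = site_p[1], P_SITE_B = site_p[2], N = sum(nn),
      VERDICT = dec$verdict, RULE = dec$rule, FLAG = dec$flag,
      stringsAsFactors = FALSE)
  }
  out <- if (n_out) do.call(rbind, res) else NULL
  if (is.null(out))
    out <- data.frame(FEATURE = character(), SNP = character(),
                      CHR = integer(), POS = integer(), EA = character(),
                      OA = character(), MICROENV = character(),
                      BETA = numeric(), SE = numeric(), P_META = numeric(),
                      P_SITE_A = numeric(), P_SITE_B = numeric(),
                      N = integer(), VERDICT = character(), RULE = character(),
                      FLAG = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor (regression method)
#'
#' Converts p-values to 1-df chi-square statistics and regresses the ordered
#' observed quantiles through the origin on the expected quantiles; the slope
#' is lambda_GC. Values near 1 indicate a well-calibrated test.
#'
#' @param p_values vector of p-values.
#' @return lambda estimate; if fewer than 100 tests are supplied a warning is
#'   raised and the attribute `"unstable"` is set.
#' @export
lambda_gc <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  unstable <- length(p) < 100
  if (unstable) warning("fewer than 100 p-values: lambda_GC is unstable")
  obs <- sort(qchisq(p, df = 1, lower.tail = FALSE))
  expd <- qchisq(ppoints(length(p)), df = 1)
  lam <- sum(obs * expd) / sum(expd^2)
  if (unstable) attr(lam, "unstable") <- TRUE
  lam
}
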