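#' Outlier mask from rarefied counts
#'
#' Samples whose rarefied count deviates from the feature's median by more
#' than `k` times the interquartile range are masked out. When the IQR is
#' zero, only samples exactly at the median are retained.
#'
#' @param rarefied_counts numeric vector of rarefied counts for one feature.
#' @param k IQR multiplier (default 5).
#' @return logical mask, TRUE = retained.
#' @export
outlier_mask <- function(rarefied_counts, k = 5) {
  if (length(rarefied_counts) == 0) stop("empty count vector")
  med <- median(rarefied_counts)
  iqr <- IQR(rarefied_counts)
  if (iqr == 0) return(rarefied_counts == med)
  abs(rarefied_counts - med) <= k * iqr
}

#' Zero-truncation mask
#'
#' Excludes samples with zero count for the feature. If fewer than `min_n`
#' samples remain the feature is marked skipped.
#'
#' @param counts non-rarefied counts for one feature.
#' @param min_n minimum retained samples (default 50).
#' @return logical mask with attribute `"skipped"` (TRUE if below `min_n`).
#' @export
zero_truncate <- function(counts, min_n = 50) {
  mask <- counts > 0
  attr(mask, "skipped") <- sum(mask) < min_n
  mask
}

#' Fit a negative-binomial GLM with a log-total offset
#'
#' Maximum-likelihood NB regression (profile ML for the dispersion theta, via
#' `MASS::glm.nb`) of feature counts on the covariate design, with the log of
#' each sample's total sequence count as offset. Non-convergence is flagged,
#' not thrown.
#'
#' @param counts integer counts (post truncation/masking).
#' @param covariates data.frame of numeric covariates (age, sex, BMI, genetic
#'   PCs); an intercept is added automatically.
#' @param offset per-sample offset on the log scale (log total counts).
#' @return object of class `nb_fit`: coefficients, `theta`, fitted `mu`,
#'   the response `y`, and `converged`.
#' @export
nb_glm_fit <- function(counts, covariates, offset) {
  stopifnot(length(counts) == nrow(covariates), length(offset) == length(counts))
  dat <- data.frame(.y = counts, covariates, .off = offset,
                    check.names = TRUE)
  covnames <- setdiff(names(dat), c(".y", ".off"))
  f <- reformulate(c(covnames, "offset(.off)"), response = ".y")
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(f, data = dat, maxit = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(converged = FALSE), class = "nb_fit"))
  }
  structure(list(
    coefficients = coef(fit),
    se = suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
    theta = fit$theta,
    mu = fitted(fit),
    y = counts,
    converged = isTRUE(fit$converged) && is.null(fit$th.warn)
  ), class = "nb_fit")
}

#' Randomized quantile (Dunn-Smyth) residuals of an NB fit
#'
#' `r_i = qnorm(u_i)` with `u_i` uniform on `(F(y_i - 1), F(y_i)]`, `F` the
#' fitted NB CDF; approximately standard normal under a correctly specified
#' model. Seeded for reproducibility.
#'
#' @param fit a converged `nb_fit`.
#' @param seed integer seed for the randomization.
#' @return numeric vector of residuals.
#' @export
dunn_smyth_residuals <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!isTRUE(fit$converged)) stop("residuals require a converged fit")
  y <- fit$y; mu <- fit$mu; th <- fit$theta
  hi <- pnbinom(y, mu = mu, size = th)
  lo <- ifelse(y > 0, pnbinom(y - 1, mu = mu, size = th), 0)
  with_seed(child_seed(seed, "dunn_smyth"), {
    u <- lo + runif(length(y)) * (hi - lo)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    qnorm(u)
  })
}

#' Per-SNP linear test on model residuals
#'
#' Ordinary least squares of the residual vector on a single dosage vector
#' (with intercept); two-sided t-test on the slope.
#'
#' @param residuals numeric residual vector.
#' @param dosage numeric dosage vector (same samples).
#' @return one-row data.frame `beta, se, p, n, stat_type`; a dosage that is
#'   monomorphic within the retained samples yields NA estimates with
#'   `stat_type = "untested"`.
#' @export
univariate_assoc <- function(residuals, dosage) {
  stopifnot(length(residuals) == length(dosage))
  ok <- is.finite(residuals) & is.finite(dosage)
  r <- residuals[ok]; x <- dosage[ok]
  n <- length(r)
  if (n < 3 || var(x) == 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                      stat_type = "untested", stringsAsFactors = FALSE))
  }
  xc <- x - mean(x); rc <- r - mean(r)
  ssx <- sum(xc^2)
  beta <- sum(xc * rc) / ssx
  rss <- sum(rc^2) - beta^2 * ssx
  se <- sqrt(max(rss, 0) / (n - 2) / ssx)
  t <- beta / se
  data.frame(beta = beta, se = se, p = 2 * pt(-abs(t), df = n - 2), n = n,
             stat_type = "t", stringsAsFactors = FALSE)
}

#' Vectorized residual-on-dosage scan
#'
#' Runs [univariate_assoc()] across every column of a dosage matrix in one
#' pass of matrix algebra, applying the within-subset MAF and monomorphism
#' inclusion criteria.
#'
#' @param residuals numeric residual vector.
#' @param dosage_matrix samples x variants dosage matrix.
#' @param maf_min minimum within-subset minor allele frequency.
#' @return data.frame with one row per variant: `snp, beta, se, p, n, eaf,
#'   stat_type`.
#' @export
assoc_scan <- function(residuals, dosage_matrix, maf_min = 0.05) {
  n <- length(residuals)
  stopifnot(nrow(dosage_matrix) == n)
  rc <- residuals - mean(residuals)
  xm <- colMeans(dosage_matrix)
  xc <- sweep(dosage_matrix, 2, xm)
  ssx <- colSums(xc^2)
  eaf <- xm / 2
  maf <- pmin(eaf, 1 - eaf)
  testable <- ssx > 0 & maf >= maf_min
  beta <- drop(crossprod(xc, rc)) / ssx
  rss <- sum(rc^2) - beta^2 * ssx
  se <- sqrt(pmax(rss, 0) / (n - 2) / ssx)
  p <- 2 * pt(-abs(beta / se), df = n - 2)
  beta[!testable] <- se[!testable] <- p[!testable] <- NA_real_
  data.frame(snp = colnames(dosage_matrix), beta = beta, se = se, p = p,
             n = n, eaf = eaf,
             stat_type = ifelse(testable, "t", "untested"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Residualized principal-coordinate matrix (dbRDA residuals)
#'
#' Gower-centers the squared dissimilarities, keeps axes with positive
#' eigenvalues (negative eigenvalues are dropped, no Lingoes/Cailliez
#' correction), and removes covariate effects by least-squares projection on
#' the design (intercept + covariates). The returned coordinates are the
#' unexplained community variance used by the per-SNP distance F-test.
#'
#' @param D square symmetric dissimilarity matrix.
#' @param covariates data.frame of numeric covariates for the same samples in
#'   the same order, or NULL for an intercept-only conditioning.
#' @return object of class `dbrda_residuals`: `coords` (samples x axes),
#'   `eigenvalues` of the retained axes, `n`.
#' @export
dbrda_residuals <- function(D, covariates = NULL) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (!is.null(covariates) && nrow(covariates) != n)
    stop("covariates do not align with the distance matrix samples")
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    sum(pos))
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  R <- qr.resid(qr(X), coords)
  rownames(R) <- rownames(D)
  structure(list(coords = R, eigenvalues = e$values[pos], n = n),
            class = "dbrda_residuals")
}

#' Moment-matched distance-based pseudo-F test
#'
#' Tests a single dosage vector against a residual ordination. The statistic
#' is the pseudo-F of the dosage regression on the residual coordinates; its
#' p-value comes from a Pearson type III distribution whose first three
#' moments equal the exact permutation moments of the explained sum of
#' squares, computed analytically from trace identities (see
#' [perm_moments()]). When the precompute carries the exact fourth moment
#' (the default), a kurtosis adequacy diagnostic guards the three-moment fit:
#' if the exact excess kurtosis differs from the Pearson III implied value
#' (`1.5 * skew^2`) by more than `kurt_tol`, or the moment solution is
#' infeasible, an explicit permutation p-value is returned instead. The
#' default `kurt_tol = 0.25` bounds the Edgeworth kurtosis term of the CDF
#' error by about 0.006 (`max|He3(z) phi(z)|/24 ~ 0.023` per kurtosis unit);
#' because that expansion is only trustworthy at moderate asymmetry, the
#' closed form is additionally restricted to `|skew| <= skew_max` (default 1,
#' i.e. matched gamma shape >= 4). Heavily skewed permutation nulls — typical
#' of ordinations dominated by one axis — go to the exact permutation route.
#'
#' @param R a `dbrda_residuals` object (or samples x axes matrix of centered
#'   residual coordinates).
#' @param dosage numeric dosage vector.
#' @param precomp optional [perm_moment_precompute()] result for `R`, reused
#'   across SNPs.
#' @param n_perm permutations for the fallback.
#' @param seed seed for the fallback permutations.
#' @param kurt_tol tolerated absolute mismatch in excess kurtosis before the
#'   permutation fallback fires; `Inf` disables the diagnostic.
#' @param skew_max largest permutation-null skewness handled by the closed
#'   form; `Inf` disables the cap.
#' @return one-row data.frame `stat` (pseudo-F), `p` (upper tail), `n`,
#'   `stat_type` (`"pseudo-F"`), `method` (`"moment"` or `"permutation"`).
#' @export
moment_matched_ftest <- function(R, dosage, precomp = NULL, n_perm = 100000,
                                 seed = 1L, kurt_tol = 0.25, skew_max = 1) {
  coords <- if (inherits(R, "dbrda_residuals")) R$coords else R
  n <- nrow(coords)
  stopifnot(length(dosage) == n)
  x <- dosage - mean(dosage)
  ssx <- sum(x^2)
  if (ssx == 0)
    return(data.frame(stat = NA_real_, p = NA_real_, n = n,
                      stat_type = "untested", method = NA_character_,
                      stringsAsFactors = FALSE))
  G <- tcrossprod(coords)
  trG <- sum(coords^2)
  if (trG <= 0) stop("degenerate ordination: zero total sum of squares")
  q_raw <- drop(crossprod(x, G %*% x)) # = ssx * explained SS
  expl <- q_raw / ssx
  Fstat <- expl / ((trG - expl) / (n - 2))
  if (is.null(precomp)) precomp <- perm_moment_precompute(G)
  mom <- perm_moments(precomp, x)
  feasible <- is.finite(mom$var) && mom$var > 0 && is.finite(mom$skew)
  adequate <- abs(mom$skew) <= skew_max
  if (adequate && feasible && is.finite(kurt_tol) && is.finite(mom$kurt))
    adequate <- abs(mom$kurt - 1.5 * mom$skew^2) <= kurt_tol
  if (feasible && adequate) {
    z <- (q_raw - mom$mean) / sqrt(mom$var)
    p <- pearson3_upper(z, mom$skew)
    method <- "moment"
  } else {
    p <- perm_pvalue_qf(G, x, q_raw, n_perm, seed)
    method <- "permutation"
  }
  data.frame(stat = Fstat, p = p, n = n, stat_type = "pseudo-F",
             method = method, stringsAsFactors = FALSE)
}

# Monte-Carlo permutation upper-tail p for the quadratic form x'Gx,
# with the add-one correction.
perm_pvalue_qf <- function(G, x, q_obs, n_perm = 10000, seed = 1L) {
  n <- length(x)
  with_seed(child_seed(seed, "perm_ftest"), {
    chunk <- 500L
    hits <- 0L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      Z <- vapply(seq_len(b), function(i) x[sample.int(n)], numeric(n))
      qs <- colSums(Z * (G %*% Z))
      hits <- hits + sum(qs >= q_obs - 1e-12 * abs(q_obs))
      done <- done + b
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Run the univariate two-stage association for one site
#'
#' For each retained feature: zero-truncate the non-rarefied counts, mask
#' outliers on the rarefied counts, fit the NB GLM with covariates and
#' log-total offset, extract Dunn-Smyth residuals, and scan all variants with
#' per-SNP linear tests (re-applying MAF and monomorphism criteria within the
#' retained subset).
#'
#' @param features samples x features matrix of non-rarefied counts for the
#'   tested features (rank-prefixed names).
#' @param rarefied samples x features matrix of rarefied counts aligned to
#'   `features` (samples dropped at rarefaction carry NA).
#' @param totals per-sample total sequence counts (offset source).
#' @param genotypes a `genotype_matrix` for the same samples.
#' @param covariates data.frame of numeric covariates (age, sex, bmi, PCs)
#'   aligned to the samples.
#' @param site site label copied to the output.
#' @param min_n minimum samples after truncation (default 50).
#' @param maf_min within-subset MAF criterion (default 0.05).
#' @param outlier_k IQR multiplier (default 5).
#' @param seed master seed for the residual randomization.
#' @return data.frame with FEATURE, SNP, CHR, POS, EA, OA, EAF, BETA, SE, P,
#'   N, STAT_TYPE, SITE; skipped features are reported in attribute
#'   `"skipped"`.
#' @export
associate_univariate_site <- function(features, rarefied, totals, genotypes,
                                      covariates, site = "site",
                                      min_n = 50, maf_min = 0.05,
                                      outlier_k = 5, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            nrow(features) == nrow(genotypes$dosage))
  out <- list(); skipped <- character()
  for (f in colnames(features)) {
    y <- features[, f]
    zt <- zero_truncate(y, min_n)
    keep <- as.logical(zt)
    rc <- rarefied[, f]
    om <- rep(TRUE, length(y))
    has_rc <- !is.na(rc)
    if (any(has_rc)) om[has_rc] <- outlier_mask(rc[has_rc], outlier_k)
    keep <- keep & om
    if (sum(keep) < min_n) { skipped <- c(skipped, f); next }
    fit <- nb_glm_fit(y[keep], covariates[keep, , drop = FALSE],
                      offset = log(totals[keep]))
    if (!isTRUE(fit$converged)) { skipped <- c(skipped, f); next }
    r <- dunn_smyth_residuals(fit, seed = child_seed(seed, paste0(site, "/", f)))
    sc <- assoc_scan(r, genotypes$dosage[keep, , drop = FALSE], maf_min)
    v <- genotypes$variants
    out[[f]] <- data.frame(FEATURE = f, SNP = sc$snp, CHR = v$chr, POS = v$pos,
                           EA = v$ea, OA = v$oa, EAF = sc$eaf, BETA = sc$beta,
                           SE = sc$se, P = sc$p, N = sc$n,
                           STAT_TYPE = sc$stat_type, SITE = site,
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(FEATURE = character(), SNP = character(), CHR = integer(),
               POS = integer(), EA = character(), OA = character(),
               EAF = numeric(), BETA = numeric(), SE = numeric(),
               P = numeric(), N = integer(), STAT_TYPE = character(),
               SITE = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Run the multivariate (beta-diversity) association for one site
#'
#' Bray-Curtis dissimilarities of the rarefied ASV table are residualized on
#' the covariates by [dbrda_residuals()] and each variant is tested with the
#' moment-matched pseudo-F.
#'
#' @param rarefied_asv rarefied ASV-level `abundance_table` (or count matrix).
#' @param genotypes `genotype_matrix` covering at least the rarefied samples.
#' @param covariates covariate data.frame aligned to the genotype samples.
#' @param site site label.
#' @param maf_min within-subset MAF criterion.
#' @param n_perm permutations for the moment-test fallback.
#' @param seed seed for the fallback permutations.
#' @return data.frame in the same layout as
#'   [associate_univariate_site()], with STAT (pseudo-F) in place of BETA/SE.
#' @export
associate_beta_site <- function(rarefied_asv, genotypes, covariates,
                                site = "site", maf_min = 0.05,
                                n_perm = 20000, seed = 1L) {
  counts <- if (inherits(rarefied_asv, "abundance_table")) rarefied_asv$counts
  else rarefied_asv
  ids <- rownames(counts)
  idx <- match(ids, genotypes$samples$sample_id)
  if (anyNA(idx)) stop("rarefied samples missing from the genotype matrix")
  D <- bray_curtis(counts)
  R <- dbrda_residuals(D, covariates[idx, , drop = FALSE])
  pre <- perm_moment_precompute(tcrossprod(R$coords))
  dos <- genotypes$dosage[idx, , drop = FALSE]
  eaf <- colMeans(dos) / 2
  maf <- pmin(eaf, 1 - eaf)
  v <- genotypes$variants
  rows <- lapply(seq_len(ncol(dos)), function(j) {
    if (maf[j] < maf_min || var(dos[, j]) == 0) {
      return(data.frame(stat = NA_real_, p = NA_real_, n = nrow(dos),
                        stat_type = "untested", method = NA_character_,
                        stringsAsFactors = FALSE))
    }
    moment_matched_ftest(R, dos[, j], precomp = pre, n_perm = n_perm,
                         seed = child_seed(seed, paste0(site, "/", v$snp[j])))
  })
  rows <- do.call(rbind, rows)
  data.frame(FEATURE = "beta_diversity", SNP = v$snp, CHR = v$chr, POS = v$pos,
             EA = v$ea, OA = v$oa, EAF = eaf, STAT = rows$stat, P = rows$p,
             N = rows$n, STAT_TYPE = rows$stat_type, SITE = site,
             stringsAsFactors = FALSE)
}
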