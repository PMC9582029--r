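test_that("outlier mask implements the 5xIQR rule with the IQR-zero special case", {
  expect_equal(outlier_mask(c(10, 10, 10, 10, 500)),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(outlier_mask(rep(7, 20))))
  # engineered: median 20, IQR 4 -> keep values within [0, 40]
  x <- c(16, 18, 20, 22, 24, 0, 40, 41, -1)
  med <- median(x); iqr <- IQR(x)
  expect_equal(outlier_mask(x, 5), abs(x - med) <= 5 * iqr)
  expect_error(outlier_mask(numeric(0)), "empty")
})

test_that("zero truncation masks zeros and flags small features", {
  m <- zero_truncate(c(0, 3, 0, 7), min_n = 2)
  expect_equal(as.logical(m), c(FALSE, TRUE, FALSE, TRUE))
  expect_false(attr(m, "skipped"))
  m2 <- zero_truncate(c(5, 1, 2), min_n = 2)
  expect_true(all(m2))
  expect_true(attr(zero_truncate(rep(0, 10)), "skipped"))
})

test_that("NB GLM: offset identity and near-Poisson dispersion behavior", {
  set.seed(21)
  n <- 400
  cov <- data.frame(age = runif(n, 39, 48), sex = rbinom(n, 1, 0.5),
                    bmi = rlnorm(n, log(26), 0.15))
  off <- rep(log(1e4), n)
  mu <- exp(-6 + 0.02 * (cov$age - 43) + 0.3 * cov$sex + off)
  y <- rnbinom(n, mu = mu, size = 5)
  f1 <- nb_glm_fit(y, cov, off)
  expect_true(f1$converged)
  f2 <- nb_glm_fit(y, cov, off + log(2))
  expect_equal(f2$coefficients["(Intercept)"],
               f1$coefficients["(Intercept)"] - log(2), tolerance = 1e-6)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-6)
  # one-replicate parameter sanity: age effect within 4 SE of truth
  expect_lt(abs(f1$coefficients["age"] - 0.02), 4 * 0.02 + 0.05)

  # Poisson-limit data: estimated dispersion is large, Pearson stat near 1
  yp <- rpois(n, mu)
  fp <- nb_glm_fit(yp, cov, off)
  expect_gt(fp$theta, 50)
  pearson <- sum((yp - fp$mu)^2 / (fp$mu + fp$mu^2 / fp$theta)) / (n - 4)
  expect_lt(abs(pearson - 1), 0.25)
})

test_that("Dunn-Smyth residuals are seeded, finite, and normal under the model", {
  set.seed(22)
  n <- 1000
  cov <- data.frame(age = runif(n, 39, 48), sex = rbinom(n, 1, 0.5),
                    bmi = rlnorm(n, log(26), 0.15))
  off <- log(rlnorm(n, log(2e4), 0.5))
  mu <- exp(-7 + 0.25 * cov$sex + off)
  y <- rnbinom(n, mu = mu, size = 2)
  fit <- nb_glm_fit(y, cov, off)
  r1 <- dunn_smyth_residuals(fit, seed = 7)
  expect_identical(r1, dunn_smyth_residuals(fit, seed = 7))
  expect_false(identical(r1, dunn_smyth_residuals(fit, seed = 8)))
  expect_true(all(is.finite(r1)))
  # KS normality across seeds: at least 9/10 runs pass at 0.01
  ks <- vapply(1:10, function(s)
    ks.test(dunn_smyth_residuals(fit, seed = s), "pnorm")$p.value, numeric(1))
  expect_gte(sum(ks > 0.01), 9)
})

test_that("univariate association: perfect fit, monomorphic guard, scan = lm oracle", {
  set.seed(23)
  d <- rbinom(200, 2, 0.3)
  res <- univariate_assoc(as.numeric(d), d)
  expect_equal(res$beta, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-200)
  mono <- univariate_assoc(rnorm(100), rep(1, 100))
  expect_equal(mono$stat_type, "untested")

  # vectorized scan equals per-SNP lm()
  r <- rnorm(150)
  D <- sapply(1:5, function(i) rbinom(150, 2, 0.4))
  colnames(D) <- paste0("v", 1:5)
  sc <- mgwas:::assoc_scan(r, D, maf_min = 0)
  for (j in 1:5) {
    cf <- summary(lm(r ~ D[, j]))$coefficients
    expect_equal(sc$beta[j], cf[2, 1], tolerance = 1e-10)
    expect_equal(sc$se[j], cf[2, 2], tolerance = 1e-10)
    expect_equal(sc$p[j], cf[2, 4], tolerance = 1e-10)
  }
})

test_that("dbRDA residuals: centered PCoA under intercept, orthogonality, recovery", {
  set.seed(24)
  conf <- matrix(rnorm(40), 20, 2) # known 2-D configuration
  D <- as.matrix(dist(conf))
  R0 <- dbrda_residuals(D, covariates = NULL)
  # classical scaling recovers the configuration up to rotation/translation
  cc <- scale(conf, scale = FALSE)
  pro <- svd(crossprod(R0$coords[, 1:2], cc))
  rot <- pro$u %*% t(pro$v)
  expect_lt(max(abs(R0$coords[, 1:2] %*% rot - cc)), 1e-8)
  # intercept-only residuals equal centered PCoA coordinates (cmdscale oracle)
  cmd <- cmdscale(D, k = 2)
  expect_equal(abs(R0$coords[, 1:2]), abs(cmd), tolerance = 1e-8,
               ignore_attr = TRUE)

  covars <- data.frame(a = rnorm(20), b = rnorm(20))
  R <- dbrda_residuals(D, covars)
  X <- cbind(1, as.matrix(covars))
  expect_lt(max(abs(crossprod(X, R$coords))), 1e-8)
  expect_error(dbrda_residuals(D, covars[1:10, ]), "align")
})

test_that("dbRDA residual inertia matches vegan::capscale", {
  skip_if_not_installed("vegan")
  set.seed(25)
  m <- matrix(rpois(30 * 12, 25), 30, 12)
  D <- bray_curtis(m)
  covars <- data.frame(a = rnorm(30), b = runif(30))
  R <- dbrda_residuals(D, covars)
  cap <- vegan::capscale(as.dist(D) ~ a + b, data = covars)
  # total unexplained (positive-axis) inertia agrees
  expect_equal(sum(R$coords^2), cap$CA$tot.chi, tolerance = 1e-6)
})

test_that("moment engine reproduces exhaustive permutation moments at n = 7", {
  set.seed(26)
  n <- 7
  R <- matrix(rnorm(n * 3), n, 3)
  R <- sweep(R, 2, colMeans(R))
  G <- tcrossprod(R)
  x <- rbinom(n, 2, 0.4)
  xc <- x - mean(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  Q <- vapply(perms(1:n), function(p) drop(crossprod(xc[p], G %*% xc[p])),
              numeric(1))
  mu <- mean(Q); v <- mean(Q^2) - mu^2
  m3 <- mean(Q^3) - 3 * mu * mean(Q^2) + 2 * mu^3
  got <- perm_moments(perm_moment_precompute(G), x)
  expect_equal(got$mean, mu, tolerance = 1e-12)
  expect_equal(got$var, v, tolerance = 1e-10)
  expect_equal(got$skew, m3 / v^1.5, tolerance = 1e-8)
})

test_that("moment-matched F-test: planted signal, null calibration, perm agreement", {
  set.seed(27)
  n <- 60
  R <- matrix(rnorm(n * 4), n, 4)
  R <- sweep(R, 2, colMeans(R))
  dosage <- rbinom(n, 2, 0.4)
  # plant the dosage as the dominant residual axis; force the closed form
  # (the permutation route would floor at 1/(n_perm + 1))
  Rp <- cbind(5 * scale(dosage, scale = FALSE), 0.3 * R[, 2:4])
  res <- moment_matched_ftest(Rp, dosage, kurt_tol = Inf, skew_max = Inf)
  expect_lt(res$p, 1e-6)
  expect_equal(res$method, "moment")
  expect_equal(res$stat_type, "pseudo-F")

  # null p-values roughly uniform
  ps <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    moment_matched_ftest(R, rbinom(n, 2, 0.3))$p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)

  # moment p close to a 20k-permutation oracle on three small instances
  for (s in 1:3) {
    set.seed(3000 + s)
    Rs <- matrix(rnorm(40 * 3), 40, 3)
    Rs <- sweep(Rs, 2, colMeans(Rs))
    ds <- rbinom(40, 2, 0.35)
    pm <- moment_matched_ftest(Rs, ds)$p
    pp <- oracle_perm_p(Rs, ds, 20000, seed = s)
    expect_lt(abs(pm - pp), 0.02)
  }

  # monomorphic dosage is reported untested
  expect_equal(moment_matched_ftest(R, rep(2, n))$stat_type, "untested")
})

test_that("site-level univariate scan reports post-masking n and skips", {
  cfg <- sim_config(n_individuals = 150, n_variants = 30, n_asvs = 12, seed = 28)
  g <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg)
  tab <- simulate_microbiome(g, cv, cfg)
  fm <- build_feature_matrix(tab)[, 1:6]
  rar <- rarefy(tab, 5000, seed = 1)
  rar_fm <- build_feature_matrix(rar)
  aligned <- matrix(NA_real_, nrow(fm), 6, dimnames = list(rownames(fm),
                                                           colnames(fm)))
  common <- intersect(rownames(rar_fm), rownames(fm))
  aligned[common, ] <- rar_fm[common, colnames(fm)]
  res <- associate_univariate_site(fm, aligned, rowSums(tab$counts), g,
                                   cv[, c("age", "sex", "bmi")],
                                   site = "siteX", min_n = 40, seed = 5)
  expect_true(all(res$SITE == "siteX"))
  for (f in unique(res$FEATURE)) {
    y <- fm[, f]
    keep <- y > 0
    rc <- aligned[, f]
    ok <- !is.na(rc)
    om <- rep(TRUE, length(y)); om[ok] <- outlier_mask(rc[ok])
    expect_equal(unique(res$N[res$FEATURE == f]), sum(keep & om))
  }
})
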