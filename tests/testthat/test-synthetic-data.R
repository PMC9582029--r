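test_that("config validation rejects bad parameter ranges", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(n_variants = 10,
                          planted_effects = data.frame(variant = 11,
                                                       feature = "ASV001",
                                                       beta = 1)),
               "variant indices")
})

test_that("genotype simulation is deterministic and respects HWE inputs", {
  cfg <- small_config(seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_true(all(g1$dosage %in% 0:2))
  # EAF metadata equals column means / 2
  expect_equal(g1$variants$eaf, unname(colMeans(g1$dosage) / 2))
  expect_true(all(diff(g1$variants$pos) > 0))
})

test_that("ld_rho = 0 gives independent variants; realized EAF concentrates", {
  cfg <- sim_config(n_individuals = 500, n_variants = 100, ld_rho = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  cm <- cor(g$dosage)
  offdiag <- abs(cm[upper.tri(cm)])
  expect_lt(mean(offdiag), 0.1)

  cfg2 <- sim_config(n_individuals = 2000, n_variants = 200,
                     maf_range = c(0.3, 0.3), seed = 4)
  eaf <- simulate_genotypes(cfg2)$variants$eaf
  expect_gt(mean(eaf >= 0.27 & eaf <= 0.33), 0.95)
})

test_that("LD blocks give r2 monotone in ld_rho", {
  r2_adj <- function(rho) {
    cfg <- sim_config(n_individuals = 800, n_variants = 40, ld_block_size = 10,
                      ld_rho = rho, seed = 9)
    d <- simulate_genotypes(cfg)$dosage
    mean(vapply(seq(1, 39), function(j) {
      if (j %% 10 == 0) return(NA_real_) # block boundary
      cor(d[, j], d[, j + 1])^2
    }, numeric(1)), na.rm = TRUE)
  }
  vals <- c(r2_adj(0), r2_adj(0.5), r2_adj(0.95))
  expect_true(all(diff(vals) > 0))
  expect_lt(vals[1], 0.05)
  # dichotomization attenuates the latent 0.95 correlation; r2 ~ 0.4-0.5
  expect_gt(vals[3], 0.3)
})

test_that("covariates: shape, determinism, age range", {
  cfg <- sim_config(n_individuals = 100, age_range = c(39, 48), seed = 5)
  cv <- simulate_covariates(cfg)
  expect_equal(nrow(cv), 100)
  expect_setequal(names(cv), c("sample_id", "age", "sex", "bmi"))
  expect_true(all(cv$age >= 39 & cv$age <= 48))
  expect_identical(cv, simulate_covariates(cfg))
  expect_true(all(cv$sex %in% 0:1))
})

test_that("microbiome counts: alignment check, offset linearity, taxonomy sums", {
  cfg <- small_config(seed = 6)
  g <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg)
  tab <- simulate_microbiome(g, cv, cfg)
  expect_true(all(tab$counts >= 0))
  expect_true(all(tab$counts == round(tab$counts)))

  bad <- cv[rev(seq_len(nrow(cv))), ]
  expect_error(simulate_microbiome(g, bad, cfg), "do not match")

  # expected counts scale exactly with depth (offset linearity)
  d0 <- rep(5000, cfg$n_individuals)
  t1 <- simulate_microbiome(g, cv, cfg, depths = d0, keep_mu = TRUE)
  t2 <- simulate_microbiome(g, cv, cfg, depths = 2 * d0, keep_mu = TRUE)
  expect_equal(attr(t2, "mu"), 2 * attr(t1, "mu"))

  # clade counts are exact sums of member ASVs
  gen <- aggregate_taxonomy(tab, "genus")
  for (gname in colnames(gen$counts)) {
    members <- tab$taxonomy$feature[!is.na(tab$taxonomy$genus) &
                                      tab$taxonomy$genus == gname]
    expect_equal(gen$counts[, gname],
                 rowSums(tab$counts[, members, drop = FALSE]))
  }
})

test_that("null model: dosage-count correlation centers on zero", {
  cfg <- sim_config(n_individuals = 60, n_variants = 5, n_asvs = 8, seed = 7)
  g <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg)
  rhos <- vapply(1:60, function(i) {
    cfg_i <- sim_config(n_individuals = 60, n_variants = 5, n_asvs = 8,
                        seed = 1000 + i)
    tab <- simulate_microbiome(g, cv, cfg_i)
    cor(g$dosage[, 1], tab$counts[, 1], method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.06)
})

test_that("MR summary simulation: null and single-instrument behavior", {
  cfg <- small_config()
  # null causal effect, no pleiotropy
  est <- vapply(1:100, function(i) {
    ss <- simulate_mr_summary(cfg, causal_beta = 0, n_instruments = 15,
                              pleiotropy_sd = 0, stream = paste0("null", i))
    h <- harmonize(ss$exposure, ss$outcome)
    ivw(h)$beta
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)) + 0.02)

  # one instrument: Wald ratio replicate mean near the causal effect
  wald <- vapply(1:100, function(i) {
    ss <- simulate_mr_summary(cfg, causal_beta = 0.25, n_instruments = 1,
                              pleiotropy_sd = 0, exposure_beta_sd = 0.3,
                              stream = paste0("wald", i))
    h <- harmonize(ss$exposure, ss$outcome)
    wald_ratio(h$BETA_EXP, h$SE_EXP, h$BETA_OUT, h$SE_OUT)$beta
  }, numeric(1))
  expect_lt(abs(median(wald) - 0.25), 0.05)
})
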