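mk_stats <- function(beta, se, p = NULL, ea = "A", oa = "G", eaf = 0.3,
                     pos = NULL) {
  m <- length(beta)
  data.frame(SNP = paste0("rs", seq_len(m)), CHR = 1L,
             POS = pos %||% (seq_len(m) * 1e6), EA = rep(ea, length.out = m),
             OA = rep(oa, length.out = m), EAF = rep(eaf, length.out = m),
             BETA = beta, SE = se,
             P = p %||% (2 * pnorm(-abs(beta / se))), N = 10000,
             stringsAsFactors = FALSE)
}

test_that("instrument selection applies p, clumping and F filters", {
  # F = (0.3/0.1)^2 = 9 < 10: excluded
  weak <- mk_stats(0.3, 0.1)
  expect_equal(nrow(select_instruments(weak, p_max = 1)), 0)

  # two perfectly correlated variants: only the smaller p survives clumping
  set.seed(51)
  d <- rbinom(400, 2, 0.3)
  G <- toy_genotypes(cbind(d, d))
  G$variants$snp <- c("rs1", "rs2")
  colnames(G$dosage) <- G$variants$snp
  two <- mk_stats(c(0.5, 0.45), c(0.05, 0.05), p = c(1e-8, 1e-6),
                  pos = c(1e6, 1.5e6))
  kept <- select_instruments(two, G_ref = G, p_max = 1e-5)
  expect_equal(kept$SNP, "rs1")

  # engineered 9 candidates, exactly 4 survive all three filters:
  # rs1 ok, rs2 fails p, rs3 ok, rs4 clumped into rs3 (same position block),
  # rs5 fails F, rs6 ok, rs7 fails p, rs8 ok, rs9 fails F; only rs3/rs4 share
  # a clumping window (all other pairs sit > 10 Mb apart)
  set.seed(52)
  base <- rbinom(500, 2, 0.4)
  dos <- cbind(rbinom(500, 2, 0.3), rbinom(500, 2, 0.3), base, base,
               rbinom(500, 2, 0.3), rbinom(500, 2, 0.3), rbinom(500, 2, 0.3),
               rbinom(500, 2, 0.3), rbinom(500, 2, 0.3))
  Gr <- toy_genotypes(dos)
  Gr$variants$snp <- paste0("rs", 1:9)
  colnames(Gr$dosage) <- Gr$variants$snp
  cand <- mk_stats(beta = c(0.5, 0.5, 0.6, 0.55, 0.20, 0.5, 0.5, 0.5, -0.15),
                   se = c(0.05, 0.05, 0.05, 0.05, 0.066, 0.05, 0.05, 0.05, 0.05),
                   p = c(1e-8, 1e-4, 1e-9, 1e-7, 1e-6, 1e-8, 0.2, 1e-8, 1e-6),
                   pos = c(20, 40, 60, 61, 80, 100, 120, 140, 160) * 1e6)
  out <- select_instruments(cand, G_ref = Gr, p_max = 1e-5, f_min = 10)
  expect_setequal(out$SNP, c("rs1", "rs3", "rs6", "rs8"))
  expect_true(all(out$F_STAT >= 10))
})

test_that("harmonization: sign flip, identity, palindrome rules, involution", {
  ex <- mk_stats(0.2, 0.05, ea = "A", oa = "G", eaf = 0.8)
  out_flip <- mk_stats(-0.1, 0.05, ea = "G", oa = "A", eaf = 0.25)
  h <- harmonize(ex, out_flip)
  expect_equal(h$BETA_OUT, 0.1)
  expect_equal(h$EAF_OUT, 0.75)
  expect_equal(h$EA_OUT, "A")

  out_same <- mk_stats(-0.1, 0.05, ea = "A", oa = "G")
  expect_equal(harmonize(ex, out_same)$BETA_OUT, -0.1)

  # ambiguous palindromic variant dropped
  pal <- mk_stats(0.2, 0.05, ea = "A", oa = "T", eaf = 0.5)
  pal_out <- mk_stats(0.1, 0.05, ea = "A", oa = "T", eaf = 0.5)
  h2 <- harmonize(pal, pal_out)
  expect_equal(nrow(h2), 0)
  expect_equal(attr(h2, "dropped"), "rs1")
  # unambiguous palindrome kept and aligned by frequency
  pal3 <- mk_stats(0.2, 0.05, ea = "C", oa = "G", eaf = 0.8)
  pal3_out <- mk_stats(-0.1, 0.05, ea = "C", oa = "G", eaf = 0.2)
  h3 <- harmonize(pal3, pal3_out)
  expect_equal(h3$BETA_OUT, 0.1)
  # incompatible allele sets dropped
  bad <- mk_stats(0.1, 0.05, ea = "C", oa = "T")
  expect_equal(nrow(harmonize(ex, bad)), 0)
  # involution: harmonizing twice equals once
  once <- harmonize(ex, out_flip)
  renamed <- once
  names(renamed) <- sub("_OUT$", "", names(renamed))
  twice <- harmonize(ex, renamed[c("SNP", "CHR", "POS", "EA", "OA", "EAF",
                                   "BETA", "SE", "P", "N")])
  expect_equal(twice$BETA_OUT, once$BETA_OUT)
})

test_that("estimator reduction identities hold", {
  # Wald ratio hand case
  w <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.05)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.005)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.005), "undefined")

  # identical ratios: all estimators agree exactly, IVW residual scale ~ 0
  h <- data.frame(BETA_EXP = c(0.1, 0.2, 0.4), SE_EXP = rep(0.01, 3),
                  BETA_OUT = c(0.02, 0.04, 0.08), SE_OUT = rep(0.01, 3))
  expect_equal(ivw(h)$beta, 0.2, tolerance = 1e-12)
  expect_lt(ivw(h)$residual_scale, 1e-20)
  expect_equal(egger(h)$beta, 0.2, tolerance = 1e-10)
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 0.2,
               tolerance = 1e-10)

  # equal weights, ratios {0.1, 0.2, 0.3}: weighted median = 0.2
  h2 <- data.frame(BETA_EXP = rep(1, 3), SE_EXP = rep(0.01, 3),
                   BETA_OUT = c(0.1, 0.2, 0.3), SE_OUT = rep(0.1, 3))
  expect_equal(weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.2)
  # same seed, same bootstrap SE
  expect_equal(weighted_median(h2, n_boot = 200, seed = 9)$se,
               weighted_median(h2, n_boot = 200, seed = 9)$se)
  expect_error(egger(h2[1:2, ]), ">= 3")
  expect_error(weighted_median(h2[1:2, ]), ">= 3")
  expect_error(ivw(h2[1, , drop = FALSE]), ">= 2")
})

test_that("Egger recovers directional pleiotropy; wmedian resists minority invalidity", {
  set.seed(53)
  hits <- 0
  for (i in 1:60) {
    k <- 20
    bx <- runif(k, 0.05, 0.3)
    delta <- 0.05
    by <- 0.2 * bx + delta + rnorm(k, 0, 0.01)
    h <- data.frame(BETA_EXP = bx, SE_EXP = 0.005, BETA_OUT = by,
                    SE_OUT = 0.01)
    e <- egger(h)
    if (abs(e$intercept - delta) < 3 * e$intercept_se) hits <- hits + 1
  }
  expect_gte(hits, 54) # >= 90%

  # 10 valid instruments (ratio 0.3) + 4 invalid (ratio 1.0)
  set.seed(54)
  bx <- runif(14, 0.2, 0.4)
  by <- c(0.3 * bx[1:10], 1.0 * bx[11:14]) + rnorm(14, 0, 0.002)
  h <- data.frame(BETA_EXP = bx, SE_EXP = 0.005, BETA_OUT = by, SE_OUT = 0.01)
  wm <- weighted_median(h, n_boot = 200, seed = 2)
  expect_lt(abs(wm$beta - 0.3), 0.05)
})

test_that("sensitivity verdicts follow the published rule", {
  prim <- list(beta = 0.3, p = 1e-4)
  eg_ok <- list(beta = 0.25, p = 0.5, intercept_p = 0.4)
  wm_ok <- list(beta = 0.28, p = 0.02)
  expect_equal(sensitivity_verdict(prim, eg_ok, wm_ok)$verdict, "supporting")
  wm_flip <- list(beta = -0.28, p = 0.02)
  expect_equal(sensitivity_verdict(prim, eg_ok, wm_flip)$verdict,
               "weak_or_inconclusive")
  eg_bad <- list(beta = 0.25, p = 0.01)
  expect_equal(sensitivity_verdict(prim, eg_bad, wm_ok)$verdict,
               "weak_or_inconclusive")
  wm_weak <- list(beta = 0.28, p = 0.2)
  expect_equal(sensitivity_verdict(prim, eg_ok, wm_weak)$verdict,
               "weak_or_inconclusive")
  expect_equal(sensitivity_verdict(prim, NULL, wm_ok)$verdict,
               "weak_or_inconclusive")
})

test_that("per-trait and global FDR behave like BH on each family", {
  res <- data.frame(OUTCOME = c("t1", "t1", "t2", "t2", "t2"),
                    P = c(0.01, 0.04, 0.001, 0.5, 1))
  out <- fdr_correct(res)
  expect_equal(out$Q_TRAIT[1:2], p.adjust(c(0.01, 0.04), "BH"))
  expect_equal(out$Q_TRAIT[3:5], p.adjust(c(0.001, 0.5, 1), "BH"))
  expect_equal(out$Q_GLOBAL, p.adjust(res$P, "BH"))
  expect_true(all(out$Q_TRAIT >= res$P - 1e-15))
  # single test: q equals p
  one <- fdr_correct(data.frame(OUTCOME = "t", P = 0.01))
  expect_equal(one$Q_TRAIT, 0.01)
  expect_equal(one$Q_GLOBAL, 0.01)
  # all p = 1
  ones <- fdr_correct(data.frame(OUTCOME = "t", P = rep(1, 4)))
  expect_true(all(ones$Q_TRAIT == 1 & ones$Q_GLOBAL == 1))
})

test_that("run_mr cascades: IVW when > 2 instruments, Wald otherwise", {
  cfg <- small_config(seed = 55)
  ss <- simulate_mr_summary(cfg, causal_beta = 0.3, n_instruments = 15,
                            exposure_beta_sd = 0.3, stream = "cascade")
  r <- run_mr(ss$exposure, ss$outcome, "expo", "outc", p_max = 1e-5)
  expect_equal(r$METHOD, "ivw")
  expect_true(r$N_SNPS > 2)
  expect_true(is.finite(r$EGGER_INTERCEPT_P))

  ss2 <- simulate_mr_summary(cfg, causal_beta = 0.3, n_instruments = 2,
                             exposure_beta_sd = 0.3, stream = "wald2")
  r2 <- run_mr(ss2$exposure, ss2$outcome, p_max = 1)
  expect_equal(r2$METHOD, "wald")
  expect_equal(r2$VERDICT, "weak_or_inconclusive")
})
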