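#' Simulation configuration for a synthetic microbiome-GWAS study
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate a
#' modest population cohort: adult participants in the 39-48 y band, lognormal
#' sequencing depth with median 20,000 reads, negative-binomial taxon counts
#' whose log-mean carries confounder and (optional) planted SNP effects, and
#' LD blocks generated by a Gaussian AR(1) copula over haplotypes.
#'
#' @param n_individuals individuals per cohort.
#' @param n_variants number of variants.
#' @param maf_range interval within (0, 0.5] from which per-variant allele
#'   frequencies are drawn uniformly.
#' @param ld_block_size variants per correlated LD block (1 = independence).
#' @param ld_rho AR(1) latent haplotype correlation within a block, in [0, 1).
#' @param n_asvs number of ASVs.
#' @param taxonomy_depth number of ranks above ASV (5 = genus...phylum).
#' @param depth_lognormal_params `c(meanlog, sdlog)` of sequencing depth.
#' @param planted_effects `data.frame(variant, feature, beta)`: SNP dosage
#'   effects on the log-mean of the named ASV.
#' @param confounder_effects optional `data.frame(feature, age, sex, bmi)` of
#'   per-ASV log-scale confounder coefficients; if `NULL` they are drawn once
#'   from centered normals with sd 0.01 (age, per year), 0.2 (sex) and
#'   0.02 (BMI, per unit).
#' @param dispersion_range interval from which per-ASV NB dispersions
#'   (`theta`, with Var = mu + mu^2/theta) are drawn log-uniformly.
#' @param age_range adult age band in years.
#' @param unclassified_prob probability that an ASV is unclassified at genus.
#' @param seed master seed; all sub-generators derive child streams from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 250, n_variants = 2000,
                       maf_range = c(0.05, 0.5), ld_block_size = 1,
                       ld_rho = 0, n_asvs = 50, taxonomy_depth = 5,
                       depth_lognormal_params = c(log(20000), 0.5),
                       planted_effects = NULL, confounder_effects = NULL,
                       dispersion_range = c(0.5, 5), age_range = c(39, 48),
                       unclassified_prob = 0.1, seed = 1L) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  stopifnot(n_individuals >= 1, n_variants >= 1, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1, n_asvs >= 1,
            dispersion_range[1] > 0, dispersion_range[1] <= dispersion_range[2])
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("variant", "feature", "beta") %in% names(planted_effects)))
    if (any(planted_effects$variant > n_variants | planted_effects$variant < 1))
      stop("planted effect variant indices must lie in [1, n_variants]")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants), maf_range = maf_range,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    n_asvs = as.integer(n_asvs), taxonomy_depth = as.integer(taxonomy_depth),
    depth_lognormal_params = depth_lognormal_params,
    planted_effects = planted_effects, confounder_effects = confounder_effects,
    dispersion_range = dispersion_range, age_range = age_range,
    unclassified_prob = unclassified_prob, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Construct a genotype matrix object
#'
#' @param dosage samples x variants matrix of 0/1/2 dosages (NA = missing).
#' @param variants data.frame with columns `snp, chr, pos, ea, oa` (EAF is
#'   recomputed from the dosages).
#' @param samples optional data.frame with `sample_id` and `cohort`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples = NULL) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage),
            all(c("snp", "chr", "pos", "ea", "oa") %in% names(variants)))
  if (is.null(samples))
    samples <- data.frame(sample_id = rownames(dosage) %||%
                            paste0("S", seq_len(nrow(dosage))),
                          cohort = "cohort1")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$snp
  variants$eaf <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d cohort(s))\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$samples$cohort))))
  invisible(x)
}

#' Simulate genotypes under Hardy-Weinberg with block LD
#'
#' Allele frequencies are drawn uniformly from `maf_range`. Within each block
#' of `ld_block_size` variants, the two haplotypes of an individual follow a
#' Gaussian AR(1) copula with parameter `ld_rho`, thresholded to alleles, so
#' adjacent-variant r^2 increases monotonically with `ld_rho`; across blocks
#' variants are independent. Dosages are the per-individual allele counts of
#' the effect allele, giving HWE genotype proportions marginally.
#'
#' @param config a [sim_config()].
#' @param cohort cohort label stored with the samples.
#' @return a `genotype_matrix` with 1-based positions and realized EAF.
#' @export
simulate_genotypes <- function(config, cohort = "cohort1") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals; m <- config$n_variants
  with_seed(child_seed(config$seed, paste0("genotypes/", cohort)), {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    thr <- qnorm(p)
    rho <- config$ld_rho; bs <- config$ld_block_size
    hap <- function() {
      z <- matrix(rnorm(n * m), n, m)
      if (rho > 0 && bs > 1) {
        for (j in seq_len(m)[-1]) {
          if ((j - 1) %/% bs == (j - 2) %/% bs) # same block as predecessor
            z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
      }
      sweep(z, 2, thr, "<") * 1L
    }
    dosage <- hap() + hap()
    variants <- data.frame(
      snp = sprintf("rs%06d", seq_len(m)),
      chr = rep(1L, m),
      pos = seq_len(m) * 5000L, # 1-based, 5 kb spacing
      ea = "A", oa = "G",
      stringsAsFactors = FALSE
    )
    genotype_matrix(dosage, variants,
                    samples = data.frame(
                      sample_id = sprintf("%s_I%04d", cohort, seq_len(n)),
                      cohort = cohort, stringsAsFactors = FALSE))
  })
}

#' Simulate host covariates (age, sex, BMI)
#'
#' Age uniform on `config$age_range`, sex Bernoulli(0.5) coded 0/1, BMI
#' lognormal with median 26 kg/m^2. Genetic PCs are not simulated: they are
#' computed from the genotypes by [genetic_pcs()].
#'
#' @inheritParams simulate_genotypes
#' @return data.frame with `sample_id, age, sex, bmi`.
#' @export
simulate_covariates <- function(config, cohort = "cohort1") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  with_seed(child_seed(config$seed, paste0("covariates/", cohort)), {
    data.frame(
      sample_id = sprintf("%s_I%04d", cohort, seq_len(n)),
      age = runif(n, config$age_range[1], config$age_range[2]),
      sex = rbinom(n, 1, 0.5),
      bmi = rlnorm(n, log(26), 0.15),
      stringsAsFactors = FALSE
    )
  })
}

# Nested taxonomy ladder for n ASVs: genus..phylum labels, with a fraction of
# ASVs unclassified at genus (their genus is NA; higher ranks remain known).
simulate_taxonomy <- function(config) {
  n <- config$n_asvs
  with_seed(child_seed(config$seed, "taxonomy"), {
    n_gen <- max(3L, ceiling(n / 3))
    n_fam <- max(2L, ceiling(n_gen / 2))
    n_ord <- max(2L, ceiling(n_fam / 1.5))
    n_cla <- max(2L, ceiling(n_ord / 1.5))
    n_phy <- max(2L, ceiling(n_cla / 2))
    gen_of_asv <- sample.int(n_gen, n, replace = TRUE)
    fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
    ord_of_fam <- sample.int(n_ord, n_fam, replace = TRUE)
    cla_of_ord <- sample.int(n_cla, n_ord, replace = TRUE)
    phy_of_cla <- sample.int(n_phy, n_cla, replace = TRUE)
    unc <- runif(n) < config$unclassified_prob
    g <- sprintf("Genus_%02d", gen_of_asv)
    g[unc] <- NA_character_
    fam <- fam_of_gen[gen_of_asv]; ord <- ord_of_fam[fam]
    cla <- cla_of_ord[ord]; phy <- phy_of_cla[cla]
    data.frame(
      feature = sprintf("ASV%03d", seq_len(n)),
      genus = g,
      family = sprintf("Family_%02d", fam),
      order = sprintf("Order_%02d", ord),
      class = sprintf("Class_%02d", cla),
      phylum = sprintf("Phylum_%02d", phy),
      stringsAsFactors = FALSE
    )
  })
}

#' Construct an abundance table object
#'
#' @param counts samples x features non-negative integer matrix.
#' @param taxonomy data.frame with `feature` plus rank columns
#'   (`genus, family, order, class, phylum`); NA = unclassified at that rank.
#' @param samples data.frame with `sample_id` and optionally `cohort`, `site`.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy, samples = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            "feature" %in% names(taxonomy),
            ncol(counts) == nrow(taxonomy))
  if (is.null(samples))
    samples <- data.frame(sample_id = rownames(counts) %||%
                            paste0("S", seq_len(nrow(counts))))
  rownames(counts) <- samples$sample_id
  colnames(counts) <- taxonomy$feature
  structure(list(counts = counts, taxonomy = taxonomy, samples = samples),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Simulate an ASV count table driven by genotypes and covariates
#'
#' Inverts the analysis model: each ASV count is negative binomial with
#' `log(mu) = baseline + beta_age*(age-mean) + beta_sex*sex + beta_bmi*(bmi-mean)
#' + sum(planted beta * dosage) + log(depth)`, with per-sample depth drawn
#' lognormally (or supplied) and per-ASV dispersion drawn log-uniformly from
#' `dispersion_range`. Baseline log relative abundances follow a stick-breaking
#' profile so a few ASVs dominate, as in real amplicon data.
#'
#' @param genotypes a `genotype_matrix`.
#' @param covariates data.frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @param site label stored with the samples (also salts the random stream,
#'   so different sites of a cohort get independent draws).
#' @param depths optional fixed per-sample sequencing depths.
#' @param keep_mu if TRUE the expected-count matrix is attached as attribute
#'   `"mu"` (used by tests of offset linearity).
#' @return an `abundance_table`.
#' @export
simulate_microbiome <- function(genotypes, covariates, config, site = "siteA",
                                depths = NULL, keep_mu = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (!identical(genotypes$samples$sample_id, covariates$sample_id))
    stop("genotype and covariate sample sets do not match")
  n <- nrow(genotypes$dosage)
  taxa <- simulate_taxonomy(config)
  k <- config$n_asvs
  with_seed(child_seed(config$seed, paste0("microbiome/", site, "/",
                                           genotypes$samples$cohort[1])), {
    # per-ASV baseline relative abundance: stick-breaking (GEM) profile
    sticks <- rbeta(k, 1, 5)
    prop <- sticks * cumprod(c(1, 1 - sticks[-k]))
    prop <- prop / sum(prop)
    base <- log(prop)
    ce <- config$confounder_effects
    if (is.null(ce)) {
      ce <- data.frame(feature = taxa$feature,
                       age = rnorm(k, 0, 0.01),
                       sex = rnorm(k, 0, 0.2),
                       bmi = rnorm(k, 0, 0.02))
    }
    ce <- ce[match(taxa$feature, ce$feature), ]
    theta <- exp(runif(k, log(config$dispersion_range[1]),
                       log(config$dispersion_range[2])))
    if (is.null(depths)) {
      dp <- config$depth_lognormal_params
      depths <- rlnorm(n, dp[1], dp[2])
    }
    eta <- outer(rep(1, n), base) +
      outer(covariates$age - mean(covariates$age), ce$age) +
      outer(covariates$sex, ce$sex) +
      outer(covariates$bmi - mean(covariates$bmi), ce$bmi)
    pe <- config$planted_effects
    if (!is.null(pe)) {
      for (i in seq_len(nrow(pe))) {
        j <- match(pe$feature[i], taxa$feature)
        if (is.na(j)) stop("planted effect names unknown feature: ", pe$feature[i])
        eta[, j] <- eta[, j] + pe$beta[i] * genotypes$dosage[, pe$variant[i]]
      }
    }
    mu <- exp(eta + log(depths))
    counts <- matrix(rnbinom(n * k, mu = mu, size = rep(theta, each = n)), n, k)
    out <- abundance_table(counts, taxa,
                           samples = cbind(genotypes$samples, site = site,
                                           stringsAsFactors = FALSE))
    if (keep_mu) attr(out, "mu") <- mu
    out
  })
}

#' Simulate exposure/outcome GWAS summary statistics for MR
#'
#' Generates `n_instruments` independent variants whose true effects on a
#' microbial exposure are drawn N(0, `exposure_beta_sd`^2); the outcome effect
#' of each variant is `causal_beta` times its exposure effect plus pleiotropy
#' noise N(0, `pleiotropy_sd`^2). Estimation noise reflects GWAS sample sizes
#' `n_exposure` and `n_outcome` through the usual 1/(2 N p(1-p)) variance.
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param causal_beta true causal effect of exposure on outcome.
#' @param n_instruments number of instrument variants (>= 1).
#' @param pleiotropy_sd sd of per-variant directional pleiotropy.
#' @param exposure_beta_sd sd of true instrument effects on the exposure.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param stream tag appended to the child seed (vary across replicates).
#' @return list with `exposure` and `outcome` summary-statistics data.frames
#'   (columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N).
#' @export
simulate_mr_summary <- function(config, causal_beta, n_instruments,
                                pleiotropy_sd = 0, exposure_beta_sd = 0.1,
                                n_exposure = 20000, n_outcome = 50000,
                                stream = "mr") {
  stopifnot(inherits(config, "sim_config"), n_instruments >= 1)
  with_seed(child_seed(config$seed, paste0("mr_summary/", stream)), {
    m <- n_instruments
    eaf <- runif(m, 0.1, 0.9)
    bx <- rnorm(m, 0, exposure_beta_sd)
    se_x <- 1 / sqrt(2 * n_exposure * eaf * (1 - eaf))
    se_y <- 1 / sqrt(2 * n_outcome * eaf * (1 - eaf))
    bx_hat <- bx + rnorm(m, 0, se_x)
    by <- causal_beta * bx + rnorm(m, 0, pleiotropy_sd)
    by_hat <- by + rnorm(m, 0, se_y)
    alleles <- cbind(ea = rep("A", m), oa = rep("G", m))
    mk <- function(beta, se, n) data.frame(
      SNP = sprintf("rs%06d", seq_len(m)), CHR = 1L,
      POS = seq_len(m) * 1000000L, EA = alleles[, "ea"], OA = alleles[, "oa"],
      EAF = eaf, BETA = beta, SE = se,
      P = 2 * pnorm(-abs(beta / se)), N = n, stringsAsFactors = FALSE)
    list(exposure = mk(bx_hat, se_x, n_exposure),
         outcome = mk(by_hat, se_y, n_outcome))
  })
}

#' Simulate a full two-cohort, multi-site study
#'
#' Emulates the design of a two-cohort skin study: a moist microenvironment
#' sampled at the same site in both cohorts, a sebaceous microenvironment
#' sampled at a different site in each cohort, and a dry microenvironment with
#' two sites in the second cohort only.
#'
#' @param config a [sim_config()]; the same genotype/covariate set is shared
#'   by all sites of a cohort.
#' @return list with `genotypes` (per cohort), `covariates` (per cohort),
#'   `tables` (per "cohort.site"), and a `design` data.frame mapping sites to
#'   microenvironments and cohorts.
#' @export
simulate_study <- function(config) {
  design <- data.frame(
    cohort = c("cohort1", "cohort2", "cohort1", "cohort2", "cohort2", "cohort2"),
    site = c("antecubital_fossa", "antecubital_fossa", "retroauricular_fold",
             "forehead", "dorsal_forearm", "volar_forearm"),
    microenv = c("moist", "moist", "sebaceous", "sebaceous", "dry", "dry"),
    stringsAsFactors = FALSE
  )
  cohorts <- unique(design$cohort)
  genotypes <- lapply(cohorts, function(co) simulate_genotypes(config, co))
  names(genotypes) <- cohorts
  covariates <- lapply(cohorts, function(co) simulate_covariates(config, co))
  names(covariates) <- cohorts
  tables <- list()
  for (i in seq_len(nrow(design))) {
    co <- design$cohort[i]; si <- design$site[i]
    tables[[paste(co, si, sep = ".")]] <-
      simulate_microbiome(genotypes[[co]], covariates[[co]], config, site = si)
  }
  list(genotypes = genotypes, covariates = covariates, tables = tables,
       design = design)
}
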