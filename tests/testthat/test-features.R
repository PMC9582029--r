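test_that("taxonomy aggregation sums member ASVs and conserves totals", {
  tab <- toy_table()
  gen <- aggregate_taxonomy(tab, "genus")
  # ASV1(G1)=[3,1,0], ASV2(G1)=[4,2,0] -> G1=[7,3,0]
  expect_equal(unname(gen$counts[, "G1"]), c(7, 3, 0))
  # single-ASV genus passes through unchanged
  expect_equal(unname(gen$counts[, "G2"]), unname(tab$counts[, "ASV3"]))
  # conservation over classified ASVs
  classified <- !is.na(tab$taxonomy$genus)
  expect_equal(sum(gen$counts), sum(tab$counts[, classified]))
  # unclassified ASV4 is excluded at genus but present at family
  fam <- aggregate_taxonomy(tab, "family")
  expect_equal(unname(fam$counts[, "F2"]),
               unname(rowSums(tab$counts[, 4:6])))
  expect_error(aggregate_taxonomy(tab, "kingdom"), "unknown taxonomic rank")
})

test_that("rarefaction: exact depth, determinism, zero stays zero", {
  tab <- toy_table()
  tab$counts <- tab$counts * 10 # totals 150, 90, 100
  r <- rarefy(tab, 90, seed = 2)
  expect_true(all(rowSums(r$counts) == 90))
  # the sample whose total equals the depth is preserved exactly
  expect_equal(r$counts["S2", ], tab$counts["S2", ])
  # zero counts never gain mass
  expect_true(all(r$counts[tab$counts[rownames(r$counts), ] == 0] == 0))
  expect_identical(rarefy(tab, 90, seed = 2)$counts, r$counts)
  # samples below depth are dropped and logged
  r2 <- rarefy(tab, 120, seed = 1)
  expect_setequal(attr(r2, "dropped"), c("S2", "S3"))
  expect_error(rarefy(tab, 0), "positive")
})

test_that("rarefaction preserves relative-abundance expectations", {
  x <- c(500, 300, 150, 50, 0)
  tab <- abundance_table(matrix(x, 1), data.frame(feature = paste0("A", 1:5)),
                        data.frame(sample_id = "S1"))
  draws <- vapply(1:300, function(i) rarefy(tab, 100, seed = i)$counts[1, ],
                  numeric(5))
  expect_equal(unname(rowMeans(draws) / 100), x / sum(x), tolerance = 0.03)
})

test_that("median/prevalence filters with both-sites rule", {
  # engineered: exactly 2 of 5 features pass at both sites
  n <- 120
  mk <- function(meds) {
    m <- sapply(meds, function(md) rep(md, n))
    colnames(m) <- paste0("f", seq_along(meds))
    m
  }
  a <- mk(c(60, 60, 51, 50, 10))  # f4 fails median (50 not > 50), f5 fails
  b <- mk(c(70, 55, 40, 80, 90))  # f3 fails median at site b
  pass <- filter_features(list(a, b), median_min = 50, prevalence_min = 100)
  expect_setequal(pass, c("f1", "f2"))

  # prevalence is strict: present in exactly 100 participants fails
  cc <- matrix(0, n, 1, dimnames = list(NULL, "g1"))
  cc[1:100, 1] <- 1000
  expect_length(filter_features(list(cc, cc), 50, 100), 0)
  cc[101, 1] <- 1000
  expect_equal(filter_features(list(cc, cc), 50, 100), "g1",
               ignore_attr = TRUE)
})

test_that("redundancy clustering merges rho > cutoff and picks deep representatives", {
  set.seed(1)
  base <- rnorm(50)
  m <- cbind(`a.ASV001` = base,
             `g.Genus_01` = 2 * base + 5, # Spearman rho = 1 with ASV001
             `f.Family_01` = rnorm(50))
  cl <- cluster_redundant(m, rho_cut = 0.985)
  expect_equal(nrow(cl), 2)
  # representative of the merged pair is the deepest rank (the ASV)
  expect_true("a.ASV001" %in% cl$feature)
  expect_false("g.Genus_01" %in% cl$feature)
  expect_match(cl$members[cl$feature == "a.ASV001"], "g.Genus_01")

  # all mutually below cutoff: identity
  m2 <- matrix(rnorm(200), 50, 4,
               dimnames = list(NULL, paste0("a.A", 1:4)))
  expect_equal(nrow(cluster_redundant(m2)), 4)
})

test_that("Bray-Curtis matches the closed form and vegan oracle", {
  m <- rbind(S1 = c(1, 0), S2 = c(1, 1))
  D <- bray_curtis(m)
  expect_equal(D[1, 2], 1 / 3)
  expect_equal(diag(D), c(S1 = 0, S2 = 0))
  # identical and disjoint samples
  m2 <- rbind(a = c(2, 3, 0), b = c(2, 3, 0), c = c(0, 0, 9))
  D2 <- bray_curtis(m2)
  expect_equal(D2["a", "b"], 0)
  expect_equal(D2["a", "c"], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "zero total")

  skip_if_not_installed("vegan")
  set.seed(8)
  big <- matrix(rpois(300, 20), 15, 20)
  expect_equal(bray_curtis(big),
               as.matrix(vegan::vegdist(big, method = "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("feature construction is equivariant to sample reordering", {
  cfg <- small_config(seed = 11)
  g <- simulate_genotypes(cfg)
  cv <- simulate_covariates(cfg)
  tab <- simulate_microbiome(g, cv, cfg)
  fm <- build_feature_matrix(tab)
  perm <- sample(nrow(tab$counts))
  tab2 <- abundance_table(tab$counts[perm, ], tab$taxonomy,
                          tab$samples[perm, , drop = FALSE])
  fm2 <- build_feature_matrix(tab2)
  expect_equal(fm2, fm[perm, colnames(fm2)])
  f1 <- filter_features(list(fm, fm), 5, 60)
  f2 <- filter_features(list(fm2, fm2), 5, 60)
  expect_setequal(f1, f2)
})
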