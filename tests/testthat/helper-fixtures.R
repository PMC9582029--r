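# Shared fixtures: everything is generated in code at test time.

small_config <- function(seed = 1L, ...) {
  sim_config(n_individuals = 120, n_variants = 150, n_asvs = 25, seed = seed,
             ...)
}

# tiny hand-built abundance table with a known taxonomy ladder
toy_table <- function() {
  counts <- matrix(c(3, 4, 1, 2, 0, 5,
                     1, 2, 3, 0, 2, 1,
                     0, 0, 4, 4, 1, 1), nrow = 3, byrow = TRUE)
  taxonomy <- data.frame(
    feature = paste0("ASV", 1:6),
    genus = c("G1", "G1", "G2", NA, "G3", "G3"),
    family = c("F1", "F1", "F1", "F2", "F2", "F2"),
    order = c("O1", "O1", "O1", "O1", "O1", "O1"),
    class = c("C1", "C1", "C1", "C1", "C1", "C1"),
    phylum = c("P1", "P1", "P1", "P1", "P1", "P1"),
    stringsAsFactors = FALSE)
  abundance_table(counts, taxonomy,
                  data.frame(sample_id = paste0("S", 1:3)))
}

# small genotype matrix built by hand
toy_genotypes <- function(dosage, ea = NULL, oa = NULL) {
  m <- ncol(dosage)
  genotype_matrix(dosage, data.frame(
    snp = paste0("v", seq_len(m)), chr = 1L, pos = seq_len(m) * 1000L,
    ea = ea %||% rep("A", m), oa = oa %||% rep("G", m),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo permutation p-value for the explained-SS statistic, written
# independently of the package's fallback (used as the oracle).
oracle_perm_p <- function(coords, dosage, n_perm, seed) {
  x <- dosage - mean(dosage)
  G <- tcrossprod(coords)
  q_obs <- drop(crossprod(x, G %*% x))
  set.seed(seed)
  n <- length(x)
  hits <- 0L
  block <- 1000L
  left <- n_perm
  while (left > 0) {
    b <- min(block, left)
    Z <- matrix(0, n, b)
    for (i in seq_len(b)) Z[, i] <- x[sample.int(n)]
    hits <- hits + sum(colSums(Z * (G %*% Z)) >= q_obs - 1e-12 * abs(q_obs))
    left <- left - b
  }
  (hits + 1) / (n_perm + 1)
}
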