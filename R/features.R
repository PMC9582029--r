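#' Aggregate ASV counts to a taxonomic rank
#'
#' Counts of all ASVs sharing the same taxonomy at `rank` are summed into one
#' feature per taxon. ASVs unclassified (NA) at that rank are excluded from
#' the aggregation (they remain available as ASV-level features).
#'
#' @param table an `abundance_table` at ASV level.
#' @param rank one of `"genus", "family", "order", "class", "phylum"`.
#' @return an `abundance_table` with one feature per taxon at `rank`.
#' @export
aggregate_taxonomy <- function(table, rank) {
  stopifnot(inherits(table, "abundance_table"))
  if (!rank %in% names(table$taxonomy) || rank == "feature")
    stop("unknown taxonomic rank: ", rank)
  lab <- table$taxonomy[[rank]]
  keep <- !is.na(lab)
  if (!any(keep)) stop("no ASV is classified at rank ", rank)
  groups <- lab[keep]
  sub <- table$counts[, keep, drop = FALSE]
  agg <- t(rowsum(t(sub), group = groups)) # exact sums of member ASVs
  taxa <- unique(table$taxonomy[keep, setdiff(names(table$taxonomy), "feature"),
                                drop = FALSE])
  ranks_above <- c("genus", "family", "order", "class", "phylum")
  keep_cols <- ranks_above[seq(match(rank, ranks_above), length(ranks_above))]
  taxa <- unique(taxa[, keep_cols, drop = FALSE])
  taxa <- taxa[match(colnames(agg), taxa[[rank]]), , drop = FALSE]
  taxonomy <- cbind(feature = colnames(agg), taxa, stringsAsFactors = FALSE)
  rownames(taxonomy) <- NULL
  abundance_table(agg, taxonomy, table$samples)
}

#' Rarefy an abundance table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` total
#' counts; samples whose total is below `depth` are dropped (and listed in the
#' `"dropped"` attribute). Each sample uses its own deterministic child seed.
#'
#' @param table an `abundance_table`.
#' @param depth target total count per sample (>= 1).
#' @param seed integer seed.
#' @return a rarefied `abundance_table`; attribute `"dropped"` holds the ids
#'   of removed samples.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  if (depth <= 0) stop("rarefaction depth must be positive")
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  out <- table$counts[keep, , drop = FALSE]
  ids <- table$samples$sample_id[keep]
  for (i in seq_len(nrow(out))) {
    x <- out[i, ]
    tot <- sum(x)
    if (tot == depth) next
    with_seed(child_seed(seed, paste0("rarefy/", ids[i])), {
      drawn <- sample.int(tot, depth) # positions in the read multiset
      cum <- cumsum(x)
      out[i, ] <- tabulate(findInterval(drawn - 1L, c(0L, cum), left.open = FALSE),
                           nbins = length(x))
    })
  }
  res <- abundance_table(out, table$taxonomy,
                         table$samples[keep, , drop = FALSE])
  attr(res, "dropped") <- table$samples$sample_id[!keep]
  res
}

#' Build the rank-prefixed candidate feature matrix for one site
#'
#' Stacks ASV-level counts with aggregations at every rank from genus to
#' phylum, naming features with the field's rank prefixes (`a.` ASV,
#' `g.` genus, `f.` family, `o.` order, `c.` class, `p.` phylum).
#'
#' @param table an ASV-level `abundance_table`.
#' @return samples x features numeric matrix with prefixed column names.
#' @export
build_feature_matrix <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  prefix <- c(genus = "g.", family = "f.", order = "o.", class = "c.",
              phylum = "p.")
  mats <- list(a = {
    m <- table$counts
    colnames(m) <- paste0("a.", colnames(m))
    m
  })
  for (rk in names(prefix)) {
    if (!rk %in% names(table$taxonomy)) next
    if (all(is.na(table$taxonomy[[rk]]))) next
    ag <- aggregate_taxonomy(table, rk)$counts
    colnames(ag) <- paste0(prefix[rk], colnames(ag))
    mats[[rk]] <- ag
  }
  do.call(cbind, unname(mats))
}

#' Median-count and prevalence filter, with the both-sites rule
#'
#' A univariate feature is a candidate for a microenvironment iff, at *each*
#' of the microenvironment's two sites, its median count exceeds `median_min`
#' (strict) and it is present (count > 0) in more than `prevalence_min`
#' participants (strict).
#'
#' @param site_features named list of two samples x features matrices (one per
#'   site of a microenvironment), as built by [build_feature_matrix()].
#' @param median_min median count threshold (default 50).
#' @param prevalence_min participant-presence threshold (default 100).
#' @return character vector of features passing at both sites; attribute
#'   `"per_site"` holds the per-site survivor lists.
#' @export
filter_features <- function(site_features, median_min = 50,
                            prevalence_min = 100) {
  stopifnot(is.list(site_features), length(site_features) == 2)
  pass1 <- lapply(site_features, function(m) {
    med <- apply(m, 2, median)
    prev <- colSums(m > 0)
    colnames(m)[med > median_min & prev > prevalence_min]
  })
  out <- intersect(pass1[[1]], pass1[[2]])
  attr(out, "per_site") <- pass1
  out
}

# rank depth for representative choice: ASVs are deepest
.rank_depth <- c(a. = 6, g. = 5, f. = 4, o. = 3, c. = 2, p. = 1)

feature_rank_depth <- function(x) {
  pre <- substr(x, 1, 2)
  d <- .rank_depth[pre]
  d[is.na(d)] <- 0
  unname(d)
}

#' Collapse redundant features by Spearman correlation clustering
#'
#' Features whose pairwise Spearman correlation exceeds `rho_cut` are linked;
#' connected components form clusters (single linkage at the cutoff, computed
#' per microenvironment). One representative is retained per cluster: the
#' feature of deepest taxonomic rank (ASV > genus > ... > phylum), ties broken
#' alphabetically. Ties in ranks use average ranks (standard Spearman).
#'
#' @param candidates samples x features matrix restricted to the candidate
#'   features of one microenvironment (sites stacked by row).
#' @param rho_cut clustering cutoff (default 0.985, strict `>`).
#' @return data.frame with `feature` (representative), `cluster` id and
#'   `members` (comma-joined member list).
#' @export
cluster_redundant <- function(candidates, rho_cut = 0.985) {
  stopifnot(is.matrix(candidates))
  p <- ncol(candidates)
  if (p == 0) return(data.frame(feature = character(), cluster = integer(),
                                members = character()))
  rho <- cor(apply(candidates, 2, rank), method = "pearson")
  adj <- rho > rho_cut
  # connected components by repeated expansion
  comp <- integer(p); cur <- 0L
  for (i in seq_len(p)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  nm <- colnames(candidates)
  out <- lapply(seq_len(cur), function(cl) {
    mem <- nm[comp == cl]
    depth <- feature_rank_depth(mem)
    rep <- mem[order(-depth, mem)][1]
    data.frame(feature = rep, cluster = cl,
               members = paste(sort(mem), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 * sum(min(x_i, y_i)) / (sum(x) + sum(y))`, computed on
#' (typically rarefied) count rows.
#'
#' @param table an `abundance_table` or a samples x features count matrix.
#' @return a square symmetric matrix of class `matrix` with zero diagonal and
#'   entries in [0, 1], labeled by sample id.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else table
  stopifnot(is.matrix(m), all(m >= 0))
  tot <- rowSums(m)
  if (any(tot == 0)) stop("samples with zero total count: ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    shared <- colSums(pmin(t(m[(i + 1):n, , drop = FALSE]), m[i, ]))
    D[i, (i + 1):n] <- D[(i + 1):n, i] <-
      1 - 2 * shared / (tot[(i + 1):n] + tot[i])
  }
  D
}

#' Build the per-microenvironment feature set
#'
#' Convenience wrapper running [build_feature_matrix()], [filter_features()]
#' and [cluster_redundant()] for the two sites of one microenvironment.
#'
#' @param tables named list of two ASV-level `abundance_table`s (the two sites).
#' @param median_min,prevalence_min passed to [filter_features()].
#' @param rho_cut passed to [cluster_redundant()].
#' @return data.frame of retained features with cluster membership; attribute
#'   `"matrices"` holds the per-site feature matrices restricted to survivors.
#' @export
build_feature_set <- function(tables, median_min = 50, prevalence_min = 100,
                              rho_cut = 0.985) {
  stopifnot(length(tables) == 2)
  mats <- lapply(tables, build_feature_matrix)
  cand <- filter_features(mats, median_min, prevalence_min)
  if (length(cand) == 0)
    return(structure(data.frame(feature = character(), cluster = integer(),
                                members = character()), matrices = mats))
  stacked <- do.call(rbind, lapply(mats, function(m) m[, cand, drop = FALSE]))
  fs <- cluster_redundant(stacked, rho_cut)
  attr(fs, "matrices") <- lapply(mats, function(m) m[, fs$feature, drop = FALSE])
  fs
}
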