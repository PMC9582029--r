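# Exact permutation moments of the quadratic form Q = z' G z, where z is a
# uniformly random permutation of the entries of a fixed centered vector x and
# G is a symmetric, doubly centered n x n matrix (G 1 = 0).
#
# The r-th moment expands over the 2r index slots of the r copies of G.
# Grouping terms by the set partition P induced by index coincidences,
#
#   E[Q^r] = sum_P  S_G^=(P) * D_x(m(P)) / n_(d(P))
#
# where S_G^=(P) sums the G products over *distinct* block indices, D_x(m) is
# the distinct-index power-product sum of x for the block-size multiset m, and
# n_(d) is a falling factorial. Distinct-index sums follow from unrestricted
# tensor contractions by Mobius inversion on the partition lattice; double
# centering kills every contraction with a singleton block, so only
# contractions of partitions with all blocks >= 2 survive (at most r free
# indices). Because D_x depends on P only through its block-size multiset m,
# everything data-dependent collapses to
#
#   E[Q^r] = sum_m  D_x(m)/n_(|m|) * W_m,   W_m = sum_{Q good} C[m, Q] S_all(Q)
#
# with a data-independent integer-combinatorial matrix C precomputed once per
# moment order (r <= 4) and cached.

# ---- set-partition combinatorics (data independent, cached) ----------------

# All set partitions of {1..k} as restricted-growth block-assignment vectors.
set_partitions <- function(k) {
  parts <- list()
  a <- integer(k)
  rec <- function(i, mx) {
    if (i > k) {
      parts[[length(parts) + 1L]] <<- a
      return(invisible(NULL))
    }
    for (b in seq_len(mx + 1L)) {
      a[i] <<- b
      rec(i + 1L, max(mx, b))
    }
  }
  rec(1L, 0L)
  parts
}

# integer partitions of k (multisets of block sizes), sorted descending
integer_partitions <- function(k, max_part = k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (first in seq_len(min(k, max_part))) {
    for (rest in integer_partitions(k - first, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

multiset_key <- function(m) paste(sort(m, decreasing = TRUE), collapse = ",")

# Terms of the distinct-index power-product sum D(m) as a function of the
# power sums s_k of x: D(m) = sum_R mu(0,R) prod_{B in R} s_{sum_{t in B} m_t},
# aggregated over partitions R yielding identical power-sum products.
distinct_powersum_terms <- function(m) {
  d <- length(m)
  acc <- new.env(parent = emptyenv())
  for (r in set_partitions(d)) {
    blocks <- split(seq_len(d), r)
    coef <- prod(vapply(blocks, function(b)
      (-1)^(length(b) - 1) * factorial(length(b) - 1), numeric(1)))
    exps <- sort(vapply(blocks, function(b) sum(m[b]), numeric(1)))
    key <- paste(exps, collapse = ",")
    prev <- acc[[key]]
    acc[[key]] <- list(coef = (if (is.null(prev)) 0 else prev$coef) + coef,
                       exps = as.integer(exps))
  }
  out <- as.list(acc)
  names(out) <- NULL
  out[vapply(out, function(t) t$coef != 0, logical(1))]
}

.moment_cache <- new.env(parent = emptyenv())

# Structure for moment order r: the "good" partitions of 2r slots (all blocks
# >= 2), the aggregation matrix C[m, Q], and D(m) term tables per block-size
# multiset m.
moment_structure <- function(r) {
  key <- as.character(r)
  if (!is.null(.moment_cache[[key]])) return(.moment_cache[[key]])
  k <- 2L * r
  good <- Filter(function(p) min(tabulate(p)) >= 2L, set_partitions(k))
  msets <- integer_partitions(k)
  mkeys <- vapply(msets, multiset_key, character(1))
  C <- matrix(0, length(msets), length(good),
              dimnames = list(mkeys, NULL))
  for (j in seq_along(good)) {
    q <- good[[j]]
    blocks <- split(seq_len(k), q)
    # refinements of q = independent partitions of each block
    sub <- lapply(blocks, function(b) set_partitions(length(b)))
    idx <- lapply(sub, seq_along)
    for (combo in split(as.matrix(expand.grid(idx)), seq_len(prod(lengths(idx))))) {
      mu <- 1
      sizes <- integer(0)
      for (bi in seq_along(blocks)) {
        sp <- sub[[bi]][[combo[bi]]]
        nb <- max(sp)
        mu <- mu * (-1)^(nb - 1) * factorial(nb - 1)
        sizes <- c(sizes, tabulate(sp))
      }
      C[multiset_key(sizes), j] <- C[multiset_key(sizes), j] + mu
    }
  }
  st <- list(good = good, C = C,
             m_d = lengths(msets),
             dterms = lapply(msets, distinct_powersum_terms))
  .moment_cache[[key]] <- st
  st
}

# Unrestricted contraction S_all(q): r copies of G with index slots identified
# according to partition q (slots 2t-1, 2t belong to copy t). Evaluated by
# vertex elimination over the block multigraph; with all blocks >= 2 and
# r <= 4 the minimum-degree vertex always has <= 2 distinct neighbors, so the
# elimination stays within matrix algebra.
contract_G <- function(G, q) {
  n <- nrow(G)
  d <- max(q)
  r <- length(q) / 2L
  dG <- diag(G)
  L <- replicate(d, rep(1, n), simplify = FALSE)
  # oriented edge storage: M[[(i-1)*d + j]] has rows indexed by vertex i and
  # columns by vertex j (both orientations kept in sync)
  M <- vector("list", d * d)
  edge <- function(i, j) M[[(i - 1L) * d + j]]
  set_edge <- function(i, j, val) {
    # single-bracket assignment so NULL clears without shifting the list
    M[(i - 1L) * d + j] <<- list(val)
    M[(j - 1L) * d + i] <<- list(if (is.null(val)) NULL else t(val))
  }
  for (t in seq_len(r)) {
    i <- q[2L * t - 1L]; j <- q[2L * t]
    if (i == j) {
      L[[i]] <- L[[i]] * dG
    } else {
      old <- edge(i, j)
      set_edge(i, j, if (is.null(old)) G else old * G)
    }
  }
  alive <- rep(TRUE, d)
  total <- 1
  while (any(alive)) {
    vs <- which(alive)
    deg <- vapply(vs, function(v)
      sum(vapply(vs[vs != v], function(u) !is.null(edge(u, v)), logical(1))),
      integer(1))
    v <- vs[which.min(deg)]
    nb <- vs[vs != v][vapply(vs[vs != v], function(u) !is.null(edge(u, v)),
                             logical(1))]
    if (length(nb) == 0) {
      total <- total * sum(L[[v]])
    } else if (length(nb) == 1) {
      u <- nb
      L[[u]] <- L[[u]] * as.vector(edge(u, v) %*% L[[v]])
      set_edge(u, v, NULL)
    } else if (length(nb) == 2) {
      u <- nb[1]; w <- nb[2]
      K <- edge(u, v) %*% (L[[v]] * edge(v, w))
      old <- edge(u, w)
      set_edge(u, w, if (is.null(old)) K else old * K)
      set_edge(u, v, NULL); set_edge(v, w, NULL)
    } else {
      stop("elimination encountered a vertex of degree > 2")
    }
    alive[v] <- FALSE
  }
  total
}

#' Precompute permutation-moment summaries of a Gram matrix
#'
#' For a symmetric doubly centered matrix `G` (typically `R %*% t(R)` of a
#' residual ordination), precomputes the contraction sums needed for the exact
#' permutation moments of `z' G z` up to `max_order`. The result is reused
#' across all variants tested against the same ordination.
#'
#' @param G symmetric, doubly centered numeric matrix.
#' @param max_order highest moment order (3 or 4; 4 enables the kurtosis
#'   adequacy diagnostic of [moment_matched_ftest()]).
#' @return an object of class `mgwas_moment_precomp`.
#' @export
perm_moment_precompute <- function(G, max_order = 4) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), max_order %in% 3:4)
  n <- nrow(G)
  if (max(abs(rowSums(G))) > 1e-6 * max(1, max(abs(G))))
    stop("G must be doubly centered (zero row sums)")
  W <- vector("list", max_order)
  for (r in seq_len(max_order)) {
    st <- moment_structure(r)
    s_all <- vapply(st$good, function(q) contract_G(G, q), numeric(1))
    W[[r]] <- drop(st$C %*% s_all) # aggregated S^= sums per size multiset
  }
  structure(list(n = n, trG = sum(diag(G)), W = W, max_order = max_order),
            class = "mgwas_moment_precomp")
}

#' Exact permutation moments of z' G z
#'
#' Mean, variance, skewness (and excess kurtosis when the precompute carries
#' order 4) of the quadratic form under uniform permutation of the entries of
#' `x` (centered internally).
#'
#' @param precomp result of [perm_moment_precompute()].
#' @param x numeric vector of length `n` (e.g. a SNP dosage).
#' @return list with `mean`, `var`, `skew`, and `kurt` (excess; NA when not
#'   precomputed).
#' @export
perm_moments <- function(precomp, x) {
  n <- precomp$n
  stopifnot(length(x) == n)
  xc <- x - mean(x)
  mo <- precomp$max_order
  s <- vapply(seq_len(2 * mo), function(k) sum(xc^k), numeric(1))
  raw <- numeric(mo)
  for (r in seq_len(mo)) {
    st <- moment_structure(r)
    Wr <- precomp$W[[r]]
    tot <- 0
    for (i in seq_along(Wr)) {
      if (Wr[i] == 0 || st$m_d[i] > n) next # > n blocks: no distinct indices
      dv <- 0
      for (tm in st$dterms[[i]]) dv <- dv + tm$coef * prod(s[tm$exps])
      tot <- tot + Wr[i] * dv / falling_factorial(n, st$m_d[i])
    }
    raw[r] <- tot
  }
  mu <- raw[1]
  v <- raw[2] - mu^2
  m3 <- raw[3] - 3 * mu * raw[2] + 2 * mu^3
  out <- list(mean = mu, var = v,
              skew = if (v > 0) m3 / v^1.5 else NA_real_, kurt = NA_real_)
  if (mo >= 4) {
    m4 <- raw[4] - 4 * mu * raw[3] + 6 * mu^2 * raw[2] - 3 * mu^4
    out$kurt <- if (v > 0) m4 / v^2 - 3 else NA_real_
  }
  out
}

# Upper-tail probability of a Pearson type III variable with given
# standardized skewness, evaluated at standardized quantile z.
pearson3_upper <- function(z, skew) {
  if (!is.finite(skew) || abs(skew) < 1e-8) return(pnorm(z, lower.tail = FALSE))
  k <- 4 / skew^2
  if (skew > 0) {
    pgamma(k + z * sqrt(k), shape = k, lower.tail = FALSE)
  } else {
    pgamma(k - z * sqrt(k), shape = k, lower.tail = TRUE)
  }
}
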