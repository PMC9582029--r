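#' Derive a deterministic child seed from a master seed
#'
#' All stochastic components of the package draw their randomness from a
#' single master seed. Sub-generators (genotypes, covariates, per-sample
#' rarefaction draws, Dunn-Smyth randomization, bootstraps) each receive a
#' child seed derived from the master seed and a textual tag, so that adding
#' or reordering one component never perturbs the stream of another.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. `"genotypes"`,
#'   `"rarefy/sample03"`).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + h * 16807 + 12345) %% (m - 1) + 1)
}

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' package internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

falling_factorial <- function(n, k) {
  if (k == 0) return(1)
  prod(n - seq_len(k) + 1)
}

#' @keywords internal
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
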