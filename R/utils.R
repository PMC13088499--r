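#' @keywords internal
"_PACKAGE"

# Run expr under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All package-level randomness (simulation, splits, training, MC dropout) goes
# through this so that a seed in a config is the only source of nondeterminism.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_mibci <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Nearest-rank percentile: the ceil(p*n)-th order statistic.
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[max(1L, ceiling(p * length(x)))]
}
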