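# Internal helpers: classed conditions and seed derivation.

stop_stridegem <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("stridegem_", class), "error", "condition"),
    list(message = message, call = call)))
}

# Derive a reproducible sub-seed from a base seed and one or two indices.
# Kept strictly below 2^31 - 1 so set.seed() accepts it.
derive_seed <- function(seed, index, attempt = 0L) {
  s <- (as.double(seed) + 7919 * as.double(index) +
          104729 * as.double(attempt)) %% 2147483646
  as.integer(s)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# With seed = NULL the global stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 95% t-based confidence half-width of a mean across replicates.
ci95_halfwidth <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::qt(0.975, df = n - 1) * stats::sd(x) / sqrt(n)
}
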