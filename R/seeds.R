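#' Derive reproducible child seeds from a root seed
#'
#' Every experiment in the package draws all of its randomness (graph
#' generation, node choices, stochastic recovery) from a single root seed.
#' Sub-streams get deterministic child seeds derived with this helper, so a
#' run is reproducible from the root seed alone and the derivation can be
#' recorded in result metadata.
#'
#' @param seed Root seed (a single integer), or `NULL` for no seeding.
#' @param n Number of child seeds to derive.
#' @return An integer vector of `n` seeds in `[1, 2^31 - 2]`, or `NULL` when
#'   `seed` is `NULL`.
#' @examples
#' derive_seeds(42, 3)
#' @export
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  stopifnot(length(seed) == 1, is.finite(seed), n >= 1)
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

# Evaluate `code` under `seed` (restoring the RNG state afterwards); when
# seed is NULL the current RNG stream is used as-is.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Offset a seed while staying inside R's 32-bit integer range.
bump_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + k) %% 2147483645) + 1L
}
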