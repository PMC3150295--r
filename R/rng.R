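#' Derive an independent child seed from a root seed
#'
#' Simulation stages (causal-site selection, environmental noise, penetrance
#' draws, subsampling) each consume their own seed derived from one root seed,
#' so changing the configuration of one stage never perturbs the draws of
#' another. Derivation iterates a Lehmer generator (multiplier 48271, modulus
#' 2^31 - 1), keeping every value within 32-bit integer range.
#'
#' @param seed integer root seed.
#' @param stream positive integer stream index; distinct indices give
#'   distinct, reproducible child seeds.
#' @return an integer seed suitable for [set.seed()].
#' @examples
#' derive_seed(1L, 1)
#' derive_seed(1L, 2)
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 1)
  m <- 2147483647
  x <- abs(as.numeric(seed)) %% m
  for (k in seq_len(as.integer(stream))) {
    # 48271 * x < 2^47, exact in double precision
    x <- (48271 * x + 11) %% m
  }
  as.integer(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never disturb user-level streams.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
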