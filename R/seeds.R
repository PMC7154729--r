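# All randomness in the package flows from one root seed. Sub-streams for
# nested objects (animals within a cohort, replicates within a sweep) are
# derived with a multiplicative-congruential mix so that every (root seed,
# index path) pair maps to a stable 31-bit seed.

#' Derive a child seed from a root seed and an index path
#'
#' Deterministic stream splitting: `derive_seed(s, i, j)` always returns the
#' same 31-bit integer, distinct across index paths with overwhelming
#' probability. Used wherever one user-facing seed must drive several
#' independent generators.
#'
#' @param seed Integer root seed.
#' @param ... Integer indices identifying the sub-stream.
#' @return A positive integer strictly below 2^31.
#' @export
#' @examples
#' derive_seed(1, 3)
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- abs(as.double(seed)) %% 2147483647
  for (k in ks) {
    s <- (s * 48271 + abs(as.double(k)) * 8191 + 11) %% 2147483647
  }
  as.integer(s) + 1L
}
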