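## Deterministic string hashing used by the surrogate binding model and for
## deriving per-component child seeds from one global seed.  All arithmetic is
## carried out in doubles on values < 2^53, so results are exact and identical
## across platforms.  No R RNG state is touched.

MOD32 <- 4294967296 # 2^32

## (a * b) mod 2^32 for a, b < 2^32 without leaving exact double range.
.mulmod32 <- function(a, b) {
  a1 <- floor(a / 65536)
  a0 <- a - a1 * 65536
  (((a1 * b) %% MOD32) * 65536 + a0 * b) %% MOD32
}

## Polynomial rolling hash of one string, followed by two multiplicative
## avalanche rounds (Knuth constants) to decorrelate nearby inputs.
.hash32 <- function(s) {
  codes <- utf8ToInt(s)
  h <- 2166136261
  for (cc in codes) {
    h <- (h * 131 + cc) %% MOD32
  }
  h <- .mulmod32(h + 2654435769, 2246822519)
  h <- (h + floor(h / 65536)) %% MOD32
  .mulmod32(h, 2654435761)
}

#' Deterministic uniform hash of strings to \[0, 1)
#'
#' Maps each input string to a number in \[0, 1) by a pure, seeded string
#' hash.  The same `(x, salt)` pair always yields the same value, on any
#' platform, independent of R's RNG state.
#'
#' @param x Character vector.
#' @param salt Single string mixed into every hash (use it to derive
#'   independent streams from the same inputs).
#' @return Numeric vector in \[0, 1), same length as `x`.
#' @keywords internal
hashUnit <- function(x, salt = "") {
  vapply(paste0(salt, "\x1f", x), .hash32, numeric(1), USE.NAMES = FALSE) / MOD32
}

#' Derive a child seed from a global seed and a component label
#'
#' Fixed derivation so that every pipeline component gets an independent,
#' reproducible RNG stream from one user-facing seed.
#'
#' @param seed Integer global seed.
#' @param label Component label, e.g. `"transcripts"`.
#' @return A single integer in \[0, 2^31).
#' @keywords internal
childSeed <- function(seed, label) {
  as.integer(floor(hashUnit(paste0(label, ":", seed)) * 2147483647))
}
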