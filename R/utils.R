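# Internal helpers shared across modules.

# Hard cap on rule arity: exhaustive 2^k tables stay cheap up to here.
MAX_K <- 16L

#' Enumerate all binary input states of a k-input rule
#'
#' Returns the `2^k x k` matrix of binary input states in the package's
#' fixed row order: state code `i` in `[0, 2^k)` assigns input `j` the
#' j-th *most significant* bit of `i`, so rows run (0,...,0), (0,...,1),
#' ..., (1,...,1). All truth tables, decompositions and file formats in
#' this package use this order.
#'
#' @param k Number of inputs (0 to 16).
#' @return An integer matrix with `2^k` rows and `k` columns.
#' @export
#' @examples
#' state_matrix(2)
state_matrix <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 0L, k <= MAX_K)
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  codes <- 0:(2^k - 1)
  m <- vapply(seq_len(k), function(j) bitwAnd(codes %/% 2^(k - j), 1L),
              integer(2^k))
  matrix(as.integer(m), nrow = 2^k, ncol = k)
}

# Round-half-up; base round() rounds half to even, which would make
# bias -> count-of-ones conversions depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Number of set bits of each nonnegative integer in x (masks < 2^31).
bit_count <- function(x) {
  vapply(x, function(m) sum(as.integer(intToBits(as.integer(m)))), integer(1))
}

# Multi-index <-> integer mask, MSB convention matching state_matrix():
# bit (k - j) of the mask corresponds to input j.
mask_to_alpha <- function(mask, k) {
  as.integer(bitwAnd(mask %/% 2^((k - 1):0), 1L))
}

alpha_to_mask <- function(alpha) {
  k <- length(alpha)
  if (k == 0L) return(0L)
  as.integer(sum(alpha * 2^((k - 1):0)))
}

# Clamp to [0,1]; idempotent on values already inside.
clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
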