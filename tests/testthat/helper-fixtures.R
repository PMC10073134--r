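# Shared fixtures and independent oracles.

tt_and <- function() truth_table(c(0, 0, 0, 1), inputs = c("x1", "x2"))
tt_or  <- function() truth_table(c(0, 1, 1, 1), inputs = c("x1", "x2"))
tt_xor <- function() truth_table(c(0, 1, 1, 0), inputs = c("x1", "x2"))
tt_not <- function() truth_table(c(1, 0), inputs = "x")

# The 3-node illustration network: a <- NOT b, b <- a OR c, c <- a XOR b.
fig_network <- function() {
  boolean_network(
    inputs = list(a = "b", b = c("a", "c"), c = c("a", "b")),
    tables = list(a = tt_not_renamed("b"),
                  b = truth_table(c(0, 1, 1, 1), inputs = c("a", "c")),
                  c = truth_table(c(0, 1, 1, 0), inputs = c("a", "b"))),
    metadata = list(name = "not-or-xor")
  )
}

tt_not_renamed <- function(nm) truth_table(c(1, 0), inputs = nm)

# All 2^(2^k) truth tables on k inputs.
all_truth_tables <- function(k) {
  n_states <- 2^k
  lapply(0:(2^n_states - 1), function(code) {
    out <- as.integer(intToBits(code))[seq_len(n_states)]
    truth_table(out, k = k)
  })
}

# Independent symbolic-expansion oracle for Taylor coefficients: expand
# the R1 sum of Bernoulli monomials directly in the shifted coordinates
# y_j = x_j - p_j. Each 1-state contributes, per multi-index alpha,
# the product of +/-1 over differentiated coordinates (p_j + y_j vs
# (1 - p_j) - y_j) times the product of Bernoulli masses over the rest.
# No finite differences and no basis transform are involved.
oracle_taylor_coeffs <- function(f, p = rep(0.5, f$k)) {
  k <- f$k
  n_states <- 2^k
  S <- state_matrix(k)
  coeffs <- numeric(n_states)
  r1 <- which(f$outputs == 1L)
  for (m in 0:(n_states - 1)) {
    alpha <- mask_to_alpha_test(m, k)
    total <- 0
    for (r in r1) {
      x <- S[r, ]
      contrib <- 1
      for (j in seq_len(k)) {
        contrib <- contrib * if (alpha[j] == 1L) {
          if (x[j] == 1L) 1 else -1
        } else {
          if (x[j] == 1L) p[j] else 1 - p[j]
        }
      }
      total <- total + contrib
    }
    coeffs[m + 1] <- total
  }
  if (k == 0L) coeffs <- as.numeric(f$outputs[1])
  coeffs
}

mask_to_alpha_test <- function(m, k) {
  if (k == 0L) return(integer(0))
  as.integer(bitwAnd(m %/% 2^((k - 1):0), 1L))
}

alpha_to_mask_test <- function(alpha) {
  k <- length(alpha)
  sum(alpha * 2^((k - 1):0))
}

`%or%` <- function(a, b) if (is.null(a)) b else a

# Small random model suite used by several dynamics tests.
random_suite <- function(n_models, seed, n_range = 5:12, kmax = 3) {
  lapply(seq_len(n_models), function(i) {
    set.seed(seed + i)
    n <- sample(n_range, 1)
    generate_random_model(
      n,
      indegree_sampler = function(m) sample(seq_len(kmax), m, replace = TRUE),
      bias_sampler = function(m) runif(m, 0.2, 0.65),
      seed = seed + 1000 + i
    )
  })
}

write_fig_bnet <- function(path) {
  writeLines(c(
    "targets, factors",
    "# 3-node illustration: NOT / OR / XOR",
    "a, !b",
    "b, a | c",
    "c, (a & !b) | (!a & b)"
  ), path)
  path
}
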