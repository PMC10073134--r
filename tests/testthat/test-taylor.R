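test_that("decompositions of the basic gates match the printed polynomials", {
  # AND: 0.25 + 0.5(x1-1/2) + 0.5(x2-1/2) + (x1-1/2)(x2-1/2)
  expect_equal(taylor_decompose(tt_and())$values, c(0.25, 0.5, 0.5, 1))
  # OR: 0.75 + 0.5(x1-1/2) + 0.5(x2-1/2) - (x1-1/2)(x2-1/2)
  expect_equal(taylor_decompose(tt_or())$values, c(0.75, 0.5, 0.5, -1))
  # XOR: 0.5 - 2(x1-1/2)(x2-1/2); monotone gates keep linear terms,
  # XOR does not
  expect_equal(taylor_decompose(tt_xor())$values, c(0.5, 0, 0, -2))
  # NOT: 0.5 - (x-1/2) = 1 - x
  expect_equal(taylor_decompose(tt_not())$values, c(0.5, -1))
})

test_that("finite-difference derivatives match the printed gate derivatives", {
  expect_equal(partial_derivative(tt_xor(), c(1, 1)), -2)
  expect_equal(partial_derivative(tt_xor(), c(1, 0)), 0)
  expect_equal(partial_derivative(tt_xor(), c(0, 1)), 0)
  expect_equal(partial_derivative(tt_and(), c(1, 0)), 0.5)
  expect_equal(partial_derivative(tt_or(), c(0, 1)), 0.5)
  expect_equal(partial_derivative(tt_or(), c(0, 0)), 0.75)
  expect_error(partial_derivative(tt_and(), c(1, 0, 0)), "inputs")
})

test_that("all three coefficient routes agree for every 3-input function", {
  # exhaustive: basis-transform decomposition vs symbolic-expansion
  # oracle vs per-index finite difference, at the unbiased center
  for (f in all_truth_tables(3)) {
    d <- taylor_decompose(f)
    expect_equal(d$values, oracle_taylor_coeffs(f), tolerance = 1e-12)
  }
  set.seed(5)
  f_some <- all_truth_tables(3)[sample(256, 12)]
  for (f in f_some) {
    d <- taylor_decompose(f)
    fd <- vapply(d$masks, function(m)
      partial_derivative(f, mask_to_alpha_test(m, 3)), numeric(1))
    expect_equal(d$values, fd, tolerance = 1e-12)
  }
})

test_that("coefficient routes agree at arbitrary centers (k up to 4)", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    f <- truth_table(sample(0:1, 2^k, replace = TRUE), k = k)
    p <- runif(k)
    d <- taylor_decompose(f, p = p)
    expect_equal(d$values, oracle_taylor_coeffs(f, p), tolerance = 1e-12)
    alpha <- sample(0:1, k, replace = TRUE)
    expect_equal(partial_derivative(f, alpha, p),
                 d$values[d$masks == alpha_to_mask_test(alpha)],
                 tolerance = 1e-12)
  }
})

test_that("truncated evaluation reproduces the printed approximations and is exact at full order", {
  d_or <- taylor_decompose(tt_or())
  expect_equal(eval_truncated(d_or, c(0.9, 0.1), 0), 0.75)
  expect_equal(eval_truncated(d_or, c(1, 0), 2), 1)
  d_xor <- taylor_decompose(tt_xor())
  expect_equal(eval_truncated(d_xor, c(1, 1), 1), 0.5)
  set.seed(3)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    f <- truth_table(sample(0:1, 2^k, replace = TRUE), k = k)
    d <- taylor_decompose(f)
    for (j in 1:50) {
      x <- runif(k)
      expect_equal(eval_truncated(d, x, k), extension_eval(f, x),
                   tolerance = 1e-12)
    }
  }
})

test_that("the bias-dependent derivative bound holds and is attained per order", {
  expect_equal(max_abs_derivative(0.5, 2), 2)
  expect_equal(max_abs_derivative(0.25, 2), 1)
  expect_equal(max_abs_derivative(0, 3), 0)
  expect_equal(max_abs_derivative(1, 1), 0)
  expect_error(max_abs_derivative(0.5, 0), "order")

  for (k in 2:3) {
    attained <- list()
    for (f in all_truth_tables(k)) {
      b <- output_bias(f)
      d <- taylor_decompose(f)
      for (l in seq_len(k)) {
        bound <- max_abs_derivative(b, l)
        mx <- max(abs(d$values[d$orders == l]))
        expect_lte(mx, bound + 1e-12)
        key <- paste(b, l)
        attained[[key]] <- max(attained[[key]] %or% 0, mx)
      }
    }
    # every (representable bias, order) pair with a nonzero bound is hit
    for (key in names(attained)) {
      parts <- as.numeric(strsplit(key, " ")[[1]])
      bound <- max_abs_derivative(parts[1], parts[2])
      expect_equal(attained[[key]], bound, tolerance = 1e-12)
    }
  }
})

test_that("network spectra pool normalized derivative magnitudes per order", {
  sp <- nonlinearity_spectrum(fig_network())
  # hand enumeration: NOT contributes |−1|/1 = 1 at order 1; OR
  # contributes 0.5/0.5 = 1 twice (order 1) and |−1|/1 = 1 (order 2);
  # XOR contributes 0, 0 (order 1) and |−2|/2 = 1 (order 2)
  expect_equal(sp$order, c(1, 2))
  expect_equal(sp$mean, c(mean(c(1, 1, 1, 0, 0)), 1))
  expect_equal(sp$sd, c(sd(c(1, 1, 1, 0, 0)), 0))
  expect_equal(sp$n, c(5L, 2L))

  # constant nodes (bias 0/1): normalized terms are defined as 0
  const_net <- boolean_network(
    inputs = list(u = "u", v = "v"),
    tables = list(u = truth_table(c(0, 0), inputs = "u"),
                  v = truth_table(c(1, 1), inputs = "v")))
  spc <- nonlinearity_spectrum(const_net)
  expect_equal(spc$order, 1)
  expect_equal(spc$mean, 0)
  expect_equal(spc$n, 2L)
})

test_that("sparse storage above 8 inputs keeps nonzero terms and full-order exactness", {
  set.seed(21)
  k <- 9
  f <- truth_table(sample(0:1, 2^k, replace = TRUE), k = k)
  d <- taylor_decompose(f)
  expect_lte(length(d$values), 2^k)
  for (j in 1:5) {
    x <- runif(k)
    expect_equal(eval_truncated(d, x, k), extension_eval(f, x),
                 tolerance = 1e-9)
  }
})
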