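test_that("synchronous exact simulation follows hand-enumerated trajectories", {
  # 2-node toggle: a <- !b, b <- !a; from (0, 1) it cycles with period 2
  toggle <- boolean_network(
    inputs = list(a = "b", b = "a"),
    tables = list(a = truth_table(c(1, 0)), b = truth_table(c(1, 0))))
  tr <- simulate_exact(toggle, c(0, 1), steps = 4, keep_trajectory = TRUE)
  expect_equal(tr[, "a", 1], c(0, 0, 0, 0, 0))
  expect_equal(tr[, "b", 1], c(1, 1, 1, 1, 1))
  tr2 <- simulate_exact(toggle, c(1, 1), steps = 3, keep_trajectory = TRUE)
  expect_equal(tr2[, "a", 1], c(1, 0, 1, 0))
  expect_equal(tr2[, "b", 1], c(1, 0, 1, 0))

  # single-step hand evaluation of the 3-node net
  net <- fig_network()
  X <- simulate_exact(net, c(0, 0, 0), steps = 1)
  expect_equal(unname(X[1, ]), c(1, 0, 0))

  # the 3-node NOT/OR/XOR net from (1,1,1): step-by-step hand evaluation
  tr3 <- simulate_exact(net, c(1, 1, 1), steps = 4, keep_trajectory = TRUE)
  expect_equal(unname(tr3[, , 1]),
               matrix(c(1, 1, 1,
                        0, 1, 0,
                        0, 0, 1,
                        1, 1, 0,
                        0, 1, 0), ncol = 3, byrow = TRUE))
})

test_that("max-order truncated dynamics reproduce exact Boolean dynamics", {
  suite <- random_suite(50, seed = 300, n_range = 5:20, kmax = 4)
  for (net in suite) {
    ord <- max(summary(net)$per_node$k)
    X0 <- random_initial_states(net, 20, seed = 77)
    Xe <- simulate_exact(net, X0, steps = 30)
    Xt <- simulate_truncated(net, ord, X0, steps = 30)
    expect_lt(max(abs(Xe - Xt)), 1e-9)
    expect_lt(mae(net, ord, initial_states = X0, steps = 30), 1e-9)
  }
})

test_that("the XOR node's linear approximation is as poor as the constant one", {
  net <- fig_network()
  d <- lapply(net$tables, taylor_decompose)
  t0 <- simulate_truncated(net, 0, c(1, 1, 1), steps = 20, decomps = d,
                           keep_trajectory = TRUE)
  t1 <- simulate_truncated(net, 1, c(1, 1, 1), steps = 20, decomps = d,
                           keep_trajectory = TRUE)
  t2 <- simulate_truncated(net, 2, c(1, 1, 1), steps = 20, decomps = d,
                           keep_trajectory = TRUE)
  te <- simulate_exact(net, c(1, 1, 1), steps = 20, keep_trajectory = TRUE)
  # node c computes XOR: its first-order derivatives vanish, so its
  # order-1 trajectory equals its order-0 trajectory
  expect_equal(t1[, "c", 1], t0[, "c", 1])
  # order 2 includes every Taylor term of a 2-input network: exact
  expect_equal(t2, te * 1.0, tolerance = 1e-12)

  # order 0 freezes every node at its bias after one step
  expect_true(all(abs(t0[2:21, "a", 1] - 0.5) < 1e-12))
  expect_true(all(abs(t0[2:21, "b", 1] - 0.75) < 1e-12))
  expect_true(all(abs(t0[2:21, "c", 1] - 0.5) < 1e-12))
})

test_that("a linear-truncated XOR node with frozen inputs has squared error 0.25", {
  net <- boolean_network(
    inputs = list(x = c("a", "b"), a = "a", b = "b"),
    tables = list(x = truth_table(c(0, 1, 1, 0), inputs = c("a", "b")),
                  a = truth_table(c(0, 1), inputs = "a"),
                  b = truth_table(c(0, 1), inputs = "b")))
  starts <- state_matrix(3)  # all (x, a, b) binary starts
  Xe <- simulate_exact(net, starts, steps = 10)
  Xt <- simulate_truncated(net, 1, starts, steps = 10)
  expect_equal(unname((Xe[, "x"] - Xt[, "x"])^2), rep(0.25, 8))
  # frozen inputs are linear, hence exact
  expect_equal(Xe[, c("a", "b")], Xt[, c("a", "b")])
  # network MAE averages the per-node errors
  expect_equal(mae(net, 1, initial_states = starts, steps = 10),
               c(order1 = 0.25 / 3))
})

test_that("approximation error decreases with order on ensemble average", {
  suite <- random_suite(50, seed = 700, n_range = 6:12, kmax = 3)
  maes <- t(vapply(suite, function(net)
    mae(net, 1:3, n_init = 40, steps = 30, seed = 1), numeric(3)))
  m <- colMeans(maes)
  expect_gte(m[1] + 1e-9, m[2])
  expect_gte(m[2] + 1e-9, m[3])
  expect_lt(m[3], 1e-9)  # kmax = 3 makes order 3 exact
  expect_true(all(maes >= 0 & maes <= 1))
})

test_that("benchmarks are reproducible and expose the report surface", {
  net <- generate_random_model(8, seed = 50)
  r1 <- benchmark_model(net, orders = 1:2, ensemble_size = 5, n_init = 30,
                        steps = 20, seed = 123)
  r2 <- benchmark_model(net, orders = 1:2, ensemble_size = 5, n_init = 30,
                        steps = 20, seed = 123)
  expect_identical(r1, r2)
  expect_named(r1$table,
               c("order", "MAE_model", "MAE_constrained",
                 "MAE_unconstrained", "PMAE_model", "PMAE_constrained",
                 "approximability"))
  expect_identical(dim(r1$member_mae_constrained), c(5L, 2L))
  expect_equal(r1$linear_approximability,
               r1$table$approximability[r1$table$order == 1])
  expect_true(all(r1$table$MAE_model >= 0 & r1$table$MAE_model <= 1))
  expect_true(all(r1$table$PMAE_model >= -100, na.rm = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(r1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$table$approximability, r1$table$approximability)
})

test_that("clamping is idempotent on in-range continuous states", {
  net <- boolean_network(inputs = list(a = "a"),
                         tables = list(a = truth_table(c(0, 1))))
  # identity rule at order 1 is exact: an in-range continuous state
  # passes through every update (and its clamp) unchanged
  X <- matrix(0.3, 1, 1)
  expect_equal(unname(simulate_truncated(net, 1, X, steps = 5)[1, 1]), 0.3)
})
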