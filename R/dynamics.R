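#' Random binary initial states for a network
#'
#' Draws `n_init` initial states uniformly over binary vectors, without
#' enforcing uniqueness (`n_init` may exceed `2^n` for small networks).
#'
#' @param model A [boolean_network()].
#' @param n_init Number of initial states.
#' @param seed Optional integer seed.
#' @return An integer matrix of dim `n_init x n_nodes`, columns named
#'   by node.
#' @export
random_initial_states <- function(model, n_init, seed = NULL) {
  stopifnot(inherits(model, "boolean_network"), n_init >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(model$nodes)
  X <- matrix(sample(0:1, n_init * n, replace = TRUE), nrow = n_init,
              dimnames = list(NULL, model$nodes))
  X
}

# --- compiled steppers -------------------------------------------------

# Per-node regulator indices, bit weights and output columns for fast
# synchronous exact updates.
compile_exact <- function(model) {
  idx <- stats::setNames(seq_along(model$nodes), model$nodes)
  lapply(model$nodes, function(nm) {
    regs <- idx[model$inputs[[nm]]]
    k <- length(regs)
    list(regs = unname(regs), pow = 2^((k - 1):0),
         outputs = model$tables[[nm]]$outputs)
  })
}

step_exact <- function(comp, X) {
  out <- X
  for (v in seq_along(comp)) {
    cv <- comp[[v]]
    code <- as.vector(X[, cv$regs, drop = FALSE] %*% cv$pow)
    out[, v] <- cv$outputs[code + 1L]
  }
  out
}

# Per-node truncated Taylor terms (masks with |alpha| <= order).
compile_truncated <- function(model, order, decomps = NULL) {
  idx <- stats::setNames(seq_along(model$nodes), model$nodes)
  if (is.null(decomps))
    decomps <- lapply(model$tables, taylor_decompose)
  lapply(model$nodes, function(nm) {
    regs <- unname(idx[model$inputs[[nm]]])
    d <- decomps[[nm]]
    eff <- min(order, d$k)
    sel <- which(d$orders <= eff)
    cols <- lapply(d$masks[sel], function(m) which(mask_to_alpha(m, d$k) == 1L))
    list(regs = regs, center = d$center, values = d$values[sel],
         cols = cols)
  })
}

step_truncated <- function(comp, X) {
  out <- X
  for (v in seq_along(comp)) {
    cv <- comp[[v]]
    Y <- sweep(X[, cv$regs, drop = FALSE], 2L, cv$center, "-")
    val <- 0
    for (i in seq_along(cv$values)) {
      cols <- cv$cols[[i]]
      if (!length(cols)) {
        val <- val + cv$values[i]
      } else {
        term <- Y[, cols[1]]
        for (cc in cols[-1]) term <- term * Y[, cc]
        val <- val + cv$values[i] * term
      }
    }
    out[, v] <- clamp01(val)
  }
  out
}

# ----------------------------------------------------------------------

#' Exact synchronous Boolean simulation
#'
#' All nodes update in parallel: each node's next state is its truth
#' table applied to the current states of its regulators.
#'
#' @param model A [boolean_network()].
#' @param initial_states Binary matrix, one row per run (a single
#'   vector is accepted).
#' @param steps Number of synchronous update steps.
#' @param keep_trajectory If `TRUE`, return the full trajectory array
#'   (`steps + 1` x nodes x runs) including the initial state;
#'   otherwise the matrix of final states (runs x nodes).
#' @return Final-state matrix, or trajectory array.
#' @export
simulate_exact <- function(model, initial_states, steps,
                           keep_trajectory = FALSE) {
  X <- as_state_matrix(model, initial_states)
  comp <- compile_exact(model)
  run_simulation(function(S) step_exact(comp, S), X, steps, keep_trajectory)
}

#' Order-truncated continuous simulation
#'
#' Like [simulate_exact()] but each node updates through the truncation
#' of its Taylor decomposition (centered at 1/2) to
#' `min(order, in-degree)`; after every node update the value is
#' clamped to `[0, 1]` by resetting to the nearest boundary. With
#' `order >=` the maximum in-degree and binary initial states the
#' trajectory coincides with the exact Boolean one.
#'
#' @inheritParams simulate_exact
#' @param order Approximation order (0 = constant bias, 1 = linear, ...).
#' @param decomps Optional precomputed list of per-node
#'   [taylor_decompose()] results (must be centered at 1/2).
#' @return Final-state matrix, or trajectory array.
#' @export
simulate_truncated <- function(model, order, initial_states, steps,
                               decomps = NULL, keep_trajectory = FALSE) {
  X <- as_state_matrix(model, initial_states)
  storage.mode(X) <- "double"
  comp <- compile_truncated(model, order, decomps)
  run_simulation(function(S) step_truncated(comp, S), X, steps,
                 keep_trajectory)
}

as_state_matrix <- function(model, initial_states) {
  n <- length(model$nodes)
  if (is.vector(initial_states))
    initial_states <- matrix(initial_states, nrow = 1L)
  X <- as.matrix(initial_states)
  if (ncol(X) != n)
    stop("initial states must have ", n, " columns")
  colnames(X) <- model$nodes
  X
}

run_simulation <- function(stepper, X, steps, keep_trajectory) {
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  if (keep_trajectory) {
    traj <- array(NA_real_, dim = c(steps + 1L, ncol(X), nrow(X)),
                  dimnames = list(NULL, colnames(X), NULL))
    traj[1L, , ] <- t(X)
    for (s in seq_len(steps)) {
      X <- stepper(X)
      traj[s + 1L, , ] <- t(X)
    }
    traj
  } else {
    for (s in seq_len(steps)) X <- stepper(X)
    X
  }
}

#' Mean approximation error of an order-truncated simulation
#'
#' Runs the exact Boolean dynamics and the order-`order` truncated
#' dynamics from the same binary initial states and returns the mean,
#' over initial states and nodes, of the squared difference between the
#' exact and approximated states at the final step. With
#' `time_average = TRUE` the squared differences are instead averaged
#' over all update steps (a sensitivity variant; the headline statistic
#' compares final states only).
#'
#' @param model A [boolean_network()].
#' @param order Approximation order (or vector of orders).
#' @param n_init,steps Simulation size; defaults 1000 initial states,
#'   500 steps.
#' @param seed Optional seed for the initial states (ignored when
#'   `initial_states` is given).
#' @param initial_states Optional binary matrix of shared initial
#'   states.
#' @param decomps Optional precomputed decompositions.
#' @param time_average Average the error over all steps instead of the
#'   final step only.
#' @return Named numeric vector of MAE values, one per order, in
#'   `[0, 1]`.
#' @export
mae <- function(model, order, n_init = 1000, steps = 500, seed = NULL,
                initial_states = NULL, decomps = NULL,
                time_average = FALSE) {
  stopifnot(inherits(model, "boolean_network"))
  if (is.null(initial_states))
    initial_states <- random_initial_states(model, n_init, seed = seed)
  X0 <- as_state_matrix(model, initial_states)
  if (is.null(decomps))
    decomps <- lapply(model$tables, taylor_decompose)
  comp_e <- compile_exact(model)
  res <- vapply(order, function(ord) {
    comp_t <- compile_truncated(model, ord, decomps)
    Xe <- X0
    Xt <- X0
    storage.mode(Xt) <- "double"
    acc <- 0
    for (s in seq_len(steps)) {
      Xe <- step_exact(comp_e, Xe)
      Xt <- step_truncated(comp_t, Xt)
      if (time_average) acc <- acc + mean((Xe - Xt)^2)
    }
    if (time_average) acc / steps else mean((Xe - Xt)^2)
  }, numeric(1))
  stats::setNames(res, paste0("order", order))
}

#' Benchmark a model's approximability against random ensembles
#'
#' For each requested order, computes the model's MAE and the
#' ensemble-average MAE of a constrained (wiring- and bias-preserving,
#' rule-shuffled) and an unconstrained (degree/bias bootstrap-resampled)
#' ensemble, all simulated from the same initial states. From these it
#' derives
#' \itemize{
#'   \item `PMAE_model = 100 * (MAE_model - MAE_unconstrained) /
#'     MAE_unconstrained`, the percentage change in MAE relative to the
#'     unconstrained baseline (similarly `PMAE_constrained`);
#'   \item `approximability = PMAE_constrained - PMAE_model`, positive
#'     when the model is more approximable at that order than its
#'     rule-shuffled nulls. Its value at order 1 is the model's linear
#'     approximability.
#' }
#' When the unconstrained MAE is 0 at an order the PMAEs are undefined
#' and reported as `NA` with a warning.
#'
#' @param model A [boolean_network()].
#' @param orders Orders to evaluate; default 1 up to the maximum
#'   in-degree.
#' @param ensemble_size Members per ensemble (default 100).
#' @param n_init,steps Simulation size; defaults 1000 and 500.
#' @param seed Integer seed controlling the initial states and both
#'   ensembles.
#' @param time_average Passed to [mae()].
#' @return An object of class `approximation_report`: a list with
#'   `table` (one row per order with MAE/PMAE/approximability columns),
#'   `linear_approximability`, the per-member ensemble MAE matrices
#'   `member_mae_constrained` / `member_mae_unconstrained`
#'   (member x order), and `config`.
#' @export
benchmark_model <- function(model, orders = NULL, ensemble_size = 100,
                            n_init = 1000, steps = 500, seed = NULL,
                            time_average = FALSE) {
  stopifnot(inherits(model, "boolean_network"))
  if (is.null(orders)) orders <- seq_len(max_indegree(model))
  orders <- as.integer(orders)
  stopifnot(all(orders >= 0L))
  X0 <- random_initial_states(model, n_init, seed = seed)
  seed_c <- if (!is.null(seed)) seed + 1000003L
  seed_u <- if (!is.null(seed)) seed + 2000003L
  ens_c <- constrained_ensemble(model, size = ensemble_size, seed = seed_c)
  ens_u <- unconstrained_ensemble(model, size = ensemble_size, seed = seed_u)

  mae_model <- mae(model, orders, initial_states = X0, steps = steps,
                   time_average = time_average)
  member_mae <- function(ens) {
    t(vapply(ens, function(m)
      mae(m, orders, initial_states = X0, steps = steps,
          time_average = time_average),
      numeric(length(orders))))
  }
  mm_c <- member_mae(ens_c)
  mm_u <- member_mae(ens_u)
  if (length(orders) == 1L) {
    mm_c <- matrix(mm_c, ncol = 1L)
    mm_u <- matrix(mm_u, ncol = 1L)
  }
  mae_c <- colMeans(mm_c)
  mae_u <- colMeans(mm_u)

  pmae <- function(x) {
    out <- 100 * (x - mae_u) / mae_u
    bad <- mae_u == 0
    if (any(bad)) {
      warning("unconstrained MAE is 0 at order(s) ",
              paste(orders[bad], collapse = ", "),
              "; PMAE undefined there")
      out[bad] <- NA_real_
    }
    out
  }
  pmae_model <- pmae(mae_model)
  pmae_c <- pmae(mae_c)
  tab <- data.frame(order = orders,
                    MAE_model = unname(mae_model),
                    MAE_constrained = unname(mae_c),
                    MAE_unconstrained = unname(mae_u),
                    PMAE_model = unname(pmae_model),
                    PMAE_constrained = unname(pmae_c),
                    approximability = unname(pmae_c - pmae_model))
  lin <- if (1L %in% orders) tab$approximability[tab$order == 1L] else NA_real_
  structure(list(table = tab,
                 linear_approximability = lin,
                 member_mae_constrained = mm_c,
                 member_mae_unconstrained = mm_u,
                 config = list(orders = orders,
                               ensemble_size = ensemble_size,
                               n_init = n_init, steps = steps,
                               seed = seed,
                               time_average = time_average)),
            class = "approximation_report")
}

#' @export
print.approximation_report <- function(x, ...) {
  cat("Approximability benchmark (", x$config$ensemble_size,
      " members, ", x$config$n_init, " initial states, ",
      x$config$steps, " steps)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.na(x$linear_approximability))
    cat(sprintf("linear approximability: %.4g%%\n",
                x$linear_approximability))
  invisible(x)
}

#' Write an approximation report as TSV or JSON
#'
#' @param report An [benchmark_model()] result.
#' @param path Output path; format chosen by extension (`.json` for
#'   JSON, TSV otherwise).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "approximation_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(table = report$table,
                              linear_approximability =
                                report$linear_approximability,
                              config = report$config),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
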