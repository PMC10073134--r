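#' Constrained null ensemble: rule-shuffled, wiring- and bias-preserving
#'
#' Generates randomized copies of a model in which the wiring (each
#' node's ordered regulators) is kept exactly and each node's truth
#' table output column is replaced by a uniformly random permutation of
#' itself. The number of 1-states, hence the output bias, is preserved
#' node-by-node; only the logic is randomized. Nodes with bias 0 or 1
#' admit a single permutation class and are unchanged in every member.
#'
#' Each member's RNG stream is seeded as `seed + member index`, so
#' individual members are independently reproducible.
#'
#' @param model A [boolean_network()].
#' @param size Ensemble size (default 100).
#' @param seed Optional integer base seed.
#' @return A list of `size` [boolean_network()]s.
#' @export
constrained_ensemble <- function(model, size = 100, seed = NULL) {
  stopifnot(inherits(model, "boolean_network"), size >= 1)
  lapply(seq_len(size), function(i) {
    if (!is.null(seed)) set.seed(seed + i)
    tables <- lapply(model$tables, function(tt)
      truth_table(sample(tt$outputs), inputs = tt$inputs, k = tt$k))
    boolean_network(model$inputs, tables,
                    metadata = list(name = paste0(model$metadata$name %||%
                                                    "model",
                                                  "_constrained_", i),
                                    source = "constrained ensemble"))
  })
}

#' Unconstrained null ensemble: bootstrap-resampled degrees and biases
#'
#' Generates randomized models of the same node count whose per-node
#' (in-degree, bias) pairs are bootstrap-sampled with replacement from
#' the source model's per-node pairs; the wiring is re-drawn uniformly
#' (distinct regulators, self-loops permitted) and each truth table is
#' random with exactly `round(bias * 2^k)` ones. By default the
#' (in-degree, bias) pairs are resampled jointly, preserving their
#' empirical coupling; `joint = FALSE` resamples the two marginals
#' independently.
#'
#' @inheritParams constrained_ensemble
#' @param joint Resample (k, bias) pairs jointly (default) or the
#'   marginals independently.
#' @return A list of `size` [boolean_network()]s.
#' @export
unconstrained_ensemble <- function(model, size = 100, seed = NULL,
                                   joint = TRUE) {
  stopifnot(inherits(model, "boolean_network"), size >= 1)
  s <- summary(model)
  ks <- s$per_node$k
  biases <- s$per_node$bias
  n <- length(ks)
  nodes <- model$nodes
  lapply(seq_len(size), function(i) {
    if (!is.null(seed)) set.seed(seed + i)
    if (joint) {
      idx <- sample.int(n, n, replace = TRUE)
      kk <- ks[idx]
      bb <- biases[idx]
    } else {
      kk <- ks[sample.int(n, n, replace = TRUE)]
      bb <- biases[sample.int(n, n, replace = TRUE)]
    }
    kk <- pmin(kk, n)  # cannot exceed the number of distinct regulators
    inputs <- list()
    tables <- list()
    for (v in seq_len(n)) {
      regs <- sample(nodes, kk[v])
      inputs[[nodes[v]]] <- regs
      tables[[nodes[v]]] <- random_table(kk[v], bb[v], inputs = regs)
    }
    boolean_network(inputs, tables,
                    metadata = list(name = paste0(model$metadata$name %||%
                                                    "model",
                                                  "_unconstrained_", i),
                                    source = "unconstrained ensemble"))
  })
}

#' Ensemble manifest
#'
#' One row of summary statistics per ensemble member, suitable for
#' writing as TSV.
#'
#' @param ensemble A list of [boolean_network()]s.
#' @return A data frame with member id and summary columns.
#' @export
ensemble_manifest <- function(ensemble) {
  rows <- lapply(seq_along(ensemble), function(i) {
    s <- summary(ensemble[[i]])
    data.frame(member = i, n_nodes = s$n_nodes,
               mean_indegree = s$mean_indegree, sd_indegree = s$sd_indegree,
               mean_bias = s$mean_bias, sd_bias = s$sd_bias)
  })
  do.call(rbind, rows)
}
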