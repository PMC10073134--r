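#' Default in-degree sampler for random networks
#'
#' Draws in-degrees uniformly from `{1, 2, 3, 4}` (mean 2.5), squarely
#' inside the range of mean in-degrees (about 1.18 to 4.94) reported
#' across published Boolean models of biochemical regulation.
#'
#' @param n Number of draws.
#' @return Integer vector of in-degrees.
#' @export
sample_indegree_default <- function(n) sample(1:4, n, replace = TRUE)

#' Default output-bias sampler for random networks
#'
#' Draws biases uniformly on `[0.1625, 0.65625]`, the range of mean
#' output biases observed across published Boolean models.
#'
#' @param n Number of draws.
#' @return Numeric vector of biases.
#' @export
sample_bias_default <- function(n) stats::runif(n, 0.1625, 0.65625)

#' Generate a random Boolean network
#'
#' Each node draws an in-degree `k` and a target output bias `b`, gets
#' `k` distinct regulators chosen uniformly among all nodes (self-loops
#' permitted), and a truth table with exactly `round(b * 2^k)` ones
#' (half rounded up) placed uniformly at random. Fully reproducible
#' from `seed`.
#'
#' @param n_nodes Number of nodes.
#' @param indegree_sampler Function of `n` returning `n` in-degrees
#'   (each >= 1); default [sample_indegree_default()].
#' @param bias_sampler Function of `n` returning `n` biases in `[0, 1]`;
#'   default [sample_bias_default()].
#' @param seed Optional integer seed.
#' @param name Model name recorded in metadata.
#' @return A [boolean_network()].
#' @export
#' @examples
#' net <- generate_random_model(10, seed = 1)
#' summary(net)
generate_random_model <- function(n_nodes,
                                  indegree_sampler = sample_indegree_default,
                                  bias_sampler = sample_bias_default,
                                  seed = NULL,
                                  name = "random") {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  ks <- as.integer(indegree_sampler(n_nodes))
  biases <- as.numeric(bias_sampler(n_nodes))
  if (any(ks < 1L)) stop("in-degree sampler produced k < 1")
  if (any(ks > min(n_nodes, MAX_K)))
    stop("in-degree sampler produced k above min(n_nodes, ", MAX_K, ")")
  if (any(biases < 0 | biases > 1)) stop("bias sampler left [0, 1]")
  inputs <- list()
  tables <- list()
  for (v in seq_len(n_nodes)) {
    regs <- sample(nodes, ks[v])
    inputs[[nodes[v]]] <- regs
    tables[[nodes[v]]] <- random_table(ks[v], biases[v], inputs = regs)
  }
  boolean_network(inputs, tables,
                  metadata = list(name = name, source = "generated"))
}

# Truth table with exactly round_half_up(bias * 2^k) ones, placed
# uniformly; uses the current RNG stream.
random_table <- function(k, bias, inputs = NULL) {
  n_states <- 2^k
  n_ones <- round_half_up(bias * n_states)
  out <- integer(n_states)
  if (n_ones > 0L) out[sample.int(n_states, n_ones)] <- 1L
  truth_table(out, inputs = inputs, k = k)
}
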