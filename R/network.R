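#' Boolean network model container
#'
#' A named collection of nodes, each with an ordered list of regulators
#' and a [truth_table()] over them. Regulator order is semantic: it
#' fixes the bit order of the node's truth table. Constant and source
#' nodes are encoded with the node itself as sole input (a constant
#' output column for constants, the identity column for self-copying
#' sources), so every node has a decomposable table with in-degree
#' >= 1.
#'
#' @param inputs Named list: for each node, the character vector of its
#'   regulators, in truth-table bit order.
#' @param tables Named list of [truth_table()]s, one per node, with
#'   `k` equal to the number of regulators.
#' @param metadata Optional list; recognized entries include `name`,
#'   `source`, `category_C1`, `category_C2`, `notes`.
#' @return An object of class `boolean_network` with fields `nodes`
#'   (ordered names), `inputs`, `tables`, `metadata`.
#' @export
#' @examples
#' net <- boolean_network(
#'   inputs = list(a = "b", b = c("a", "c"), c = c("a", "b")),
#'   tables = list(a = truth_table(c(1, 0)),
#'                 b = truth_table(c(0, 1, 1, 1)),
#'                 c = truth_table(c(0, 1, 1, 0)))
#' )
boolean_network <- function(inputs, tables, metadata = list()) {
  nodes <- names(inputs)
  if (is.null(nodes) || any(!nzchar(nodes)) || anyDuplicated(nodes))
    stop("inputs must be a named list with unique node names")
  if (!setequal(names(tables), nodes))
    stop("tables must be named exactly like inputs")
  tables <- tables[nodes]
  for (nm in nodes) {
    regs <- inputs[[nm]]
    if (length(regs) < 1L)
      stop("node '", nm, "' has no regulators; encode constants as ",
           "self-inputs")
    missing_regs <- setdiff(regs, nodes)
    if (length(missing_regs))
      stop("node '", nm, "' has undeclared regulator(s): ",
           paste(missing_regs, collapse = ", "))
    tt <- tables[[nm]]
    if (!inherits(tt, "truth_table"))
      stop("tables[['", nm, "']] is not a truth_table")
    if (tt$k != length(regs))
      stop("node '", nm, "': table has ", tt$k, " inputs but ",
           length(regs), " regulators are declared")
  }
  structure(list(nodes = nodes, inputs = inputs, tables = tables,
                 metadata = metadata),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  nm <- x$metadata$name
  cat("Boolean network", if (!is.null(nm)) paste0("'", nm, "'") else "",
      "with", length(x$nodes), "nodes\n")
  s <- summary(x)
  cat(sprintf("  mean in-degree %.3g +/- %.3g, mean output bias %.3g +/- %.3g\n",
              s$mean_indegree, s$sd_indegree, s$mean_bias, s$sd_bias))
  invisible(x)
}

#' Summary statistics of a Boolean network model
#'
#' @param object A [boolean_network()].
#' @param ... Unused.
#' @return An object of class `model_summary`: node count, mean/sd
#'   in-degree, mean/sd output bias, and the per-node `(k, bias)` table.
#' @export
summary.boolean_network <- function(object, ...) {
  ks <- vapply(object$tables, function(t) t$k, integer(1))
  biases <- vapply(object$tables, output_bias, numeric(1))
  structure(list(
    n_nodes = length(object$nodes),
    mean_indegree = mean(ks),
    sd_indegree = if (length(ks) > 1L) stats::sd(ks) else 0,
    mean_bias = mean(biases),
    sd_bias = if (length(biases) > 1L) stats::sd(biases) else 0,
    per_node = data.frame(node = object$nodes, k = unname(ks),
                          bias = unname(biases), stringsAsFactors = FALSE)
  ), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("%d nodes; in-degree %.4g +/- %.4g; output bias %.4g +/- %.4g\n",
              x$n_nodes, x$mean_indegree, x$sd_indegree,
              x$mean_bias, x$sd_bias))
  invisible(x)
}

#' Write a model summary as TSV
#'
#' @param model A [boolean_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(model, path) {
  s <- summary(model)
  utils::write.table(s$per_node, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Maximum in-degree of a model; the highest meaningful approximation
# order.
max_indegree <- function(model) {
  max(vapply(model$tables, function(t) t$k, integer(1)))
}
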