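#' Read a Boolean network from a BoolNet-style `.bnet` file
#'
#' The dialect: an optional `targets, factors` header; one
#' `target, expression` line per node; `#` starts a comment; rules use
#' identifiers, `&`, `|`, `!`, parentheses and the constants `0`/`1`.
#' A node's regulator order is the order of first appearance of each
#' identifier in its rule and fixes the truth-table bit order. A
#' constant rule (`0` or `1`, no identifiers) is encoded under the
#' package convention as the node regulating itself with a constant
#' output column.
#'
#' @param path Path to the rule file.
#' @param name Model name stored in metadata; defaults to the file name.
#' @return A [boolean_network()].
#' @seealso [write_bnet()]
#' @export
read_bnet <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(lines)))
  targets <- character(0)
  exprs <- character(0)
  line_nos <- integer(0)
  for (i in keep) {
    ln <- trimws(lines[i])
    if (grepl("^targets\\s*,\\s*factors$", ln, ignore.case = TRUE)) next
    pos <- regexpr(",", ln, fixed = TRUE)
    if (pos == -1L)
      stop("line ", i, ": expected 'target, factors', got '", ln, "'")
    tgt <- trimws(substr(ln, 1L, pos - 1L))
    expr <- trimws(substr(ln, pos + 1L, nchar(ln)))
    if (!nzchar(tgt) || !nzchar(expr))
      stop("line ", i, ": empty target or factor expression")
    if (tgt %in% targets)
      stop("line ", i, ": duplicate target '", tgt, "'")
    targets <- c(targets, tgt)
    exprs <- c(exprs, expr)
    line_nos <- c(line_nos, i)
  }
  if (!length(targets)) stop("no rules found in ", path)
  inputs <- list()
  tables <- list()
  for (j in seq_along(targets)) {
    ids <- rule_identifiers(exprs[j])
    undeclared <- setdiff(ids, targets)
    if (length(undeclared))
      stop("line ", line_nos[j], ": undeclared regulator(s): ",
           paste(undeclared, collapse = ", "))
    if (length(ids) == 0L) {
      # constant rule: self-input with constant column
      val <- tryCatch(as.integer(trimws(exprs[j])), warning = function(w) NA)
      if (is.na(val) || !val %in% c(0L, 1L))
        stop("line ", line_nos[j], ": cannot parse constant rule '",
             exprs[j], "'")
      inputs[[targets[j]]] <- targets[j]
      tables[[targets[j]]] <- truth_table(c(val, val), inputs = targets[j])
    } else {
      tt <- tryCatch(truth_table_from_expression(exprs[j], ids),
                     error = function(e)
                       stop("line ", line_nos[j], ": ", conditionMessage(e)))
      inputs[[targets[j]]] <- ids
      tables[[targets[j]]] <- tt
    }
  }
  boolean_network(inputs, tables,
                  metadata = list(name = name %||% basename(path),
                                  source = path))
}

#' Write a Boolean network to a `.bnet` file
#'
#' Each rule is emitted in disjunctive normal form over the states
#' mapped to 1, so the written file is round-trip safe: reading it back
#' reproduces every truth table (and regulator order) bit-exactly. A
#' rule with no 1-states is written as `0 & <regulators>` to preserve
#' the declared wiring.
#'
#' @param model A [boolean_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bnet <- function(model, path) {
  stopifnot(inherits(model, "boolean_network"))
  lines <- c("targets, factors")
  for (nm in model$nodes) {
    lines <- c(lines, paste0(nm, ", ", rule_to_dnf(model$tables[[nm]],
                                                   model$inputs[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

# DNF over R1, with literal order = regulator order so that
# read_bnet() recovers the same ordered inputs.
rule_to_dnf <- function(tt, regs) {
  r1 <- which(tt$outputs == 1L)
  if (!length(r1))
    return(paste(c("0", regs), collapse = " & "))
  S <- state_matrix(tt$k)[r1, , drop = FALSE]
  terms <- apply(S, 1L, function(row) {
    lits <- ifelse(row == 1L, regs, paste0("!", regs))
    paste(lits, collapse = " & ")
  })
  if (length(terms) == 1L) terms else
    paste(paste0("(", terms, ")"), collapse = " | ")
}
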