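#' Truth table of a Boolean function
#'
#' Stores a k-input Boolean function as the explicit vector of its
#' `2^k` outputs, in the fixed row order of [state_matrix()] (first
#' listed input = most significant bit of the state code).
#'
#' @param outputs Vector of `2^k` values in `{0, 1}`.
#' @param inputs Optional character vector of `k` ordered input names.
#' @param k Number of inputs; inferred from `length(outputs)` when missing.
#' @return An object of class `truth_table` with fields `k`, `outputs`
#'   and `inputs`.
#' @seealso [truth_table_from_expression()], [extension_eval()],
#'   [output_bias()]
#' @export
#' @examples
#' AND <- truth_table(c(0, 0, 0, 1), inputs = c("x1", "x2"))
#' output_bias(AND) # 0.25
truth_table <- function(outputs, inputs = NULL, k = NULL) {
  outputs <- as.integer(outputs)
  if (anyNA(outputs) || !all(outputs %in% c(0L, 1L)))
    stop("truth table outputs must be 0/1")
  if (is.null(k)) {
    k <- as.integer(round(log2(length(outputs))))
  }
  k <- as.integer(k)
  if (k < 0L || k > MAX_K)
    stop("number of inputs must be between 0 and ", MAX_K)
  if (length(outputs) != 2^k)
    stop("expected ", 2^k, " outputs for ", k, " inputs, got ",
         length(outputs))
  if (!is.null(inputs)) {
    inputs <- as.character(inputs)
    if (length(inputs) != k) stop("length(inputs) must equal k")
  }
  structure(list(k = k, outputs = outputs, inputs = inputs),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Boolean truth table:", x$k, "input(s), bias",
      format(output_bias(x)), "\n")
  if (x$k > 0L && x$k <= 6L) {
    tab <- cbind(state_matrix(x$k), out = x$outputs)
    colnames(tab) <- c(x$inputs %||% paste0("x", seq_len(x$k)), "f")
    print(tab)
  }
  invisible(x)
}

# Tokens legal in a rule expression; identifiers are R-style names.
.RULE_TOKEN <- "(?:[A-Za-z_.][A-Za-z0-9_.]*|[01]|[&|!()]|\\s+)"

#' Build a truth table from a Boolean rule expression
#'
#' Parses a rule written in the common `.bnet` dialect -- identifiers,
#' `&` (AND), `|` (OR), `!` (NOT), parentheses and the constants `0`/`1`
#' -- and enumerates its outputs over all `2^k` input states. XOR has no
#' operator in this dialect and must be written expanded, e.g.
#' `(a & !b) | (!a & b)`.
#'
#' @param expr Rule text.
#' @param input_names Ordered input names; every identifier in `expr`
#'   must appear here. When missing, inputs are taken in order of first
#'   appearance in `expr`.
#' @return A [truth_table()] whose input order is `input_names`.
#' @export
#' @examples
#' truth_table_from_expression("x1 & x2", c("x1", "x2"))$outputs # 0 0 0 1
#' truth_table_from_expression("!x", "x")$outputs                # 1 0
truth_table_from_expression <- function(expr, input_names = NULL) {
  expr <- trimws(expr)
  if (!nzchar(expr)) stop("empty rule expression")
  leftover <- gsub(.RULE_TOKEN, "", expr, perl = TRUE)
  if (nzchar(leftover))
    stop("illegal character(s) in rule expression: '", leftover, "'")
  ids <- rule_identifiers(expr)
  if (is.null(input_names)) input_names <- ids
  unknown <- setdiff(ids, input_names)
  if (length(unknown))
    stop("unknown identifier(s) in rule: ", paste(unknown, collapse = ", "))
  k <- length(input_names)
  if (k > MAX_K)
    stop("rule has ", k, " inputs; the supported maximum is ", MAX_K)
  parsed <- tryCatch(str2lang(expr),
                     error = function(e) stop("malformed rule expression: ",
                                              conditionMessage(e)))
  S <- state_matrix(k)
  env <- new.env(parent = baseenv())
  for (j in seq_len(k)) assign(input_names[j], S[, j] == 1L, envir = env)
  val <- eval(parsed, env)
  out <- as.integer(rep_len(as.logical(val), 2^k))
  truth_table(out, inputs = if (k > 0L) input_names, k = k)
}

# Identifiers in order of first appearance (constants 0/1 excluded).
rule_identifiers <- function(expr) {
  m <- gregexpr("[A-Za-z_.][A-Za-z0-9_.]*", expr, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  unique(regmatches(expr, list(m))[[1]])
}

#' Multilinear extension of a Boolean function
#'
#' Evaluates the probabilistic (pseudo-Boolean) generalization of `f`:
#' with each input i an independent Bernoulli variable with success
#' probability `p[i]`, the extension is the probability that the output
#' is 1, i.e. the sum over the 1-states of the product of per-input
#' probabilities. It is the unique square-free polynomial agreeing with
#' `f` on every binary corner.
#'
#' @param f A [truth_table()].
#' @param p Numeric vector of `f$k` probabilities in `[0, 1]`.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' OR <- truth_table(c(0, 1, 1, 1))
#' extension_eval(OR, c(0.5, 0.5)) # 0.75
extension_eval <- function(f, p) {
  stopifnot(inherits(f, "truth_table"))
  p <- as.numeric(p)
  if (length(p) != f$k)
    stop("p has length ", length(p), " but the table has ", f$k, " inputs")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  r1 <- which(f$outputs == 1L)
  if (!length(r1)) return(0)
  if (f$k == 0L) return(1)
  S <- state_matrix(f$k)[r1, , drop = FALSE]
  P <- matrix(p, nrow = nrow(S), ncol = f$k, byrow = TRUE)
  W <- S * P + (1 - S) * (1 - P)
  sum(apply(W, 1L, prod))
}

#' Output bias of a Boolean function
#'
#' The fraction of input states mapped to 1, `|R1| / 2^k`; equals the
#' multilinear extension evaluated at the unbiased point (1/2, ..., 1/2).
#'
#' @param f A [truth_table()].
#' @return A value in `[0, 1]`.
#' @export
output_bias <- function(f) {
  stopifnot(inherits(f, "truth_table"))
  sum(f$outputs) / length(f$outputs)
}

#' Read or write a truth table as JSON
#'
#' The JSON layout is `{"name": ..., "inputs": [...], "outputs": [...]}`
#' with outputs in the documented row order.
#'
#' @param path File path.
#' @return `read_truth_table_json()` returns a [truth_table()];
#'   `write_truth_table_json()` returns `path` invisibly.
#' @export
read_truth_table_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$outputs)) stop("truth-table JSON lacks 'outputs'")
  inputs <- obj$inputs
  if (!is.null(inputs) && length(inputs) == 0L) inputs <- NULL
  tt <- truth_table(obj$outputs, inputs = inputs)
  attr(tt, "name") <- obj$name
  tt
}

#' @rdname read_truth_table_json
#' @param f A [truth_table()].
#' @param name Optional function name stored in the JSON.
#' @export
write_truth_table_json <- function(f, path, name = NULL) {
  stopifnot(inherits(f, "truth_table"))
  obj <- list(name = name %||% attr(f, "name") %||% "f",
              inputs = f$inputs %||% character(0),
              outputs = f$outputs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
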