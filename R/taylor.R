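#' Mixed partial derivative of a multilinear extension
#'
#' Because the extension is multilinear, the mixed derivative with
#' respect to the inputs flagged in `alpha` is constant along those
#' coordinates and reduces to a finite difference: the alternating sum
#' of `f` over the corners of the differentiated coordinates, averaged
#' over the remaining coordinates with Bernoulli weights taken from `p`.
#' At the unbiased center `p = (1/2, ..., 1/2)` the weights are equal
#' and the average has denominator `2^(k - |alpha|)`. `alpha = 0`
#' returns the extension value itself.
#'
#' @param f A [truth_table()].
#' @param alpha Binary vector of length `f$k`; 1 marks a differentiated
#'   input (square-free polynomial, so no repeated derivatives exist).
#' @param p Center, a vector of `f$k` probabilities; defaults to 1/2.
#' @return The derivative value.
#' @export
#' @examples
#' XOR <- truth_table(c(0, 1, 1, 0))
#' partial_derivative(XOR, c(1, 1)) # -2
#' partial_derivative(XOR, c(1, 0)) # 0
partial_derivative <- function(f, alpha, p = rep(0.5, f$k)) {
  stopifnot(inherits(f, "truth_table"))
  alpha <- as.integer(alpha)
  if (length(alpha) != f$k)
    stop("alpha has length ", length(alpha), " but the table has ",
         f$k, " inputs")
  if (!all(alpha %in% c(0L, 1L))) stop("alpha components must be 0/1")
  p <- as.numeric(p)
  if (length(p) != f$k) stop("p must have length ", f$k)
  if (f$k == 0L) return(as.numeric(f$outputs[1]))
  S <- state_matrix(f$k)
  # sign: product over differentiated coords of (2 x_j - 1)
  # weight: product over free coords of the Bernoulli mass of x_j
  sgn <- rep(1, nrow(S))
  wt <- rep(1, nrow(S))
  for (j in seq_len(f$k)) {
    if (alpha[j] == 1L) {
      sgn <- sgn * (2 * S[, j] - 1)
    } else {
      wt <- wt * (S[, j] * p[j] + (1 - S[, j]) * (1 - p[j]))
    }
  }
  sum(sgn * wt * f$outputs)
}

#' Taylor decomposition of a Boolean function's multilinear extension
#'
#' Expands the extension about the center `p` over all square-free
#' multi-indices: `f^(x) = sum_alpha  d^alpha f^(p) * (x - p)^alpha`
#' (alpha! = 1 for square-free alpha). The order-0 coefficient is the
#' extension value at `p` -- the output bias when `p = 1/2`. The
#' expansion is finite and exact at full order. Coefficients are
#' computed in one `O(k 2^k)` pass by rewriting the corner values in
#' the shifted basis one input at a time.
#'
#' Coefficients are stored densely (all `2^k` multi-indices) for
#' `k <= 8` and sparsely (magnitude above 1e-12 only) for larger rules.
#'
#' @param f A [truth_table()].
#' @param p Center; defaults to the unbiased point (1/2, ..., 1/2).
#' @return An object of class `taylor_decomposition` with fields
#'   `k`, `center`, `masks` (integer codes of the multi-indices, MSB
#'   convention), `values` (the derivatives), `orders` (`|alpha|` per
#'   entry) and `input_names`.
#' @export
#' @examples
#' OR <- truth_table(c(0, 1, 1, 1))
#' d <- taylor_decompose(OR)
#' d$values # 0.75 0.5 0.5 -1
taylor_decompose <- function(f, p = rep(0.5, f$k)) {
  stopifnot(inherits(f, "truth_table"))
  p <- as.numeric(p)
  if (length(p) != f$k) stop("p must have length ", f$k)
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  k <- f$k
  v <- as.numeric(f$outputs)
  if (k > 0L) {
    codes <- 0:(2^k - 1)
    for (j in seq_len(k)) {
      bit <- 2^(k - j)
      i0 <- codes[bitwAnd(codes, bit) == 0L] + 1L
      i1 <- i0 + bit
      a0 <- v[i0]
      a1 <- v[i1]
      v[i0] <- a0 + p[j] * (a1 - a0)  # value at x_j = p_j
      v[i1] <- a1 - a0                # coefficient of (x_j - p_j)
    }
  }
  masks <- 0:(2^k - 1)
  orders <- bit_count(masks)
  if (k > 8L) {
    keep <- abs(v) > 1e-12 | masks == 0L
    masks <- masks[keep]
    v <- v[keep]
    orders <- orders[keep]
  }
  structure(list(k = k, center = p, masks = as.integer(masks), values = v,
                 orders = as.integer(orders), input_names = f$inputs),
            class = "taylor_decomposition")
}

#' @export
print.taylor_decomposition <- function(x, ...) {
  cat("Taylor decomposition: k =", x$k, ", center =",
      paste(format(x$center), collapse = ", "), "\n")
  df <- as.data.frame(x)
  print(df[abs(df$value) > 1e-12 | df$order == 0L, ], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.taylor_decomposition <- function(x, ...) {
  alpha <- vapply(x$masks,
                  function(m) paste(mask_to_alpha(m, x$k), collapse = ""),
                  character(1))
  if (x$k == 0L) alpha <- ""
  data.frame(alpha = alpha, order = x$orders, value = x$values,
             stringsAsFactors = FALSE)
}

#' Evaluate a truncated Taylor expansion
#'
#' Sums the terms of the decomposition with `|alpha| <= max_order` at
#' the point `x`. Order 0 is the constant bias term, order 1 the linear
#' approximation, and `max_order >= k` reproduces the extension
#' exactly. The value is *not* clamped to `[0, 1]`; range restriction
#' is the simulator's job.
#'
#' @param d A [taylor_decompose()] result.
#' @param x Numeric vector of `d$k` input values.
#' @param max_order Truncation order (>= 0).
#' @return The (unclamped) approximation value.
#' @export
eval_truncated <- function(d, x, max_order) {
  stopifnot(inherits(d, "taylor_decomposition"))
  x <- as.numeric(x)
  if (length(x) != d$k) stop("x must have length ", d$k)
  max_order <- as.integer(max_order)
  if (max_order < 0L) stop("max_order must be >= 0")
  eval_truncated_matrix(d, matrix(x, nrow = 1L), max_order)[1]
}

# Vectorized truncated evaluation over rows of X (n x k). Used by the
# simulator; one pass over the retained masks, row products of shifted
# coordinates.
eval_truncated_matrix <- function(d, X, max_order) {
  sel <- which(d$orders <= max_order)
  Y <- sweep(X, 2L, d$center, "-")
  out <- rep(0, nrow(X))
  for (i in sel) {
    m <- d$masks[i]
    if (m == 0L) {
      out <- out + d$values[i]
    } else {
      cols <- which(mask_to_alpha(m, d$k) == 1L)
      term <- Y[, cols[1]]
      for (cc in cols[-1]) term <- term * Y[, cc]
      out <- out + d$values[i] * term
    }
  }
  out
}

#' Largest possible magnitude of a Taylor derivative at given bias
#'
#' For a Boolean function with output bias `bias`, the absolute value
#' of any order-`|alpha|` derivative of its extension at the unbiased
#' center is at most `(min(bias, 1/2) - max(bias - 1/2, 0)) * 2^|alpha|`.
#' The bound is attained order-by-order (e.g. XOR attains it at order
#' 2), but not necessarily by one function across several orders
#' simultaneously. Functions with bias 0 or 1 are constant and the
#' bound is 0. Used to normalize nonlinearity spectra so that rules
#' with different biases are comparable.
#'
#' @param bias Output bias in `[0, 1]` (vectorized).
#' @param order Derivative order, an integer >= 1.
#' @return The bound (same length as `bias`).
#' @export
#' @examples
#' max_abs_derivative(0.5, 2)  # 2
#' max_abs_derivative(0.25, 2) # 1
max_abs_derivative <- function(bias, order) {
  if (anyNA(bias) || any(bias < 0 | bias > 1)) stop("bias must lie in [0, 1]")
  order <- as.integer(order)
  if (length(order) != 1L || order < 1L)
    stop("order must be a single integer >= 1")
  (pmin(bias, 0.5) - pmax(bias - 0.5, 0)) * 2^order
}

#' Per-order nonlinearity spectrum of a Boolean network
#'
#' Decomposes every node's rule at the unbiased center and pools, for
#' each order `l`, the absolute derivative values of all order-`l`
#' terms of all nodes with in-degree >= `l`, each normalized by
#' [max_abs_derivative()] at that node's output bias. All terms of the
#' order are pooled -- including exact zeros -- and the mean, standard
#' deviation and count are reported per order. Nodes with bias 0 or 1
#' have provably zero derivatives; their normalized terms are defined
#' as 0 (the normalizer vanishes there too). Orders beyond the maximum
#' in-degree are absent from the result, not zero.
#'
#' @param model A [boolean_network()].
#' @return A data frame of class `nonlinearity_spectrum` with columns
#'   `order`, `mean`, `sd`, `n`.
#' @export
nonlinearity_spectrum <- function(model) {
  stopifnot(inherits(model, "boolean_network"))
  ks <- vapply(model$tables, function(t) t$k, integer(1))
  if (!length(ks) || max(ks) == 0L) {
    res <- data.frame(order = integer(0), mean = numeric(0),
                      sd = numeric(0), n = integer(0))
    class(res) <- c("nonlinearity_spectrum", "data.frame")
    return(res)
  }
  per_order <- vector("list", max(ks))
  for (nm in model$nodes) {
    tt <- model$tables[[nm]]
    if (tt$k == 0L) next
    bias <- output_bias(tt)
    d <- taylor_decompose(tt)
    for (l in seq_len(tt$k)) {
      vals <- abs(d$values[d$orders == l])
      # sparse storage drops zero terms; restore the full term count
      n_terms <- choose(tt$k, l)
      if (length(vals) < n_terms)
        vals <- c(vals, rep(0, n_terms - length(vals)))
      norm <- max_abs_derivative(bias, l)
      vals <- if (norm > 0) vals / norm else rep(0, length(vals))
      per_order[[l]] <- c(per_order[[l]], vals)
    }
  }
  keep <- which(lengths(per_order) > 0L)
  res <- data.frame(
    order = keep,
    mean = vapply(per_order[keep], mean, numeric(1)),
    sd = vapply(per_order[keep],
                function(v) if (length(v) > 1L) stats::sd(v) else NA_real_,
                numeric(1)),
    n = lengths(per_order[keep])
  )
  class(res) <- c("nonlinearity_spectrum", "data.frame")
  res
}

#' Export a network's Taylor decompositions as a table
#'
#' One row per (node, multi-index) pair, with the multi-index written
#' as a bitstring over that node's ordered inputs.
#'
#' @param model A [boolean_network()].
#' @param p Center for the decompositions; defaults to 1/2.
#' @return A data frame with columns `node`, `alpha`, `order`, `value`.
#' @export
decompose_network <- function(model, p = 0.5) {
  stopifnot(inherits(model, "boolean_network"))
  rows <- lapply(model$nodes, function(nm) {
    tt <- model$tables[[nm]]
    d <- taylor_decompose(tt, p = rep(p, tt$k))
    df <- as.data.frame(d)
    cbind(node = nm, df, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
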