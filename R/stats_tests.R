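#' Welch's unequal-variances t-test between two groups
#'
#' Two-sided two-sample t-test without the equal-variance assumption
#' (Satterthwaite degrees of freedom), as used to compare approximation
#' errors between model sets.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @param labels Length-2 character vector of group labels.
#' @return An object of class `group_comparison`: test name, statistic,
#'   degrees of freedom, p-value, tails, group labels and sizes.
#' @export
welch_t_test <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (a[1] == b[1]) {
      # identical constant samples: no evidence of any difference
      return(group_comparison("Welch two-sample t-test", 0, NA_real_, 1,
                              labels, c(length(a), length(b)),
                              note = "both groups constant"))
    }
    stop("both groups have zero variance; the Welch statistic is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  group_comparison("Welch two-sample t-test",
                   unname(ht$statistic), unname(ht$parameter),
                   ht$p.value, labels, c(length(a), length(b)))
}

#' F-test of equality of variances between two groups
#'
#' Two-sided F-test with `F = var(a) / var(b)` on
#' `(length(a) - 1, length(b) - 1)` degrees of freedom, as used to
#' compare the spread of linear approximability between model
#' categories.
#'
#' @inheritParams welch_t_test
#' @return A `group_comparison` object.
#' @export
f_variance_test <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(b) == 0)
    stop("denominator group has zero variance; F is undefined")
  ht <- stats::var.test(a, b, alternative = "two.sided")
  group_comparison("F test of equal variances",
                   unname(ht$statistic), unname(ht$parameter),
                   ht$p.value, labels, c(length(a), length(b)))
}

group_comparison <- function(test, statistic, df, p.value, labels, sizes,
                             note = NULL) {
  structure(list(test = test, statistic = statistic, df = df,
                 p.value = p.value, tails = "two-sided",
                 groups = labels, sizes = sizes, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, ": ", x$groups[1], " (n=", x$sizes[1], ") vs ",
      x$groups[2], " (n=", x$sizes[2], ")\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p.value, x$tails))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Category-level comparison of approximability scores
#'
#' Groups per-model scores (typically linear approximability) by
#' category, orders the categories by increasing variance, and runs
#' pairwise two-sided F-tests of equal variances between all category
#' pairs. Categories with fewer than two models cannot enter a variance
#' test and are excluded with a warning. Raw p-values are reported;
#' `bonferroni = TRUE` additionally adjusts them for the number of
#' pairs.
#'
#' @param scores Named numeric vector: one score per model.
#' @param labels Named character vector: category of each model (names
#'   must match `scores`).
#' @param bonferroni Add a Bonferroni-adjusted p-value column.
#' @return A list of class `category_report` with `categories` (n,
#'   mean, variance per category, in increasing order of variance) and
#'   `pairwise` (all pairwise F-tests).
#' @export
category_report <- function(scores, labels, bonferroni = FALSE) {
  if (is.null(names(scores)) || is.null(names(labels)))
    stop("scores and labels must be named by model")
  common <- intersect(names(scores), names(labels))
  if (!length(common)) stop("no models shared between scores and labels")
  scores <- scores[common]
  labels <- labels[common]
  groups <- split(unname(scores), unname(labels))
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small)) {
    warning("excluding singleton categor", if (length(small) > 1) "ies"
            else "y", ": ", paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2L]
  }
  if (length(groups) < 1L) stop("no category with >= 2 models")
  cat_df <- data.frame(
    category = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, numeric(1)),
    variance = vapply(groups, stats::var, numeric(1)),
    row.names = NULL
  )
  cat_df <- cat_df[order(cat_df$variance), ]
  pairs <- if (length(groups) >= 2L)
    utils::combn(cat_df$category, 2L, simplify = FALSE) else list()
  pw <- lapply(pairs, function(pr) {
    gc <- f_variance_test(groups[[pr[1]]], groups[[pr[2]]], labels = pr)
    data.frame(group1 = pr[1], group2 = pr[2],
               F = gc$statistic, p.value = gc$p.value)
  })
  pw <- if (length(pw)) do.call(rbind, pw) else
    data.frame(group1 = character(0), group2 = character(0),
               F = numeric(0), p.value = numeric(0))
  if (bonferroni && nrow(pw))
    pw$p.adjusted <- pmin(pw$p.value * nrow(pw), 1)
  structure(list(categories = cat_df, pairwise = pw),
            class = "category_report")
}

#' @export
print.category_report <- function(x, ...) {
  cat("Categories (increasing variance):\n")
  print(x$categories, row.names = FALSE, digits = 4)
  if (nrow(x$pairwise)) {
    cat("Pairwise F-tests of equal variances:\n")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Read category labels from a sidecar TSV
#'
#' Expects columns `model`, `C1`, `C2` (tab-separated, with header):
#' one row per model, giving its pathway-type (C1) and organism-type
#' (C2) category.
#'
#' @param path TSV path.
#' @return A data frame with columns `model`, `C1`, `C2`.
#' @export
read_category_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("model", "C1", "C2")
  if (!all(need %in% names(df)))
    stop("label file must have columns: ", paste(need, collapse = ", "))
  df[, need]
}
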