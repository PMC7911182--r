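#' Cohort summary table
#'
#' Arithmetic mean and standard deviation (divisor N-1) for continuous
#' columns and counts with percentages for binary/ordinal columns, in the
#' style of a baseline characteristics table.
#'
#' @param table Cohort data frame.
#' @param binary_cols Columns summarised as count (%) of the value 1.
#' @return Data frame: `variable`, `n` (non-missing), `mean`, `sd`, `count`,
#'   `pct` (count columns leave mean/sd `NA` and vice versa).
#' @export
summary_table <- function(table,
                          binary_cols = c("sex", "physact", "single_parent",
                                          "disease")) {
  if (nrow(table) == 0L) stop("empty table")
  num_cols <- names(table)[vapply(table, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("id", binary_cols))
  rows <- lapply(num_cols, function(v) {
    x <- table[[v]]
    data.frame(variable = v, n = sum(!is.na(x)),
               mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE),
               count = NA_integer_, pct = NA_real_)
  })
  brows <- lapply(intersect(binary_cols, names(table)), function(v) {
    x <- table[[v]]
    data.frame(variable = v, n = sum(!is.na(x)), mean = NA_real_, sd = NA_real_,
               count = sum(x == 1, na.rm = TRUE),
               pct = 100 * mean(x == 1, na.rm = TRUE))
  })
  out <- do.call(rbind, c(brows, rows))
  rownames(out) <- NULL
  out
}

#' Assign quintile categories
#'
#' Cuts a vector at its empirical 20/40/60/80th percentiles. A value exactly
#' at a cut point goes to the lower category, so category sizes can differ by
#' the sizes of tie groups.
#'
#' @param values Numeric vector, length >= 5, not all equal.
#' @return Integer vector of categories 1..5.
#' @export
quintile_assign <- function(values) {
  if (length(values) < 5L) stop("need at least five values for quintiles")
  if (anyNA(values)) stop("missing values not allowed")
  cuts <- stats::quantile(values, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  if (max(values) == min(values)) stop("quintiles undefined for a constant vector")
  1L + rowSums(outer(values, cuts, ">"))
}

#' Centered log-ratio bar heights by outcome quintile
#'
#' For each quintile category of an outcome, the log-ratio of the within-
#' category geometric mean of each fatty-acid part to its overall geometric
#' mean, then centered per part across the five categories (so each part's
#' five bars sum to zero). A positive bar marks a category whose mean
#' composition is relatively rich in that part.
#'
#' @param table Cohort data frame containing the closed parts and the outcome.
#' @param outcome Outcome column name used for the quintile split.
#' @param parts Part column names (default the four closed fatty-acid shares).
#' @return 5 x D matrix of centered log-ratio heights (rows Q1..Q5).
#' @export
quintile_clr_bars <- function(table, outcome,
                              parts = c("sfa", "mufa", "n6", "n3")) {
  if (!outcome %in% names(table)) stop(sprintf("no column '%s'", outcome))
  X <- as_comp_matrix(table[, parts, drop = FALSE])
  q <- quintile_assign(table[[outcome]])
  if (length(unique(q)) < 5L) stop("one or more empty quintile categories")
  overall <- colMeans(log(X))
  lr <- t(vapply(1:5, function(k) colMeans(log(X[q == k, , drop = FALSE])) - overall,
                 numeric(length(parts))))
  lr <- sweep(lr, 2, colMeans(lr))
  dimnames(lr) <- list(paste0("Q", 1:5), parts)
  lr
}

#' Amalgamate two parts of a four-part composition
#'
#' Sums a designated pair of parts, reducing a D-part composition to D-1
#' parts, then closes the result. Amalgamation commutes with closure, so the
#' input may be on any positive scale.
#'
#' @param X Matrix/data frame (or named vector) of positive parts.
#' @param pair Character vector of two part names to sum.
#' @param label Name for the amalgamated part (default the two names joined
#'   by "+").
#' @param kappa Closure constant of the result.
#' @return Closed composition(s) with D-1 parts.
#' @export
amalgamate <- function(X, pair, label = paste(pair, collapse = "+"), kappa = 100) {
  if (length(pair) != 2L) stop("'pair' must name exactly two parts")
  vec <- !(is.matrix(X) || is.data.frame(X))
  if (vec) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  X <- as_comp_matrix(X)
  if (!all(pair %in% colnames(X))) stop("pair parts not found")
  keep <- setdiff(colnames(X), pair)
  out <- cbind(X[, keep, drop = FALSE], rowSums(X[, pair, drop = FALSE]))
  colnames(out) <- c(keep, label)
  out <- close_rows(out, kappa)
  if (vec) out[1, ] else out
}

#' Ternary plot coordinates
#'
#' Maps three-part closed compositions `(a, b, c)` to planar barycentric
#' coordinates: `x = (2b + c) / (2 (a+b+c))`, `y = sqrt(3)/2 * c / (a+b+c)`.
#' Part `a` maps to the corner (0, 0), `b` to (1, 0) and `c` to the apex
#' (1/2, sqrt(3)/2). Four-part data must first be reduced with
#' [amalgamate()].
#'
#' @param X Three-part composition: named/unnamed vector of length 3, or a
#'   matrix/data frame with 3 columns.
#' @return Matrix with columns `x`, `y`.
#' @export
ternary_coords <- function(X) {
  vec <- !(is.matrix(X) || is.data.frame(X))
  if (vec) X <- matrix(X, 1, dimnames = list(NULL, names(X)))
  X <- as_comp_matrix(X)
  if (ncol(X) != 3L)
    stop("ternary coordinates need exactly 3 parts; amalgamate a pair first")
  s <- rowSums(X)
  out <- cbind(x = 0.5 * (2 * X[, 2] + X[, 3]) / s,
               y = sqrt(3) / 2 * X[, 3] / s)
  rownames(out) <- rownames(X)
  out
}
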