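#' Close a positive vector to a constant sum
#'
#' Rescales a strictly positive vector so that its parts sum to the closure
#' constant `kappa`. Compositions carry only relative information; closure
#' fixes the representation without changing the ratios between parts.
#'
#' @param x Numeric vector of strictly positive part values. Names, if
#'   present, are kept as part labels.
#' @param kappa Closure constant (default 100, i.e. percentages).
#' @return Numeric vector proportional to `x`, summing to `kappa`.
#' @examples
#' close_comp(c(SFA = 9.6, MUFA = 10.3, n6 = 5.3, n3 = 1.1))
#' @export
close_comp <- function(x, kappa = 100) {
  check_positive_parts(x)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("'kappa' must be a single positive number")
  x * kappa / sum(x)
}

#' Close the rows of a compositional sample
#'
#' @param X Numeric matrix or data frame, one row per subject, all entries
#'   strictly positive.
#' @param kappa Closure constant.
#' @return Matrix with each row summing to `kappa`.
#' @export
close_rows <- function(X, kappa = 100) {
  X <- as_comp_matrix(X)
  X * (kappa / rowSums(X))
}

#' Centered log-ratio transform
#'
#' `clr(x)_i = ln(x_i / g(x))` where `g` is the geometric mean of the parts.
#' The result sums to zero and is invariant under rescaling of `x`, so it does
#' not matter whether parts are stored as raw intakes, %E, or closed shares.
#'
#' @param x Positive numeric vector (one composition) or matrix (one row per
#'   subject).
#' @return Vector or matrix of the same shape; rows sum to 0.
#' @export
clr <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    X <- as_comp_matrix(x)
    L <- log(X)
    return(L - rowMeans(L))
  }
  check_positive_parts(x)
  log(x) - mean(log(x))
}

#' Inverse centered log-ratio transform
#'
#' @param z clr vector or matrix.
#' @param kappa Closure constant of the result.
#' @return Composition(s) closed to `kappa`.
#' @export
clr_inv <- function(z, kappa = 100) {
  if (is.matrix(z)) close_rows(exp(z), kappa) else close_comp(exp(z), kappa)
}

#' Pivot (sequential binary partition) ilr basis
#'
#' Builds the orthonormal contrast matrix for pivot coordinates with a chosen
#' part placed first. The first coordinate is
#' `sqrt((D-1)/D) * ln(x_first / g(remaining))`, so its regression coefficient
#' reads as the effect of the first part relative to the geometric mean of all
#' the others; the remaining coordinates apply the same construction
#' recursively to the remaining parts. Refitting a model with each part
#' rotated into first position ("rotation") spans the identical coordinate
#' space, so fitted values and R-squared do not change -- only the
#' interpretable first coordinate does.
#'
#' @param labels Character vector of part names, in their reference order.
#' @param first Label of the part to place first (default: first label).
#' @return Object of class `pivot_basis`: a list with `labels` (reference
#'   order), `order` (rotation order, `first` moved to the front), and `V`,
#'   the D x (D-1) contrast matrix with rows in rotation order. Columns of
#'   `V` are orthonormal and sum to zero.
#' @export
pivot_basis <- function(labels, first = labels[1]) {
  labels <- as.character(labels)
  D <- length(labels)
  if (D < 2L) stop("need at least two parts")
  if (anyDuplicated(labels)) stop("part labels must be unique")
  if (!first %in% labels)
    stop(sprintf("unknown part label '%s'", first))
  ord <- c(first, labels[labels != first])
  V <- matrix(0, D, D - 1L, dimnames = list(ord, paste0("z", seq_len(D - 1L))))
  for (j in seq_len(D - 1L)) {
    r <- D - j                       # parts remaining after position j
    s <- sqrt(r / (r + 1))
    V[j, j] <- s
    V[(j + 1L):D, j] <- -s / r
  }
  structure(list(labels = labels, order = ord, V = V), class = "pivot_basis")
}

#' @export
print.pivot_basis <- function(x, ...) {
  cat("Pivot ilr basis (", length(x$order), " parts), order: ",
      paste(x$order, collapse = " > "), "\n", sep = "")
  print(round(x$V, 4))
  invisible(x)
}

#' Isometric log-ratio (pivot) coordinates
#'
#' @param x Positive composition vector with names matching the basis labels,
#'   or a matrix with such column names (one row per subject).
#' @param basis A [pivot_basis()].
#' @return Numeric vector of length D-1, or an N x (D-1) matrix.
#' @export
ilr <- function(x, basis) {
  stopifnot(inherits(basis, "pivot_basis"))
  if (is.matrix(x) || is.data.frame(x)) {
    X <- as_comp_matrix(x)
    if (is.null(colnames(X))) colnames(X) <- basis$labels
    if (!all(basis$order %in% colnames(X))) stop("column names do not match basis parts")
    # columns of V sum to zero, so log() works in place of clr()
    return(log(X[, basis$order, drop = FALSE]) %*% basis$V)
  }
  check_positive_parts(x)
  if (is.null(names(x))) names(x) <- basis$labels
  if (!all(basis$order %in% names(x))) stop("part names do not match basis parts")
  drop(log(x[basis$order]) %*% basis$V)
}

#' Inverse ilr transform
#'
#' @param z Coordinate vector of length D-1 (or N x (D-1) matrix).
#' @param basis A [pivot_basis()].
#' @param kappa Closure constant of the reconstructed composition.
#' @return Composition(s) closed to `kappa`, parts in the basis reference
#'   order.
#' @export
ilr_inv <- function(z, basis, kappa = 100) {
  stopifnot(inherits(basis, "pivot_basis"))
  D <- length(basis$order)
  if (is.matrix(z)) {
    if (ncol(z) != D - 1L) stop("coordinate dimension mismatch")
    X <- close_rows(exp(z %*% t(basis$V)), kappa)
    colnames(X) <- basis$order
    return(X[, basis$labels, drop = FALSE])
  }
  if (length(z) != D - 1L) stop("coordinate dimension mismatch")
  x <- close_comp(drop(exp(basis$V %*% z)), kappa)
  names(x) <- basis$order
  x[basis$labels]
}

#' Variation matrix of a compositional sample
#'
#' Entry (i, j) is the sample variance (divisor N-1) of `ln(x_i / x_j)`
#' across subjects: the standard compositional dispersion summary. Small
#' entries indicate tightly coupled parts. Closure-invariant.
#'
#' @param X N x D matrix or data frame of strictly positive parts, N >= 2.
#' @return Symmetric D x D matrix with zero diagonal.
#' @export
variation_matrix <- function(X) {
  X <- as_comp_matrix(X)
  if (nrow(X) < 2L) stop("need at least two subjects for dispersion")
  L <- clr(X)
  S <- stats::var(L)                 # clr covariance, divisor N-1
  d <- diag(S)
  T <- outer(d, d, "+") - 2 * S
  T[T < 0] <- 0                      # guard tiny negative round-off
  diag(T) <- 0
  dimnames(T) <- list(colnames(X), colnames(X))
  T
}

#' Compositional geometric mean
#'
#' Per-part geometric mean across subjects of the closed percentages. The
#' result is reported as-is, not re-closed: the per-part geometric means of
#' a real sample do not generally sum back to the closure constant, and the
#' conventional presentation keeps them on the closed-percentage scale.
#'
#' @param X N x D matrix or data frame of positive parts.
#' @param kappa Closure constant applied to each row before averaging.
#' @return Named vector of per-part geometric means (same units as `kappa`).
#' @export
comp_geometric_mean <- function(X, kappa = 100) {
  X <- as_comp_matrix(X)
  rs <- rowSums(X)
  if (any(abs(rs - kappa) > 1e-6 * kappa)) {
    warning("rows not closed to kappa; closing before computing geometric means")
    X <- X * (kappa / rs)
  }
  exp(colMeans(log(X)))
}

#' Reallocate a fixed amount between two parts
#'
#' Moves `delta` percentage points of the closed composition from one part to
#' another, leaving all other parts untouched. This is the perturbation used
#' to express model effects as "swap delta points of part A for part B around
#' the mean composition".
#'
#' @param x Closed composition (named numeric vector).
#' @param from,to Part labels.
#' @param delta Amount to move, in the units of `x` (percentage points for a
#'   composition closed to 100). Must be strictly less than `x[from]`.
#' @return Composition with the same sum.
#' @export
reallocate <- function(x, from, to, delta) {
  check_positive_parts(x)
  if (is.null(names(x))) stop("composition must have part names")
  if (!from %in% names(x)) stop(sprintf("unknown part '%s'", from))
  if (!to %in% names(x)) stop(sprintf("unknown part '%s'", to))
  if (delta < 0) stop("'delta' must be non-negative")
  if (delta >= x[[from]])
    stop(sprintf("cannot move %g from part '%s' (only %g available); result would not be positive",
                 delta, from, x[[from]]))
  x[from] <- x[[from]] - delta
  x[to] <- x[[to]] + delta
  x
}

#' clr coefficients from rotated first-pivot coefficients
#'
#' In a compositional regression fitted once per rotation, the first-pivot
#' coefficient for part j equals `sqrt(D/(D-1))` times the clr-space
#' coefficient of that part. This helper inverts the relation,
#' `a_j = sqrt((D-1)/D) * beta_j`, to assemble the full clr coefficient
#' vector from the D reported first-pivot coefficients. For coefficients
#' taken from a single fitted model the clr vector sums to zero exactly; a
#' nonzero residual signals rounded or mutually inconsistent inputs, and is
#' returned so the caller can judge.
#'
#' @param beta Numeric vector of D first-pivot coefficients, one per
#'   rotation, in part order.
#' @return List with `a` (clr coefficients, same names as `beta`) and
#'   `residual` (`sum(a)`, zero for internally consistent inputs).
#' @export
clr_from_first_pivot <- function(beta) {
  D <- length(beta)
  if (D < 2L) stop("need at least two parts")
  a <- sqrt((D - 1) / D) * beta
  list(a = a, residual = sum(a))
}

# -- internal validators ------------------------------------------------------

check_positive_parts <- function(x) {
  if (length(x) == 0L) stop("empty composition")
  if (!is.numeric(x)) stop("composition must be numeric")
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    lab <- if (!is.null(names(x))) names(x)[bad] else paste0("part ", which(bad))
    stop(sprintf("non-positive or non-finite part(s): %s", paste(lab, collapse = ", ")))
  }
  invisible(x)
}

as_comp_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("compositional sample must be numeric")
  if (ncol(X) < 2L) stop("need at least two parts")
  bad <- !is.finite(X) | X <= 0
  if (any(bad)) {
    j <- unique(col(X)[bad])
    lab <- if (!is.null(colnames(X))) colnames(X)[j] else paste0("column ", j)
    stop(sprintf("non-positive or non-finite entries in part(s): %s", paste(lab, collapse = ", ")))
  }
  X
}
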