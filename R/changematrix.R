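#' Reallocation change matrix
#'
#' Model-predicted outcome change when `delta` percentage points of the
#' composition are moved from one part (column) to another (row), around a
#' reference composition -- typically the compositional mean. For each
#' ordered pair, the perturbed composition is `reallocate(xbar, from, to,
#' delta)` and the predicted change is `a . (clr(x') - clr(xbar))` with `a`
#' the clr coefficient vector of the outcome model; for outcomes modelled on
#' the natural-log scale the change is exponentiated into a multiplicative
#' ratio. `delta` is an absolute amount of the closed composition
#' (percentage points), not a relative change.
#'
#' Pairs for which the donor part cannot give up `delta` (i.e.
#' `delta >= xbar[from]`) are returned as `NA` and listed in the
#' `"undefined"` attribute rather than silently clamped. Donor parts left
#' with less than a quarter of their reference share are listed in the
#' `"extrapolation"` attribute: predictions there stretch the model far from
#' the data (moving 4 points out of a 4.2-point omega-3 share is the
#' motivating example).
#'
#' @param a clr coefficient vector, named by part.
#' @param xbar Reference composition (named vector, parts matching `a`);
#'   defaults to the published compositional geometric means.
#' @param delta Amount reallocated, percentage points (default 4).
#' @param kind "difference" for raw-scale outcomes, "ratio" for log-scale.
#' @return Object of class `change_matrix`: a D x D matrix, rows the
#'   receiving part, columns the donor; diagonal 0 (differences) or 1
#'   (ratios).
#' @export
change_matrix <- function(a, xbar = reference_estimates()$geometric_mean,
                          delta = 4, kind = c("difference", "ratio")) {
  kind <- match.arg(kind)
  check_positive_parts(xbar)
  if (is.null(names(xbar)) || is.null(names(a)))
    stop("'a' and 'xbar' must be named by part")
  if (!setequal(names(a), names(xbar))) stop("part names of 'a' and 'xbar' differ")
  parts <- names(xbar)
  a <- a[parts]
  D <- length(parts)
  M <- matrix(if (kind == "ratio") 1 else 0, D, D,
              dimnames = list(to = parts, from = parts))
  base_clr <- clr(xbar)
  undef <- character(0)
  for (from in parts) {
    if (delta >= xbar[[from]]) {
      M[parts != from, from] <- NA_real_
      undef <- c(undef, from)
      next
    }
    for (to in setdiff(parts, from)) {
      xp <- reallocate(xbar, from, to, delta)
      d_eta <- sum(a * (clr(xp) - base_clr))
      M[to, from] <- if (kind == "ratio") exp(d_eta) else d_eta
    }
  }
  extreme <- parts[delta < xbar & (xbar - delta) / xbar < 0.25]
  structure(M, class = c("change_matrix", "matrix"),
            kind = kind, delta = delta, xbar = xbar,
            undefined = undef, extrapolation = extreme)
}

#' @export
print.change_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Change matrix (%s scale), delta = %g points moved column -> row\n",
              attr(x, "kind"), attr(x, "delta")))
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  print(round(m, digits))
  if (length(attr(x, "undefined")))
    cat("undefined donor part(s):", paste(attr(x, "undefined"), collapse = ", "), "\n")
  if (length(attr(x, "extrapolation")))
    cat("extreme extrapolation when donating from:",
        paste(attr(x, "extrapolation"), collapse = ", "), "\n")
  invisible(x)
}

#' Change matrix from a fitted compositional model
#'
#' @param fit A [fit_compositional()] result; the matrix is on the ratio
#'   scale when the outcome was modelled on the log scale.
#' @param xbar Reference composition (default the published geometric means).
#' @param delta Amount reallocated, percentage points.
#' @return A [change_matrix()].
#' @export
change_matrix_from_fit <- function(fit,
                                   xbar = reference_estimates()$geometric_mean,
                                   delta = 4) {
  stopifnot(inherits(fit, "coda_fit"))
  change_matrix(fit$clr_coef, xbar = xbar[fit$parts], delta = delta,
                kind = if (fit$log_outcome) "ratio" else "difference")
}
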