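#' Confounder sets for the outcome models
#'
#' Set "A" (anthropometric outcomes): age, sex, energy (kcal), carbohydrate
#' (%E), sodium (mg/1000 kcal), physical activity, sleep duration, screen
#' time, single parent, number of siblings. Set "B" (blood markers and blood
#' pressure) adds zBMI. Ordinal covariates (screen time, siblings) enter as
#' single numeric scores.
#'
#' @param id "A" or "B".
#' @return Character vector of column names.
#' @export
confounder_set <- function(id = c("A", "B")) {
  id <- match.arg(id)
  a <- c("age", "sex", "energy_kcal", "carb_e", "sodium_mg", "physact",
         "sleep_h", "screen", "single_parent", "siblings")
  if (id == "A") a else c(a, "zbmi")
}

outcome_defaults <- function(outcome) {
  ref <- reference_estimates()$outcomes
  i <- match(outcome, ref$name)
  if (is.na(i)) return(list(log = FALSE, set = "A", known = FALSE))
  list(log = ref$log[i], set = ref$confounder_set[i], known = TRUE)
}

#' Compositional linear regression with pivot rotation
#'
#' Ordinary least squares of a (possibly natural-log-transformed) outcome on
#' the D-1 pivot ilr coordinates of a composition plus confounders, refitted
#' once with each part rotated into first position. The four (or D) rotations
#' span the same coordinate space, so fitted values, R-squared and the
#' overall F-test are identical across rotations; only the first coordinate
#' -- the chosen part against the geometric mean of the rest -- changes
#' interpretation. The reported per-rotation estimate is that first-pivot
#' coefficient; the full clr coefficient vector is reconstructed from any
#' single rotation as `a = V b` and sums to zero by construction.
#'
#' The unadjusted R-squared and F-test p-value come from the companion model
#' with intercept and the D-1 coordinates only (no confounders), describing
#' the share of outcome variance attributable to the composition.
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column name. Known outcomes default their log flag
#'   and confounder set from [reference_estimates()].
#' @param parts Composition columns (default the closed fatty-acid shares).
#' @param log_outcome Model `log(outcome)`? Default: the outcome's standard
#'   choice (LDL-C, HDL-C, AST, ALT, GGT on the log scale).
#' @param confounders Character vector of confounder columns; default the
#'   outcome's standard set ([confounder_set()]); `character(0)` fits the
#'   composition-only model.
#' @param rotation_order Part order defining the rotation sequence (default
#'   `parts`).
#' @return Object of class `coda_fit`: `rotations` (data frame with `first`,
#'   `estimate`, `se`, `p` for the first pivot coordinate per rotation),
#'   `clr_coef`, `r_squared` and `f_p` (unadjusted), `n`, `sigma` (residual
#'   SD of the adjusted model), `coord_coef` and `basis` (first rotation, for
#'   prediction), and diagnostics on cross-rotation agreement.
#' @export
fit_compositional <- function(table, outcome, parts = c("sfa", "mufa", "n6", "n3"),
                              log_outcome = NULL, confounders = NULL,
                              rotation_order = parts) {
  od <- outcome_defaults(outcome)
  if (is.null(log_outcome)) log_outcome <- od$log
  if (is.null(confounders)) confounders <- confounder_set(od$set)
  if (!outcome %in% names(table)) stop(sprintf("no column '%s'", outcome))
  missing_cols <- setdiff(c(parts, confounders), names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  confounders <- setdiff(confounders, parts)

  dat <- table[stats::complete.cases(table[, c(outcome, parts, confounders), drop = FALSE]), ,
               drop = FALSE]
  n <- nrow(dat)
  D <- length(parts)
  if (n <= D + length(confounders)) stop("too few complete rows to fit the model")
  y <- dat[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) stop("log-scale outcome has non-positive values")
    y <- log(y)
  }
  X <- as_comp_matrix(dat[, parts, drop = FALSE])
  CF <- dat[, confounders, drop = FALSE]

  rot <- data.frame(first = rotation_order, estimate = NA_real_,
                    se = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  fitted_ref <- NULL
  fitted_dev <- 0
  clr_dev <- 0
  first_res <- NULL
  for (k in seq_along(rotation_order)) {
    basis <- pivot_basis(parts, rotation_order[k])
    Z <- ilr(X, basis)
    mf <- data.frame(.y = y, Z, CF, check.names = TRUE)
    fit <- stats::lm(.y ~ ., data = mf)
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop(sprintf("rank-deficient design; aliased column(s): %s",
                   paste(names(cf)[is.na(cf)], collapse = ", ")))
    sm <- summary(fit)
    ct <- sm$coefficients
    rot$estimate[k] <- ct["z1", 1]
    rot$se[k] <- ct["z1", 2]
    rot$p[k] <- ct["z1", 4]
    b <- cf[colnames(basis$V)]
    a_k <- drop(basis$V %*% b)[parts]
    if (k == 1L) {
      fitted_ref <- stats::fitted(fit)
      a <- a_k
      first_res <- list(coord_coef = b, basis = basis, sigma = sm$sigma,
                        coefficients = cf)
    } else {
      fitted_dev <- max(fitted_dev, max(abs(stats::fitted(fit) - fitted_ref)))
      clr_dev <- max(clr_dev, max(abs(a_k - a)))
    }
  }

  basis1 <- pivot_basis(parts, rotation_order[1])
  Z1 <- ilr(X, basis1)
  fit0 <- stats::lm(y ~ Z1)
  sm0 <- summary(fit0)
  fs <- sm0$fstatistic
  f_p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)

  structure(list(
    outcome = outcome, log_outcome = log_outcome, parts = parts,
    confounders = confounders, n = n,
    rotations = rot, clr_coef = a,
    r_squared = sm0$r.squared, f_p = unname(f_p),
    sigma = first_res$sigma,
    coord_coef = first_res$coord_coef, basis = first_res$basis,
    diagnostics = c(max_fitted_dev = fitted_dev, max_clr_dev = clr_dev)),
    class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Compositional regression: %s%s (n = %d)\n",
              if (x$log_outcome) "log " else "", x$outcome, x$n))
  cat(sprintf("Unadjusted R-squared = %.4g (F-test p = %.3g)\n",
              x$r_squared, x$f_p))
  cat("First-pivot coefficients by rotation:\n")
  print(cbind(x$rotations[, "first", drop = FALSE],
              round(x$rotations[, c("estimate", "se", "p")], digits)),
        row.names = FALSE)
  cat("clr coefficients:\n")
  print(round(x$clr_coef, digits))
  invisible(x)
}

#' Model-predicted change between two compositions
#'
#' Difference in the linear predictor of a fitted compositional model between
#' two compositions, holding confounders fixed: computed through the stored
#' ilr coordinates, `b' (ilr(x2) - ilr(x1))`. For log-scale outcomes this is
#' a log-ratio; exponentiate for a multiplicative effect.
#'
#' @param fit A [fit_compositional()] result.
#' @param x1,x2 Compositions (named vectors over `fit$parts`).
#' @return Scalar predicted change on the model scale.
#' @export
predict_change <- function(fit, x1, x2) {
  stopifnot(inherits(fit, "coda_fit"))
  drop((ilr(x2, fit$basis) - ilr(x1, fit$basis)) %*% fit$coord_coef)
}

#' Sensitivity-analysis suite for the compositional models
#'
#' Refits the compositional regression for one outcome under the enumerated
#' specification variants: (i) total fat (%E) replacing carbohydrate among
#' the confounders; (ii) every subset of \{energy, protein, fat,
#' carbohydrate\} as the macro-adjustment block (16 variants; any variant
#' whose design is collinear is reported as skipped with the reason, not
#' dropped silently); (iii) the seven-part energy-nutrient composition
#' (protein, carbohydrate, the four fatty-acid classes, and fat other than
#' fatty acids, all in %E) analysed with the same pivot machinery -- six
#' coordinates per rotation, seven rotations.
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column name.
#' @return List with elements `fat_for_carb` (a `coda_fit`), `macro_subsets`
#'   (named list of `coda_fit` or skip records), and `seven_part`.
#' @export
sensitivity_suite <- function(table, outcome) {
  od <- outcome_defaults(outcome)
  base <- confounder_set(od$set)
  nonmacro <- setdiff(base, c("energy_kcal", "carb_e", "protein_e", "fat_e"))

  try_fit <- function(...) {
    tryCatch(fit_compositional(table, outcome, ...),
             error = function(e) list(skipped = TRUE, reason = conditionMessage(e)))
  }

  fat_for_carb <- try_fit(confounders = c(setdiff(base, "carb_e"), "fat_e"))

  macros <- c("energy_kcal", "protein_e", "fat_e", "carb_e")
  subsets <- lapply(0:15, function(m) macros[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0])
  names(subsets) <- vapply(subsets, function(s)
    if (length(s)) paste(sub("_e$|_kcal$", "", s), collapse = "+") else "none", "")
  macro_fits <- lapply(subsets, function(s) try_fit(confounders = c(nonmacro, s)))

  if (!"fat_other_e" %in% names(table))
    table$fat_other_e <- table$fat_e - table$fa_total_e
  parts7 <- c("protein_e", "carb_e", "sfa_e", "mufa_e", "n6_e", "n3_e",
              "fat_other_e")
  seven <- try_fit(parts = parts7,
                   confounders = c(nonmacro, "energy_kcal"),
                   rotation_order = parts7)

  list(fat_for_carb = fat_for_carb, macro_subsets = macro_fits,
       seven_part = seven)
}
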