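#' Traditional isocaloric substitution model
#'
#' Ordinary least squares of a (possibly log-transformed) outcome on energy
#' (kcal), protein (%E), carbohydrate (%E), three of the four fatty-acid
#' classes (%E), fat other than fatty acids (%E), and the outcome's standard
#' confounders. Because total energy and every other energy source are held
#' fixed, the coefficient of an included fatty acid reads as the effect of a
#' 1 %E increase at the expense of the omitted fatty acid. The omitted
#' reference is omega-6 PUFA for the SFA model and SFA for the MUFA, omega-6
#' and omega-3 models.
#'
#' The fat-other-than-fatty-acids term (`fat_e` minus the four FA %E columns)
#' is included in all four models by default: dropping it would let the
#' substitution come from an unnamed fat fraction and break the isocaloric
#' interpretation. Set `include_fat_other = FALSE` for the leaner reading.
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column name.
#' @param target Fatty acid of interest: "sfa", "mufa", "n6" or "n3".
#' @param omitted Substituted-out reference; default "n6" when
#'   `target == "sfa"`, otherwise "sfa".
#' @param include_fat_other Include the fat-without-fatty-acids term.
#' @param log_outcome,confounders As in [fit_compositional()].
#' @return Object of class `substitution_fit`: `fa_coefficients` (data frame
#'   `term`, `estimate`, `se`, `p` for each included FA, target first),
#'   `target`, `omitted`, `n`, and the full coefficient table.
#' @export
fit_substitution <- function(table, outcome,
                             target = c("sfa", "mufa", "n6", "n3"),
                             omitted = NULL, include_fat_other = TRUE,
                             log_outcome = NULL, confounders = NULL) {
  target <- match.arg(target)
  fa <- c("sfa", "mufa", "n6", "n3")
  if (is.null(omitted)) omitted <- if (target == "sfa") "n6" else "sfa"
  if (!omitted %in% fa) stop("'omitted' must be one of the four fatty acids")
  if (omitted == target) stop("target cannot be the omitted reference")
  od <- outcome_defaults(outcome)
  if (is.null(log_outcome)) log_outcome <- od$log
  if (is.null(confounders)) confounders <- confounder_set(od$set)

  included <- setdiff(fa, omitted)
  fa_cols <- paste0(included, "_e")
  if (!"fat_other_e" %in% names(table))
    table$fat_other_e <- table$fat_e - table$fa_total_e
  nutrient_cols <- c("energy_kcal", "protein_e", "carb_e", fa_cols,
                     if (include_fat_other) "fat_other_e")
  covars <- unique(c(nutrient_cols, confounders))
  missing_cols <- setdiff(c(outcome, covars), names(table))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))

  neg <- mean(table$fat_other_e < 0, na.rm = TRUE)
  if (include_fat_other && isTRUE(neg > 0.01))
    warning(sprintf("fat-without-fatty-acids negative in %.1f%% of rows; %s",
                    100 * neg, "check fat and fatty-acid columns for consistency"))

  dat <- table[stats::complete.cases(table[, c(outcome, covars), drop = FALSE]), ,
               drop = FALSE]
  y <- dat[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) stop("log-scale outcome has non-positive values")
    y <- log(y)
  }
  mf <- data.frame(.y = y, dat[, covars, drop = FALSE], check.names = TRUE)
  fit <- stats::lm(.y ~ ., data = mf)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; aliased column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  ct <- summary(fit)$coefficients
  ord <- c(target, setdiff(included, target))
  fa_tab <- data.frame(term = ord,
                       estimate = ct[paste0(ord, "_e"), 1],
                       se = ct[paste0(ord, "_e"), 2],
                       p = ct[paste0(ord, "_e"), 4],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(outcome = outcome, log_outcome = log_outcome,
                 target = target, omitted = omitted, n = nrow(dat),
                 include_fat_other = include_fat_other,
                 fa_coefficients = fa_tab, coefficients = ct),
            class = "substitution_fit")
}

#' @export
print.substitution_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Isocaloric substitution model: %s%s, %s <- %s (n = %d)\n",
              if (x$log_outcome) "log " else "", x$outcome,
              x$target, x$omitted, x$n))
  tab <- x$fa_coefficients
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Substitution-model summary across outcomes
#'
#' Fits the four standard substitution models (SFA at the expense of omega-6;
#' MUFA, omega-6 and omega-3 each at the expense of SFA) for each outcome and
#' tabulates the target fatty acid's coefficient.
#'
#' @param table Cohort data frame.
#' @param outcomes Outcome column names (default the ten standard outcomes).
#' @param ... Passed to [fit_substitution()].
#' @return Data frame: `outcome`, `target`, `omitted`, `estimate`, `se`, `p`,
#'   `n`.
#' @export
substitution_table <- function(table,
                               outcomes = reference_estimates()$outcomes$name,
                               ...) {
  rows <- list()
  for (oc in outcomes) {
    for (tg in c("sfa", "mufa", "n6", "n3")) {
      f <- fit_substitution(table, oc, target = tg, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, target = tg, omitted = f$omitted,
        estimate = f$fa_coefficients$estimate[1],
        se = f$fa_coefficients$se[1], p = f$fa_coefficients$p[1],
        n = f$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
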