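#' Exclusion-rule configuration
#'
#' Reference energy expenditures (EER) used by the plausible-energy screen,
#' and the LDL-C cut-off for suspected familial hyperlipidaemia. The EER
#' defaults are the Japanese Dietary Reference Intakes for 12-14-year-olds:
#' physical activity level I (low) and level III (high), sex-specific. They
#' are package defaults for this age band, to be replaced when screening a
#' different population.
#'
#' @param eer_low Named vector `c(male=, female=)`: EER (kcal/day) at
#'   physical activity level I.
#' @param eer_high Named vector `c(male=, female=)`: EER at physical activity
#'   level III.
#' @param ldl_cut LDL-C exclusion threshold in mg/dL (inclusive; default 140).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(eer_low = c(male = 2300, female = 2150),
                          eer_high = c(male = 2900, female = 2700),
                          ldl_cut = 140) {
  for (v in list(eer_low, eer_high)) {
    if (!all(c("male", "female") %in% names(v)))
      stop("EER references must be named vectors with 'male' and 'female'")
    if (any(v <= 0)) stop("EER references must be positive")
  }
  if (any(eer_low[c("male", "female")] >= eer_high[c("male", "female")]))
    stop("eer_low must be below eer_high")
  if (ldl_cut <= 0) stop("ldl_cut must be positive")
  structure(list(eer_low = eer_low, eer_high = eer_high, ldl_cut = ldl_cut),
            class = "filter_config")
}

#' Plausible-energy screen
#'
#' An energy intake is plausible when it lies between half the low-activity
#' reference energy expenditure and 1.5 times the high-activity reference,
#' for the subject's sex. Both boundaries are inclusive.
#'
#' @param energy Energy intake(s), kcal/day.
#' @param sex 0/1 (female/male) or "female"/"male", recycled against `energy`.
#' @param config A [filter_config()].
#' @return Logical vector; `NA` energy yields `NA`.
#' @export
plausible_energy <- function(energy, sex, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  sx <- sex_key(sex)
  lo <- 0.5 * config$eer_low[sx]
  hi <- 1.5 * config$eer_high[sx]
  unname(energy >= lo & energy <= hi)
}

sex_key <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1) | is.na(sex))) stop("numeric sex must be 0 (female) or 1 (male)")
    return(ifelse(sex == 1, "male", "female"))
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female") | is.na(sex)))
    stop("sex must be 0/1 or 'female'/'male'")
  sex
}

#' Apply subject exclusion rules
#'
#' Removes subjects failing any of four rules, in order: (1) missing data in
#' any required analysis column; (2) implausible energy intake
#' ([plausible_energy()]); (3) physician-diagnosed disease (`disease == 1`);
#' (4) LDL-C at or above the cut-off (suspected familial
#' hyperlipidaemia; the boundary is excluded, `>=`). Each removed subject is
#' tallied at the first rule it fails, mirroring a subject-selection
#' flowchart.
#'
#' @param table Cohort data frame (see [generate_cohort()] for the schema).
#' @param config A [filter_config()].
#' @param required_cols Columns checked for missingness under rule 1;
#'   defaults to every analysis column present in the table.
#' @return List with `data` (retained rows), `tally` (named integer vector
#'   `missing`, `implausible_energy`, `disease`, `high_ldl`), and `n_input`.
#' @export
apply_exclusions <- function(table, config = filter_config(),
                             required_cols = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (is.null(required_cols)) {
    candidates <- c("sex", "age", "physact", "sleep_h", "screen",
                    "single_parent", "siblings", "energy_kcal", "protein_e",
                    "fat_e", "carb_e", "sodium_mg", "fa_total_e",
                    "sfa_e", "mufa_e", "n6_e", "n3_e", "zbmi", "ldl")
    required_cols <- intersect(candidates, names(table))
  }
  n <- nrow(table)
  fail_rule <- integer(n)  # 0 = retained, k = first rule failed

  miss <- rowSums(is.na(table[, required_cols, drop = FALSE])) > 0
  fail_rule[miss] <- 1L

  ok_energy <- plausible_energy(table$energy_kcal, table$sex, config)
  bad <- !is.na(ok_energy) & !ok_energy
  fail_rule[fail_rule == 0L & bad] <- 2L

  if ("disease" %in% names(table)) {
    dz <- !is.na(table$disease) & table$disease == 1
    fail_rule[fail_rule == 0L & dz] <- 3L
  }

  hi <- !is.na(table$ldl) & table$ldl >= config$ldl_cut
  fail_rule[fail_rule == 0L & hi] <- 4L

  tally <- c(missing = sum(fail_rule == 1L),
             implausible_energy = sum(fail_rule == 2L),
             disease = sum(fail_rule == 3L),
             high_ldl = sum(fail_rule == 4L))
  list(data = table[fail_rule == 0L, , drop = FALSE],
       tally = tally, n_input = n)
}
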