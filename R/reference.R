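#' Published reference estimates from the motivating cohort
#'
#' Summary statistics reported by the motivating study of dietary fatty-acid
#' composition in a school-based sample of 5485 Japanese eighth-graders: the
#' compositional geometric means and variation matrix of the four fatty-acid
#' classes, arithmetic marginals of energy, macronutrients, sodium and the
#' cardiometabolic outcomes, and the first-pivot regression coefficients
#' (one per rotation) of the confounder-adjusted compositional models. These
#' values calibrate the synthetic cohort generator and drive the worked
#' change-matrix reconstruction; subject-level data were never deposited.
#'
#' Fatty-acid parts are always ordered SFA, MUFA, omega-6 PUFA, omega-3 PUFA
#' (labels `sfa`, `mufa`, `n6`, `n3`).
#'
#' @return A list with components:
#' \describe{
#'   \item{parts}{part labels in rotation order.}
#'   \item{geometric_mean}{per-part compositional geometric means (% of total
#'     fatty acids; not re-closed, sum 99.2).}
#'   \item{variation}{4 x 4 variation matrix (variances of pairwise
#'     log-ratios).}
#'   \item{marginals}{named list of `c(mean, sd)` for dietary energy (kcal),
#'     total fatty acids (%E), protein/fat/carbohydrate (%E), sodium
#'     (mg/1000 kcal) and age (years).}
#'   \item{fa_share_of_fat}{total fatty acids as a fraction of fat intake
#'     (26.2/30.1).}
#'   \item{sex_male_p}{proportion of male subjects.}
#'   \item{outcomes}{data frame, one row per cardiometabolic outcome: `name`,
#'     `log` (modelled on the natural-log scale), `mean`, `sd` (arithmetic,
#'     original scale), `confounder_set` ("A" anthropometric, "B" adds zBMI).}
#'   \item{pivot_beta}{outcomes x 4 matrix of published first-pivot
#'     coefficients (effect of each fatty acid relative to the remaining
#'     ones, confounder-adjusted).}
#' }
#' @export
reference_estimates <- function() {
  parts <- c("sfa", "mufa", "n6", "n3")
  variation <- matrix(
    c(0,     0.031, 0.077, 0.112,
      0.031, 0,     0.018, 0.046,
      0.077, 0.018, 0,     0.038,
      0.112, 0.046, 0.038, 0),
    4, 4, byrow = TRUE, dimnames = list(parts, parts))
  outcomes <- data.frame(
    name = c("height", "weight", "zbmi", "ldl", "hdl", "sbp", "dbp",
             "ast", "alt", "ggt"),
    log  = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    mean = c(156.8, 47.2, 0, 86.9, 67.2, 114.5, 67.7, 21.1, 13.5, 15.4),
    sd   = c(7.1, 8.6, 1, 19, 13.8, 11.5, 8.6, 5.9, 6.9, 5),
    confounder_set = c("A", "A", "A", "B", "B", "B", "B", "B", "B", "B"),
    stringsAsFactors = FALSE)
  pivot_beta <- matrix(
    c(-0.22,  0.78, -0.32, -0.06,   # height, cm
      -0.83,  2.55, -1.52,  0.92,   # weight, kg
       0.01,  0.10, -0.17,  0.17,   # zBMI
       0.02,  0.08, -0.11,  0.00,   # log LDL-C
       0.03, -0.03,  0.02, -0.02,   # log HDL-C
      -0.85,  1.44,  1.32, -2.35,   # SBP, mmHg
      -0.47,  0.57,  1.68, -2.41,   # DBP, mmHg
       0.01, -0.01, -0.01,  0.02,   # log AST
       0.05, -0.10, -0.01,  0.10,   # log ALT
       0.07, -0.08, -0.01,  0.03),  # log GGT
    nrow = 10, byrow = TRUE, dimnames = list(outcomes$name, parts))
  list(
    parts = parts,
    geometric_mean = c(sfa = 36.1, mufa = 38.9, n6 = 20.0, n3 = 4.2),
    variation = variation,
    marginals = list(
      energy_kcal = c(mean = 2238, sd = 640),
      fa_total_e  = c(mean = 26.2, sd = 5.1),
      protein_e   = c(mean = 14.2, sd = 2.4),
      fat_e       = c(mean = 30.1, sd = 5.6),
      carb_e      = c(mean = 54.2, sd = 6.7),
      sodium_mg   = c(mean = 1848, sd = 429),
      age         = c(mean = 13.56, sd = 0.29)),
    fa_share_of_fat = 0.87,
    sex_male_p = 0.521,
    outcomes = outcomes,
    pivot_beta = pivot_beta)
}
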