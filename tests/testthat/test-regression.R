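tab <- test_cohort(n = 3000, seed = 7)
parts <- c("sfa", "mufa", "n6", "n3")

test_that("rotations agree on fitted values and clr coefficients", {
  f <- fit_compositional(tab, "ldl")
  expect_lt(f$diagnostics[["max_fitted_dev"]], 1e-9)
  expect_lt(f$diagnostics[["max_clr_dev"]], 1e-10)
  # clr coefficients from any single fit sum to zero
  expect_lt(abs(sum(f$clr_coef)), 1e-10)
  # first-pivot coefficient of each rotation is sqrt(D/(D-1)) * clr coef
  expect_equal(f$rotations$estimate, unname(f$clr_coef[f$rotations$first]) * 2 / sqrt(3),
               tolerance = 1e-9)
  # assembling clr coefficients from the four first-pivot estimates is
  # self-consistent (zero residual) on the package's own fits
  rec <- clr_from_first_pivot(f$rotations$estimate)
  expect_lt(abs(rec$residual), 1e-10)
  expect_equal(unname(rec$a), unname(f$clr_coef[f$rotations$first]),
               tolerance = 1e-10)
  # unadjusted R^2 / F p are invariant to the rotation order used
  g <- fit_compositional(tab, "ldl", rotation_order = rev(parts))
  expect_equal(g$r_squared, f$r_squared, tolerance = 1e-9)
  expect_equal(g$f_p, f$f_p, tolerance = 1e-9)
  expect_equal(sort(g$rotations$estimate), sort(f$rotations$estimate),
               tolerance = 1e-9)
})

test_that("outcome defaults select log scale and confounder set", {
  f <- fit_compositional(tab, "ldl")
  expect_true(f$log_outcome)
  expect_true("zbmi" %in% f$confounders)
  h <- fit_compositional(tab, "height")
  expect_false(h$log_outcome)
  expect_false("zbmi" %in% h$confounders)
  expect_error(fit_compositional(tab, "nope"), "no column")
  # rank-deficient designs are reported, not silently dropped
  tab2 <- tab
  tab2$dup <- tab2$age
  expect_error(fit_compositional(tab2, "ldl",
                                 confounders = c("age", "dup")),
               "aliased.*dup")
})

test_that("configured clr coefficients are recovered from generated data", {
  big <- test_cohort(n = 20000, seed = 7)
  a_true <- cohort_config()$outcome_models$ldl$clr_coef
  # the generator's systematic part only identifies the centered component
  a_true <- a_true - mean(a_true)
  f <- fit_compositional(big, "ldl", confounders = character(0))
  se <- f$rotations$se * sqrt(3) / 2           # clr-scale standard errors
  expect_true(all(abs(f$clr_coef[f$rotations$first] - a_true[f$rotations$first])
                  <= 3 * se))
})

test_that("a pure-noise outcome shows no compositional signal", {
  set.seed(31)
  tab3 <- tab
  tab3$noise <- rnorm(nrow(tab3))
  f <- fit_compositional(tab3, "noise", log_outcome = FALSE,
                         confounders = character(0))
  expect_lt(f$r_squared, 0.005)   # approx (D-1)/N scale
  expect_gt(f$f_p, 0.001)
})

test_that("sensitivity suite runs the enumerated specification variants", {
  small <- test_cohort(n = 1500, seed = 13)
  s <- sensitivity_suite(small, "ldl")
  # (i) fat replaces carbohydrate among the confounders
  expect_s3_class(s$fat_for_carb, "coda_fit")
  expect_true("fat_e" %in% s$fat_for_carb$confounders)
  expect_false("carb_e" %in% s$fat_for_carb$confounders)
  expect_lt(abs(sum(s$fat_for_carb$clr_coef)), 1e-10)
  # (ii) all 16 macro-adjustment subsets
  expect_length(s$macro_subsets, 16L)
  expect_true("none" %in% names(s$macro_subsets))
  expect_true("energy+protein+fat+carb" %in% names(s$macro_subsets))
  fitted_ok <- vapply(s$macro_subsets, inherits, TRUE, what = "coda_fit")
  skipped <- !fitted_ok
  if (any(skipped))
    expect_true(all(vapply(s$macro_subsets[skipped],
                           function(z) isTRUE(z$skipped) && nzchar(z$reason), TRUE)))
  # (iii) seven-part energy-nutrient composition: 7 rotations, 6 coordinates
  expect_s3_class(s$seven_part, "coda_fit")
  expect_equal(nrow(s$seven_part$rotations), 7L)
  expect_length(s$seven_part$coord_coef, 6L)
  expect_lt(abs(sum(s$seven_part$clr_coef)), 1e-10)
})
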