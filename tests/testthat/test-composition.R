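test_that("closure rescales to kappa and preserves ratios", {
  expect_equal(close_comp(c(1, 1, 1, 1)), c(25, 25, 25, 25))
  expect_equal(close_comp(c(2, 2), kappa = 1), c(0.5, 0.5))
  # arithmetic means of the four fatty-acid classes in %E, closed to 100
  x <- close_comp(c(sfa = 9.6, mufa = 10.3, n6 = 5.3, n3 = 1.1))
  expect_equal(sum(x), 100)
  expect_equal(unname(x), c(9.6, 10.3, 5.3, 1.1) * 100 / 26.3, tolerance = 1e-12)
  expect_equal(unname(x["sfa"]), 36.5019011, tolerance = 1e-7)

  expect_error(close_comp(c(a = 1, b = 0)), "b")
  expect_error(close_comp(c(1, -2, 3)), "part 2")
  expect_error(close_comp(numeric(0)), "empty")
  expect_error(close_comp(c(1, 1), kappa = -1), "kappa")
})

test_that("clr centers log parts and is scale invariant", {
  expect_equal(clr(rep(12, 5)), rep(0, 5))
  z <- clr(c(36.1, 38.9, 20.0, 4.2))
  expect_equal(sum(z), 0, tolerance = 1e-10)
  expect_equal(z[1], 0.6667669, tolerance = 1e-6)      # ln(36.1 / g(x))
  x <- c(3, 1, 4, 1.5)
  expect_equal(clr(7 * x), clr(x), tolerance = 1e-12)
  expect_error(clr(c(1, 0, 2)))
  # matrix form matches row-wise vector form
  X <- random_comps(6, 4)
  expect_equal(clr(X)[3, ], clr(X[3, ]))
  expect_equal(clr_inv(clr(X)), close_rows(X), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pivot basis has the closed-form first coordinate and orthonormal columns", {
  labs <- c("sfa", "mufa", "n6", "n3")
  for (f in labs) {
    B <- pivot_basis(labs, f)
    expect_equal(crossprod(B$V), diag(3), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(colSums(B$V), rep(0, 3), ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(B$V[1, 1], sqrt(3 / 4))
    expect_equal(B$V[2:4, 1], rep(-1 / sqrt(4 * 3), 3), ignore_attr = TRUE)
  }
  x <- c(sfa = 36.1, mufa = 38.9, n6 = 20.0, n3 = 4.2)
  z1 <- ilr(x, pivot_basis(labs, "sfa"))[1]
  expect_equal(unname(z1), 0.7699161, tolerance = 1e-6)
  # D = 2 closed form
  z <- ilr(c(a = 3, b = 5), pivot_basis(c("a", "b")))
  expect_equal(unname(z), log(3 / 5) / sqrt(2), tolerance = 1e-12)
  expect_error(pivot_basis(labs, "trans"), "unknown")
  expect_error(pivot_basis("one"), "two parts")
})

test_that("ilr is an isometry with exact round trip", {
  labs <- paste0("p", 1:4)
  B <- pivot_basis(labs, "p2")
  x <- c(p1 = 36.1, p2 = 38.9, p3 = 20.0, p4 = 4.2)
  expect_equal(ilr_inv(ilr(x, B), B), close_comp(x), tolerance = 1e-9)
  expect_equal(ilr(rep(25, 4), B), rep(0, 3), ignore_attr = TRUE)
  # pairwise ilr distances equal clr-space Euclidean distances
  X <- random_comps(8, 4, seed = 3)
  Z <- ilr(X, pivot_basis(colnames(X)))
  C <- clr(X)
  expect_equal(as.matrix(dist(Z)), as.matrix(dist(C)), tolerance = 1e-9)
  # matrix round trip
  B2 <- pivot_basis(colnames(X), "p3")
  expect_equal(ilr_inv(ilr(X, B2), B2),
               close_rows(X), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(ilr_inv(c(1, 2), B), "dimension")
})

test_that("variation matrix matches the naive log-ratio variances", {
  # all rows proportional to one composition -> zero dispersion
  X <- outer(c(1, 2, 5), c(2, 3, 4, 1))
  expect_equal(max(abs(variation_matrix(X))), 0, tolerance = 1e-12)
  # two-subject hand case: var{ln(1/2), ln(2)} = 2 ln(2)^2
  T2 <- variation_matrix(rbind(c(1, 2), c(2, 1)))
  expect_equal(T2[1, 2], 2 * log(2)^2, tolerance = 1e-12)
  expect_equal(T2[1, 2], 0.9609060, tolerance = 1e-6)
  # brute-force oracle on small random samples
  for (s in 1:3) {
    X <- random_comps(10, 5, seed = s)
    T <- variation_matrix(X)
    expect_equal(unclass(T), naive_variation(X), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(T, t(T))
    expect_true(all(diag(T) == 0) && all(T >= 0))
    # scale invariance under arbitrary per-row rescaling
    set.seed(s + 100)
    expect_equal(variation_matrix(X * runif(10, 0.1, 9)), T, tolerance = 1e-10)
  }
  expect_error(variation_matrix(X[1, , drop = FALSE]), "two subjects")
})

test_that("compositional geometric mean is per-part and not re-closed", {
  X <- matrix(rep(c(30, 50, 20), each = 4), 4)
  expect_equal(unname(comp_geometric_mean(X)), c(30, 50, 20))
  g <- comp_geometric_mean(rbind(c(50, 50), c(25, 75)))
  expect_equal(unname(g), c(sqrt(50 * 25), sqrt(50 * 75)), tolerance = 1e-12)
  expect_equal(unname(g), c(35.35534, 61.23724), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(sum(g), 100)))  # deliberately not re-closed
  expect_warning(comp_geometric_mean(rbind(c(1, 2), c(2, 1))), "closing")
})

test_that("reallocation moves mass between two parts only", {
  x <- c(sfa = 36.1, mufa = 38.9, n6 = 20.0, n3 = 4.2)
  y <- reallocate(x, "sfa", "n6", 4)
  expect_equal(unname(y), c(32.1, 38.9, 24.0, 4.2))
  expect_equal(sum(y), sum(x))
  expect_equal(reallocate(x, "mufa", "n3", 0), x)
  expect_error(reallocate(x, "n3", "sfa", 4.3), "not be positive")
  expect_error(reallocate(x, "tfa", "sfa", 1), "unknown")
})

test_that("clr coefficients follow from first-pivot coefficients", {
  z <- clr_from_first_pivot(c(0, 0, 0, 0))
  expect_equal(z$a, c(0, 0, 0, 0))
  expect_equal(z$residual, 0)
  # published log LDL-C first-pivot row, rounded to two decimals
  r <- clr_from_first_pivot(c(0.02, 0.08, -0.11, 0.00))
  expect_equal(r$a, sqrt(3) / 2 * c(0.02, 0.08, -0.11, 0), tolerance = 1e-12)
  expect_equal(r$a, c(0.0173205, 0.0692820, -0.0952628, 0), tolerance = 1e-6)
  expect_equal(r$residual, -0.00866025, tolerance = 1e-5)  # rounding artefact
  expect_error(clr_from_first_pivot(1), "two parts")
})
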