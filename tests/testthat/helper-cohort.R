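# shared fixtures, built once per test run

.facoda_cache <- new.env(parent = emptyenv())

# moderate synthetic cohort reused by the model-fitting tests
test_cohort <- function(n = 3000, seed = 7L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(.facoda_cache[[key]]))
    .facoda_cache[[key]] <- generate_cohort(cohort_config(n = n, seed = seed))
  .facoda_cache[[key]]
}

# random strictly positive compositions for property-style tests
random_comps <- function(n, D, seed = 1L) {
  set.seed(seed)
  m <- matrix(exp(stats::rnorm(n * D)), n, D)
  colnames(m) <- paste0("p", seq_len(D))
  m
}

# naive variation matrix: double loop over part pairs, plain var()
naive_variation <- function(X) {
  D <- ncol(X)
  T <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D))
    if (i != j) T[i, j] <- stats::var(log(X[, i] / X[, j]))
  T
}
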