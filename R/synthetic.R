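#' clr covariance from a variation matrix
#'
#' Converts a variation matrix T (variances of pairwise log-ratios) into the
#' clr-space covariance that generates it, by double centering:
#' `Sigma = -1/2 * G T G` with `G = I - (1/D) 11'`. The induced
#' `var(clr_i - clr_j) = Sigma_ii + Sigma_jj - 2 Sigma_ij` reproduces
#' `T[i, j]` exactly. Rows of `Sigma` sum to zero (clr is a contrast space),
#' so `Sigma` is singular by construction.
#'
#' @param T Symmetric non-negative matrix with zero diagonal.
#' @return D x D clr covariance matrix.
#' @export
clr_cov_from_variation <- function(T) {
  T <- as.matrix(T)
  D <- nrow(T)
  if (ncol(T) != D) stop("variation matrix must be square")
  if (max(abs(T - t(T))) > 1e-10) stop("variation matrix must be symmetric")
  if (max(abs(diag(T))) > 1e-10) stop("variation matrix must have zero diagonal")
  if (any(T < 0)) stop("variation matrix entries must be non-negative")
  G <- diag(D) - 1 / D
  Sigma <- -0.5 * G %*% T %*% G
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("variation matrix is not realizable as a clr covariance (eigenvalue %.3g)",
                 min(ev)))
  dimnames(Sigma) <- dimnames(T)
  Sigma
}

#' Calibrate the clr-normal center to target geometric means
#'
#' Closure is nonlinear, so the per-part geometric means of closed draws from
#' a clr-normal distribution do not equal `exp(mu)`. This routine finds the
#' clr-space mean `mu` whose closed draws hit the target per-part geometric
#' means, by a fixed-point iteration on a single pilot sample (common random
#' numbers): draw once, then repeatedly close, measure the achieved geometric
#' means, and shift `mu` by `log(target / achieved)`. Ratios between parts
#' converge after one step; the remaining common scale factor reflects how
#' close the (rounded) targets are to a realizable geometric-mean vector.
#'
#' @param gm_target Positive vector of target per-part geometric means, on
#'   the closed scale.
#' @param Sigma clr covariance (from [clr_cov_from_variation()]).
#' @param kappa Closure constant (default 100).
#' @param n_pilot Pilot sample size (default 1e5).
#' @param tol Convergence tolerance on `max |achieved - target|`, in the
#'   units of `gm_target` (default 0.05 percentage points).
#' @param max_iter Maximum fixed-point iterations.
#' @return Numeric `mu` (clr-space mean) with attributes `achieved`
#'   (pilot-sample geometric means) and `iterations`. Uses the current RNG
#'   stream; seed upstream for reproducibility.
#' @export
calibrate_center <- function(gm_target, Sigma, kappa = 100, n_pilot = 1e5,
                             tol = 0.05, max_iter = 50) {
  check_positive_parts(gm_target)
  D <- length(gm_target)
  if (!all(dim(Sigma) == D)) stop("dimension mismatch between targets and Sigma")
  mu <- log(gm_target)
  if (max(abs(Sigma)) == 0) {
    # closure is deterministic: achieved = closed targets
    ach <- close_comp(gm_target, kappa)
    return(structure(mu, achieved = ach, iterations = 0L))
  }
  E <- rclrnorm(n_pilot, rep(0, D), Sigma)
  ach <- NULL
  for (it in seq_len(max_iter)) {
    Xc <- close_rows(exp(sweep(E, 2, mu, "+")), kappa)
    ach <- exp(colMeans(log(Xc)))
    if (max(abs(ach - gm_target)) < tol)
      return(structure(mu, achieved = stats::setNames(ach, names(gm_target)),
                       iterations = it))
    mu <- mu + log(gm_target / ach)
  }
  stop(sprintf(
    "center calibration did not converge in %d iterations; achieved (%s) vs target (%s)",
    max_iter, paste(signif(ach, 5), collapse = ", "),
    paste(gm_target, collapse = ", ")))
}

# draw n clr-normal vectors (rows sum to mu-centred contrast space)
rclrnorm <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sigma))
  D <- nrow(Sigma)
  sweep(matrix(stats::rnorm(n * D), nrow = n, ncol = D) %*% t(L), 2, mu, "+")
}

# inverse-CDF truncated normal: reproducible, no rejection loop
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Configuration for the synthetic cohort generator
#'
#' Assembles the full generator configuration, defaulting every distribution
#' to the published summary statistics of the motivating cohort
#' ([reference_estimates()]): the fatty-acid composition is logistic-normal
#' with the published variation matrix and center calibrated to the published
#' geometric means; energy, macronutrients and sodium are truncated normals
#' with the published mean/SD; each outcome follows a linear model in the clr
#' composition (coefficients reconstructed from the published first-pivot
#' coefficients via `a = sqrt((D-1)/D) * beta`) with Gaussian residuals, on
#' the natural-log scale for LDL-C, HDL-C, AST, ALT and GGT. Residual SDs
#' default to values reproducing the published outcome SDs (for log-scale
#' outcomes, `sqrt(log(1 + (sd/mean)^2))`), since the composition explains
#' under 1% of outcome variance. Confounders are generated independently of
#' the composition unless `confounder_coef` entries are supplied.
#'
#' @param n Number of subjects (default 5485, the motivating cohort size).
#' @param seed Integer seed; the generated table is byte-identical across
#'   runs for a fixed config.
#' @param ... Named overrides for any top-level config element (e.g.
#'   `gm_target`, `variation`, `marginals`, `outcome_models`, `confounders`,
#'   `disease_p`, `missing_p`, `calib`). Lists are merged element-wise.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 5485, seed = 1L, ...) {
  ref <- reference_estimates()
  om <- list()
  for (i in seq_len(nrow(ref$outcomes))) {
    o <- ref$outcomes[i, ]
    sd_resid <- if (o$log) sqrt(log1p((o$sd / o$mean)^2)) else o$sd
    om[[o$name]] <- list(
      clr_coef = sqrt(3 / 4) * ref$pivot_beta[o$name, ],  # sqrt((D-1)/D), D = 4
      log = o$log, mean = o$mean, sd_resid = sd_resid,
      confounder_coef = NULL)
  }
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed), kappa = 100,
    parts = ref$parts,
    gm_target = ref$geometric_mean,
    variation = ref$variation,
    fa_share_of_fat = ref$fa_share_of_fat,
    marginals = ref$marginals,
    confounders = list(
      sex_male_p = ref$sex_male_p,
      age = ref$marginals$age,
      activity_p = 0.5,
      sleep = c(mean = 7.3, sd = 0.9),
      screen_p = c(0.30, 0.30, 0.20, 0.12, 0.08),
      single_parent_p = 0.12,
      siblings_p = c(0.40, 0.45, 0.15)),
    outcome_models = om,
    trunc_sd = 4,
    disease_p = 0,
    missing_p = 0,
    calib = list(n_pilot = 1e5, tol = 0.05, max_iter = 50))
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown config element(s): %s", paste(unknown, collapse = ", ")))
    cfg <- utils::modifyList(cfg, dots)
  }
  if (cfg$n < 0) stop("'n' must be non-negative")
  if (any(cfg$gm_target <= 0)) stop("geometric-mean targets must be positive")
  sds <- vapply(cfg$outcome_models, function(m) m$sd_resid, 0)
  if (any(sds <= 0)) stop("residual SDs must be positive")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort table
#'
#' Draws a subject-level table with the statistical structure the analysis
#' pipeline assumes: a logistic-normal four-part fatty-acid composition,
#' truncated-normal dietary marginals, independent confounders, and outcomes
#' that are linear in the clr-transformed composition with Gaussian noise
#' (additive on the natural-log scale for the skewed blood markers, then
#' exponentiated). Fully reproducible from `config$seed`.
#'
#' Columns: closed fatty-acid shares (`sfa`, `mufa`, `n6`, `n3`, summing to
#' 100), the same parts as %E (`*_e`), `fa_total_e`, `energy_kcal`,
#' `protein_e`, `fat_e`, `carb_e`, `sodium_mg`, confounders (`sex` 0/1
#' female/male, `age`, `physact` 0/1, `sleep_h`, `screen` ordinal 1-5,
#' `single_parent` 0/1, `siblings` ordinal 1-3, `disease` 0/1) and the ten
#' outcome columns on their original measurement scales. See
#' [cohort_dictionary()].
#'
#' @param config A [cohort_config()].
#' @return A `data.frame`, one row per subject (possibly zero rows).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  set.seed(config$seed)
  D <- length(config$parts)
  Sigma <- clr_cov_from_variation(config$variation)

  # composition: calibrated clr-normal, closed to kappa
  if (n > 0L) {
    mu <- calibrate_center(config$gm_target, Sigma, kappa = config$kappa,
                           n_pilot = config$calib$n_pilot,
                           tol = config$calib$tol,
                           max_iter = config$calib$max_iter)
  } else {
    mu <- log(config$gm_target)
  }
  Z <- rclrnorm(n, mu, Sigma)
  comp <- close_rows(exp(Z), config$kappa)
  colnames(comp) <- config$parts

  tn <- function(par, lower_floor = NULL) {
    lo <- par[["mean"]] - config$trunc_sd * par[["sd"]]
    if (!is.null(lower_floor)) lo <- max(lo, lower_floor)
    rtnorm(n, par[["mean"]], par[["sd"]], lo, par[["mean"]] + config$trunc_sd * par[["sd"]])
  }
  fa_total_e <- tn(config$marginals$fa_total_e, 1e-3)
  fat_e <- fa_total_e / config$fa_share_of_fat
  fa_e <- comp / config$kappa * fa_total_e
  colnames(fa_e) <- paste0(config$parts, "_e")

  energy_kcal <- tn(config$marginals$energy_kcal, 1)
  protein_e <- tn(config$marginals$protein_e, 1e-3)
  carb_e <- tn(config$marginals$carb_e, 1e-3)
  sodium_mg <- tn(config$marginals$sodium_mg, 1)

  cf <- config$confounders
  sex <- as.integer(stats::runif(n) < cf$sex_male_p)
  age <- rtnorm(n, cf$age[["mean"]], cf$age[["sd"]],
                cf$age[["mean"]] - config$trunc_sd * cf$age[["sd"]],
                cf$age[["mean"]] + config$trunc_sd * cf$age[["sd"]])
  physact <- as.integer(stats::runif(n) < cf$activity_p)
  sleep_h <- rtnorm(n, cf$sleep[["mean"]], cf$sleep[["sd"]],
                    cf$sleep[["mean"]] - config$trunc_sd * cf$sleep[["sd"]],
                    cf$sleep[["mean"]] + config$trunc_sd * cf$sleep[["sd"]])
  screen <- ordinal_draw(n, cf$screen_p)
  single_parent <- as.integer(stats::runif(n) < cf$single_parent_p)
  siblings <- ordinal_draw(n, cf$siblings_p)
  disease <- as.integer(stats::runif(n) < config$disease_p)

  tab <- data.frame(
    id = seq_len(n), sex = sex, age = age, physact = physact,
    sleep_h = sleep_h, screen = screen, single_parent = single_parent,
    siblings = siblings, disease = disease,
    energy_kcal = energy_kcal, protein_e = protein_e, fat_e = fat_e,
    carb_e = carb_e, sodium_mg = sodium_mg, fa_total_e = fa_total_e)
  tab <- cbind(tab, as.data.frame(fa_e), as.data.frame(comp))

  # outcomes: linear in clr(composition) (+ optional confounder terms);
  # intercept absorbs the realized mean of the systematic part so the
  # outcome mean matches its target (for log outcomes, E[X] = mean via
  # the lognormal mean correction).
  C <- clr(comp)
  for (nm in names(config$outcome_models)) {
    m <- config$outcome_models[[nm]]
    eta <- if (n > 0L) drop(C %*% m$clr_coef) else numeric(0)
    if (!is.null(m$confounder_coef) && length(m$confounder_coef)) {
      for (v in names(m$confounder_coef)) {
        if (!v %in% names(tab)) stop(sprintf("confounder '%s' not in table", v))
        eta <- eta + m$confounder_coef[[v]] * tab[[v]]
      }
    }
    eps <- stats::rnorm(n, 0, m$sd_resid)
    if (m$log) {
      icpt <- log(m$mean) - m$sd_resid^2 / 2 - if (n > 0L) mean(eta) else 0
      tab[[nm]] <- exp(icpt + eta + eps)
    } else {
      icpt <- m$mean - if (n > 0L) mean(eta) else 0
      tab[[nm]] <- icpt + eta + eps
    }
  }

  if (config$missing_p > 0 && n > 0L) {
    miss <- stats::runif(n) < config$missing_p
    tab$sodium_mg[miss] <- NA_real_
  }
  attr(tab, "clr_center") <- mu
  tab
}

ordinal_draw <- function(n, probs) {
  if (abs(sum(probs) - 1) > 1e-8) stop("ordinal probabilities must sum to 1")
  findInterval(stats::runif(n), cumsum(probs)) + 1L
}

#' Column dictionary for the synthetic cohort table
#'
#' @return Data frame with one row per column of [generate_cohort()] output:
#'   name, units, description.
#' @export
cohort_dictionary <- function() {
  d <- rbind(
    c("id", "-", "subject index"),
    c("sex", "0/1", "0 = female, 1 = male"),
    c("age", "years", "age at examination"),
    c("physact", "0/1", "exercises more than twice per week"),
    c("sleep_h", "hours", "sleep duration"),
    c("screen", "ordinal 1-5", "daily screen time category (<1, 2, 3, 4, >=5 h)"),
    c("single_parent", "0/1", "single-parent household"),
    c("siblings", "ordinal 1-3", "number of siblings (1, 2, >=3)"),
    c("disease", "0/1", "physician-diagnosed cardiometabolic/renal disease"),
    c("energy_kcal", "kcal/day", "total energy intake"),
    c("protein_e", "%E", "protein energy share"),
    c("fat_e", "%E", "fat energy share"),
    c("carb_e", "%E", "carbohydrate energy share"),
    c("sodium_mg", "mg/1000 kcal", "sodium density"),
    c("fa_total_e", "%E", "sum of the four fatty-acid classes"),
    c("sfa_e", "%E", "saturated fatty acids"),
    c("mufa_e", "%E", "monounsaturated fatty acids"),
    c("n6_e", "%E", "omega-6 polyunsaturated fatty acids"),
    c("n3_e", "%E", "omega-3 polyunsaturated fatty acids"),
    c("sfa", "% of fatty acids", "closed SFA share"),
    c("mufa", "% of fatty acids", "closed MUFA share"),
    c("n6", "% of fatty acids", "closed omega-6 share"),
    c("n3", "% of fatty acids", "closed omega-3 share"),
    c("height", "cm", "standing height"),
    c("weight", "kg", "body weight"),
    c("zbmi", "z-score", "BMI standardized to an external growth reference"),
    c("ldl", "mg/dL", "LDL cholesterol"),
    c("hdl", "mg/dL", "HDL cholesterol"),
    c("sbp", "mmHg", "systolic blood pressure"),
    c("dbp", "mmHg", "diastolic blood pressure"),
    c("ast", "IU/L", "aspartate transaminase"),
    c("alt", "IU/L", "alanine transaminase"),
    c("ggt", "IU/L", "gamma-glutamyl transpeptidase"))
  data.frame(name = d[, 1], units = d[, 2], description = d[, 3],
             stringsAsFactors = FALSE)
}
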