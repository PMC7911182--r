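#' Run the full analysis pipeline
#'
#' Drives the end-to-end analysis: obtain a cohort (generate synthetically or
#' ingest a supplied table), apply the exclusion rules, compute descriptive
#' summaries (characteristics table, compositional geometric means, variation
#' matrix, quintile clr bar data), fit the compositional regressions and the
#' isocaloric substitution models for every outcome, and assemble the
#' reallocation change matrices from the package's own fits. Deterministic
#' given the generator seed.
#'
#' @param config A [cohort_config()] (generate mode); ignored when `data` is
#'   supplied.
#' @param data Optional cohort data frame (ingest mode).
#' @param filter_cfg A [filter_config()].
#' @param delta Reallocation amount for the change matrices (percentage
#'   points).
#' @param outcomes Outcome columns to model (default all ten standard ones).
#' @param out_dir Optional directory; when given, every table is written as
#'   CSV and the run manifest as JSON.
#' @return List of class `facoda_report`: `manifest` (seed, config hash, row
#'   counts per stage, package version, wall time), `summary`,
#'   `geometric_mean`, `variation`, `quintile_bars` (per outcome),
#'   `coda_fits`, `coda_table` (tidy outcome x rotation), `substitution`,
#'   `change_matrices`, `exclusions`.
#' @export
run_pipeline <- function(config = cohort_config(), data = NULL,
                         filter_cfg = filter_config(), delta = 4,
                         outcomes = reference_estimates()$outcomes$name,
                         out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- "ingest"
  fail <- function(stage, e) stop(sprintf("pipeline failed at stage '%s': %s",
                                          stage, conditionMessage(e)), call. = FALSE)
  tab <- tryCatch({
    if (is.null(data)) {
      stage <- "generate"
      generate_cohort(config)
    } else as.data.frame(data)
  }, error = function(e) fail(stage, e))
  n_raw <- nrow(tab)

  excl <- tryCatch(apply_exclusions(tab, filter_cfg),
                   error = function(e) fail("filter", e))
  dat <- excl$data
  if (nrow(dat) == 0L)
    stop("pipeline failed at stage 'filter': no subjects retained after exclusions",
         call. = FALSE)

  res <- tryCatch({
    parts <- c("sfa", "mufa", "n6", "n3")
    list(summary = summary_table(dat),
         geometric_mean = comp_geometric_mean(dat[, parts]),
         variation = variation_matrix(dat[, parts]),
         quintile_bars = lapply(stats::setNames(outcomes, outcomes),
                                function(oc) quintile_clr_bars(dat, oc, parts)))
  }, error = function(e) fail("descriptives", e))

  coda_fits <- tryCatch(
    lapply(stats::setNames(outcomes, outcomes),
           function(oc) fit_compositional(dat, oc)),
    error = function(e) fail("coda_regression", e))
  coda_table <- do.call(rbind, lapply(coda_fits, function(f)
    cbind(outcome = f$outcome, log_outcome = f$log_outcome,
          r_squared = f$r_squared, f_p = f$f_p, n = f$n, f$rotations)))
  rownames(coda_table) <- NULL

  subs <- tryCatch(substitution_table(dat, outcomes),
                   error = function(e) fail("substitution", e))

  cms <- tryCatch(
    lapply(coda_fits, function(f)
      change_matrix_from_fit(f, xbar = res$geometric_mean, delta = delta)),
    error = function(e) fail("change_matrix", e))

  manifest <- list(
    package_version = as.character(utils::packageVersion("facoda")),
    mode = if (is.null(data)) "generate" else "ingest",
    seed = if (is.null(data)) config$seed else NA_integer_,
    config_hash = config_hash(if (is.null(data)) config else list(ingest = TRUE)),
    delta = delta,
    rows = list(input = n_raw, retained = nrow(dat)),
    exclusion_tally = as.list(excl$tally),
    wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))

  report <- structure(list(
    manifest = manifest, summary = res$summary,
    geometric_mean = res$geometric_mean, variation = res$variation,
    quintile_bars = res$quintile_bars, coda_fits = coda_fits,
    coda_table = coda_table, substitution = subs, change_matrices = cms,
    exclusions = excl$tally), class = "facoda_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# stable fingerprint of the configuration (content-based, no serialization
# of environments)
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, digits.d = 15)), collapse = "\n")
  # small polynomial rolling hash over the printed config
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.facoda_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("facoda report (%s mode, seed %s): %d -> %d subjects\n",
              m$mode, m$seed, m$rows[["input"]], m$rows[["retained"]]))
  cat("Compositional geometric means (%):\n")
  print(round(x$geometric_mean, 1))
  cat("Outcomes modelled:", paste(names(x$coda_fits), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits each table of a [run_pipeline()] report as CSV plus the run manifest
#' and exclusion tally as JSON.
#'
#' @param report A `facoda_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "facoda_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(obj, name, rownames = FALSE) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = rownames)
    files <<- c(files, p)
  }
  wr(report$summary, "summary.csv")
  wr(data.frame(part = names(report$geometric_mean),
                geometric_mean = unname(report$geometric_mean)),
     "geometric_means.csv")
  wr(as.data.frame(report$variation), "variation_matrix.csv", rownames = TRUE)
  wr(report$coda_table, "coda_regression.csv")
  wr(report$substitution, "substitution_models.csv")
  for (oc in names(report$change_matrices))
    wr(as.data.frame(unclass(report$change_matrices[[oc]])),
       sprintf("change_matrix_%s.csv", oc), rownames = TRUE)
  bars <- do.call(rbind, lapply(names(report$quintile_bars), function(oc) {
    b <- report$quintile_bars[[oc]]
    data.frame(outcome = oc, quintile = rep(rownames(b), ncol(b)),
               part = rep(colnames(b), each = nrow(b)), clr = as.vector(b))
  }))
  wr(bars, "quintile_clr_bars.csv")
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(report$manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mpath))
}
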