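#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: either a cohort table on
#' disk or a simulation config (exactly one of the two), the VDT
#' method(s) to report, the fast/slow cut-off, the output directory and
#' the seed.
#'
#' @param input_path Path to a cohort CSV ([read_cohort()] schema), or
#'   `NULL` to simulate.
#' @param sim_config A [cohort_config()], or `NULL` when reading a
#'   file.
#' @param method `"both"` (default), `"diameter"` or `"volume"`.
#' @param cutoff_days Fast/slow VDT cut-off in days.
#' @param output_dir Directory for run artifacts (created if needed).
#' @param seed Integer seed; overrides the simulation config's seed so
#'   one flag controls the whole run.
#' @param verbosity 0 = quiet, 1 = progress messages to stderr.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_path = NULL, sim_config = NULL,
                            method = c("both", "diameter", "volume"),
                            cutoff_days = 60, output_dir = tempfile("run"),
                            seed = 1L, verbosity = 1L) {
  method <- match.arg(method)
  if (is.null(input_path) == is.null(sim_config)) {
    stop("pipeline_config: provide exactly one of input_path / sim_config",
         call. = FALSE)
  }
  if (!is.finite(cutoff_days) || cutoff_days <= 0) {
    stop("pipeline_config: cutoff_days must be > 0", call. = FALSE)
  }
  structure(list(input_path = input_path, sim_config = sim_config,
                 method = method, cutoff_days = cutoff_days,
                 output_dir = output_dir, seed = as.integer(seed),
                 verbosity = verbosity),
            class = "pipeline_config")
}

#' Run the full growth-history analysis pipeline
#'
#' simulate (or read) -> per-patient kinetics -> growth-curve fits ->
#' cohort summary, covariate screen, univariate speed analysis and
#' de-novo lesion report, all written as delimited text into the output
#' directory together with a JSON run manifest (config echo, package
#' version, seed, warnings). Runs are deterministic given the seed;
#' re-running a config reproduces every machine-readable output
#' byte-for-byte.
#'
#' Output files: `cohort.csv` (+ `cohort_truth.csv` when simulated),
#' `results.csv`, `fits.csv`, `curves.csv`, `summary.json`,
#' `summary.txt`, `covariate_screen.csv`, `univariate.csv`,
#' `de_novo.csv`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts (`cohort`,
#'   `results`, `fits`, `summary`, ...) and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) {
    if (config$verbosity > 0) message("[sclcgrowth] ", sprintf(...))
  }
  warnings_log <- character(0)
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  if (!is.null(config$sim_config)) {
    sim <- config$sim_config
    sim$seed <- config$seed
    say("simulating cohort: %d patients (seed %d)", sim$n_patients,
        config$seed)
    cohort <- simulate_cohort(sim)
  } else {
    say("reading cohort from %s", config$input_path)
    cohort <- read_cohort(config$input_path)
  }
  scans <- cohort$scans
  if (config$method %in% c("diameter", "both") &&
      !all(c("max_diam_xy", "perp_diam_xy", "max_diam_z") %in% names(scans)) &&
      config$method == "diameter") {
    stop("run_pipeline: method 'diameter' needs columns max_diam_xy, ",
         "perp_diam_xy, max_diam_z", call. = FALSE)
  }
  if (config$method %in% c("volume", "both") &&
      !"voxel_volume" %in% names(scans) && config$method == "volume") {
    stop("run_pipeline: method 'volume' needs column voxel_volume",
         call. = FALSE)
  }
  write_cohort(cohort, file.path(config$output_dir, "cohort.csv"))

  say("computing per-patient kinetics")
  results <- compute_kinetics(cohort, cutoff_days = config$cutoff_days)
  if (config$method == "diameter") {
    results$vdt_roi <- results$gr_roi <- NA_real_
  } else if (config$method == "volume") {
    results$vdt_manual <- results$gr_manual <- NA_real_
    pos <- is.finite(results$vdt_roi) & results$vdt_roi > 0
    results$speed_class <- NA_character_
    results$speed_class[pos] <- classify_speed(results$vdt_roi[pos],
                                               config$cutoff_days)
  }
  for (f in results$flags[nzchar(results$flags)]) note(f)
  excluded <- results[!is.finite(results$vdt_manual) &
                        !is.finite(results$vdt_roi), "patient_id"]
  included <- results[!results$patient_id %in% excluded, , drop = FALSE]
  write_results_csv(included, file.path(config$output_dir, "results.csv"))
  exclusions <- data.frame(
    patient_id = excluded,
    reason = rep("no method computable (fewer than 2 usable scans)",
                 length(excluded)))
  utils::write.csv(exclusions, file.path(config$output_dir, "exclusions.csv"),
                   row.names = FALSE, quote = FALSE)

  say("fitting growth curves (patients with >= 3 volume scans)")
  fits <- fit_cohort_curves(cohort)
  utils::write.csv(fits, file.path(config$output_dir, "fits.csv"),
                   row.names = FALSE, quote = FALSE)
  curves <- growth_curve_data(cohort)
  utils::write.csv(curves, file.path(config$output_dir, "curves.csv"),
                   row.names = FALSE, quote = FALSE)
  for (f in fits$flags[nzchar(fits$flags)]) note(f)

  say("cohort statistics")
  summ <- summarize_cohort(included, cutoff_days = config$cutoff_days)
  screen <- covariate_screen(included)
  uni <- tryCatch(univariate_speed_analysis(included),
                  error = function(e) { note(conditionMessage(e)); NULL })
  utils::write.csv(screen,
                   file.path(config$output_dir, "covariate_screen.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(uni)) {
    utils::write.csv(uni, file.path(config$output_dir, "univariate.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  denovo <- de_novo_report(cohort)
  dn <- denovo
  dn$last_negative_date <- format(dn$last_negative_date)
  dn$first_positive_date <- format(dn$first_positive_date)
  utils::write.csv(dn, file.path(config$output_dir, "de_novo.csv"),
                   row.names = FALSE, quote = FALSE)

  summary_list <- list(
    n_patients = summ$n_patients,
    median_vdt_manual = null_na(summ$manual$median_vdt),
    iqr_vdt_manual = if (is.null(summ$manual)) NULL else summ$manual$iqr_vdt,
    median_vdt_roi = null_na(summ$roi$median_vdt),
    iqr_vdt_roi = if (is.null(summ$roi)) NULL else summ$roi$iqr_vdt,
    gr_mean_manual = null_na(summ$manual$gr_mean),
    gr_sd_manual = null_na(summ$manual$gr_sd),
    gr_mean_roi = null_na(summ$roi$gr_mean),
    gr_sd_roi = null_na(summ$roi$gr_sd),
    icc_vdt = summ$agreement_vdt, icc_gr = summ$agreement_gr,
    cutoff_days = summ$cutoff_days,
    n_fast = summ$speed_counts[["n_fast"]],
    n_slow = summ$speed_counts[["n_slow"]])
  jsonlite::write_json(summary_list,
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(summ))
  writeLines(txt, file.path(config$output_dir, "summary.txt"))

  manifest <- list(
    package = "sclcgrowth",
    version = as.character(utils::packageVersion("sclcgrowth")),
    seed = config$seed,
    method = config$method,
    cutoff_days = config$cutoff_days,
    input = if (is.null(config$input_path)) "simulated" else config$input_path,
    sim_config = if (is.null(config$sim_config)) NULL else {
      sc <- config$sim_config
      sc$seed <- config$seed
      unclass(sc)
    },
    n_patients = nrow(results),
    n_excluded = length(excluded),
    warnings = sort(unique(warnings_log)))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; artifacts in %s", config$output_dir)
  invisible(list(cohort = cohort, results = included, exclusions = exclusions,
                 fits = fits, curves = curves, summary = summ,
                 covariate_screen = screen, univariate = uni,
                 de_novo = denovo, manifest = manifest,
                 output_dir = config$output_dir))
}

null_na <- function(x) if (is.null(x)) NA_real_ else x

# results table with human-readable rounding (VDT whole days, GR 4 dp);
# full precision lives in the returned objects, not the CSV
write_results_csv <- function(results, path) {
  out <- results
  for (cc in c("vdt_manual", "vdt_roi")) out[[cc]] <- round(out[[cc]])
  for (cc in c("gr_manual", "gr_roi")) out[[cc]] <- round(out[[cc]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
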