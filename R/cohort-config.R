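#' Default covariate frequencies for the simulated cohort
#'
#' Marginal category frequencies of the clinical and imaging covariates
#' carried by each simulated patient, chosen to approximate a small
#' surgical cohort of peripheral small-cell lung cancer (n = 27): mostly
#' male current/former smokers, predominantly intraparenchymal solid
#' nodules, pleural retraction rare.
#'
#' @return Named list mapping covariate name to a named probability
#'   vector over its categories.
#' @export
default_covariate_freqs <- function() {
  list(
    sex = c(male = 25 / 27, female = 2 / 27),
    smoking_history = c(current_or_former = 21 / 27, never = 6 / 27),
    tumour_history = c(yes = 10 / 27, no = 17 / 27),
    family_history = c(yes = 3 / 27, no = 24 / 27),
    lobe_site = c(upper_middle = 15 / 27, lower = 12 / 27),
    shape = c(irregular = 19 / 27, regular = 8 / 27),
    spiculated = c(yes = 3 / 27, no = 24 / 27),
    lobulation = c(yes = 16 / 27, no = 11 / 27),
    pleural_retraction = c(yes = 1 / 27, no = 26 / 27),
    location_pleural_attached = c(yes = 6 / 27, no = 21 / 27),
    emphysema = c(yes = 13 / 27, no = 14 / 27),
    interstitial_pneumonia = c(yes = 4 / 27, no = 23 / 27)
  )
}

#' Configuration for the synthetic serial-CT cohort generator
#'
#' Defines the study conditions the simulator emulates: a lognormal
#' doubling-time distribution (median `vdt_log_median` days, log-scale
#' spread `vdt_log_sigma`), a mix of exponential and Gompertz latent
#' trajectories, 2--4 scans per patient at intervals of at least
#' `min_gap_days` (the cohort inclusion rule), multiplicative lognormal
#' measurement noise on diameters and volumes, and categorical
#' covariates with fixed marginal frequencies.
#'
#' Defaults reflect the observed cohort: median VDT 61 days with
#' log-sigma 0.53 (reproducing an interquartile spread of roughly
#' 51--104 days), scan-count probabilities 19/27, 7/27, 1/27 over
#' {2, 3, 4} scans, 20-day minimum inter-scan gap, 5% diameter and 10%
#' volume coefficients of variation, and a quarter of trajectories
#' Gompertzian.
#'
#' @param n_patients Number of patients (positive integer).
#' @param vdt_log_median Median true doubling time in days.
#' @param vdt_log_sigma Standard deviation of log(VDT) (dimensionless).
#' @param frac_gompertz Fraction of patients with Gompertz trajectories,
#'   in `[0, 1]`.
#' @param scans_per_patient_probs Probability vector over 2, 3 and 4
#'   scans; must sum to 1.
#' @param min_gap_days Minimum days between consecutive scans (>= 20).
#' @param max_gap_days Upper bound of the uniform inter-scan gap draw.
#' @param diameter_cv Fractional coefficient of variation of diameter
#'   noise (>= 0).
#' @param volume_cv Fractional CV of volume noise (>= 0).
#' @param baseline_volume_range Range (mm^3) for the baseline true
#'   volume, drawn log-uniformly.
#' @param carrying_factor_range For Gompertz patients, range of the
#'   carrying-volume-to-baseline ratio (drawn log-uniformly; > 1).
#' @param covariate_freqs Named list of category-frequency vectors; see
#'   [default_covariate_freqs()].
#' @param first_scan_window ISO dates bounding the baseline scan date.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_patients = 27,
                          vdt_log_median = 61,
                          vdt_log_sigma = 0.53,
                          frac_gompertz = 0.25,
                          scans_per_patient_probs = c(19, 7, 1) / 27,
                          min_gap_days = 20,
                          max_gap_days = 180,
                          diameter_cv = 0.05,
                          volume_cv = 0.10,
                          baseline_volume_range = c(200, 6000),
                          carrying_factor_range = c(10, 50),
                          covariate_freqs = default_covariate_freqs(),
                          first_scan_window = c("2015-01-01", "2022-06-30"),
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients),
         vdt_log_median = vdt_log_median,
         vdt_log_sigma = vdt_log_sigma,
         frac_gompertz = frac_gompertz,
         scans_per_patient_probs = scans_per_patient_probs,
         min_gap_days = as.integer(min_gap_days),
         max_gap_days = as.integer(max_gap_days),
         diameter_cv = diameter_cv,
         volume_cv = volume_cv,
         baseline_volume_range = baseline_volume_range,
         carrying_factor_range = carrying_factor_range,
         covariate_freqs = covariate_freqs,
         first_scan_window = first_scan_window,
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    fail("n_patients", "must be a positive integer")
  }
  if (!is.finite(cfg$vdt_log_median) || cfg$vdt_log_median <= 0) {
    fail("vdt_log_median", "must be > 0 days")
  }
  if (!is.finite(cfg$vdt_log_sigma) || cfg$vdt_log_sigma < 0) {
    fail("vdt_log_sigma", "must be >= 0")
  }
  if (cfg$frac_gompertz < 0 || cfg$frac_gompertz > 1) {
    fail("frac_gompertz", "must lie in [0, 1]")
  }
  p <- cfg$scans_per_patient_probs
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    fail("scans_per_patient_probs",
         "must be 3 non-negative probabilities over {2,3,4} summing to 1")
  }
  if (is.na(cfg$min_gap_days) || cfg$min_gap_days < 20L) {
    fail("min_gap_days", "must be >= 20 (cohort inclusion rule)")
  }
  if (cfg$max_gap_days < cfg$min_gap_days) {
    fail("max_gap_days", "must be >= min_gap_days")
  }
  if (cfg$diameter_cv < 0) fail("diameter_cv", "must be >= 0")
  if (cfg$volume_cv < 0) fail("volume_cv", "must be >= 0")
  bv <- cfg$baseline_volume_range
  if (length(bv) != 2L || any(bv <= 0) || bv[2L] < bv[1L]) {
    fail("baseline_volume_range", "must be a positive increasing interval")
  }
  cf <- cfg$carrying_factor_range
  if (length(cf) != 2L || any(cf <= 1) || cf[2L] < cf[1L]) {
    fail("carrying_factor_range", "must be an increasing interval with values > 1")
  }
  for (nm in names(cfg$covariate_freqs)) {
    q <- cfg$covariate_freqs[[nm]]
    if (any(q < 0) || abs(sum(q) - 1) > 1e-9 || is.null(names(q))) {
      fail(paste0("covariate_freqs$", nm),
           "must be a named probability vector summing to 1")
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic serial-CT cohort config: %d patients, median VDT %g d (log-sd %g),\n",
    x$n_patients, x$vdt_log_median, x$vdt_log_sigma))
  cat(sprintf(
    "  %.0f%% Gompertz trajectories, gaps %d-%d d, CV diam %.2f / vol %.2f, seed %d\n",
    100 * x$frac_gompertz, x$min_gap_days, x$max_gap_days,
    x$diameter_cv, x$volume_cv, x$seed))
  invisible(x)
}
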