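#' Latent tumour growth trajectory
#'
#' Ground-truth volume law for a simulated patient. Two functional forms
#' are supported: pure exponential growth `v0 * exp(k * t)` and the
#' Gompertz law
#' \deqn{V(t) = V_\infty \exp\{\ln(V_0 / V_\infty)\, e^{-k t}\},}
#' which starts at `v0`, grows with initial specific rate
#' `k * ln(carrying_volume / v0)`, and plateaus at the carrying volume.
#'
#' @param model `"exponential"` or `"gompertz"`.
#' @param v0 Baseline volume in mm^3 (> 0).
#' @param k Per-day rate: the exponential growth rate, or the Gompertz
#'   decay rate of the specific growth rate (> 0).
#' @param carrying_volume Plateau volume in mm^3 (Gompertz only; must
#'   exceed `v0`).
#' @return An object of class `latent_trajectory`.
#' @export
latent_trajectory <- function(model = c("exponential", "gompertz"),
                              v0, k, carrying_volume = NA_real_) {
  model <- match.arg(model)
  if (!is.finite(v0) || v0 <= 0) {
    stop("latent_trajectory: v0 must be > 0", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) {
    stop("latent_trajectory: k must be > 0", call. = FALSE)
  }
  if (model == "gompertz" &&
      (!is.finite(carrying_volume) || carrying_volume <= v0)) {
    stop("latent_trajectory: carrying_volume must exceed v0 for Gompertz",
         call. = FALSE)
  }
  structure(list(model = model, v0 = v0, k = k,
                 carrying_volume = carrying_volume),
            class = "latent_trajectory")
}

#' True (noise-free) volume of a latent trajectory
#'
#' @param traj A [latent_trajectory()].
#' @param t Time in days since baseline (vectorised, `t >= 0`).
#' @return Volume(s) in mm^3; strictly increasing in `t`.
#' @export
true_volume <- function(traj, t) {
  stopifnot(inherits(traj, "latent_trajectory"))
  if (any(t < 0)) stop("true_volume: t must be >= 0", call. = FALSE)
  switch(traj$model,
    exponential = traj$v0 * exp(traj$k * t),
    gompertz = traj$carrying_volume *
      exp(log(traj$v0 / traj$carrying_volume) * exp(-traj$k * t)))
}

# lognormal multiplicative noise with unit mean and given fractional CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sample_category <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Simulate a synthetic serial-CT cohort
#'
#' Generates `n_patients` patients, each with a latent exponential or
#' Gompertz growth trajectory, a scan schedule honouring the minimum
#' inter-scan gap, noisy three-diameter calliper measurements, noisy
#' segmentation volumes, and categorical covariates. The latent truth is
#' returned alongside the observations so estimator accuracy can be
#' scored exactly.
#'
#' The measurement model ties diameters to volume through the ellipsoid
#' relation `V = pi/6 * X * Y * Z`: per-patient shape factors fix the
#' axis ratios, the true volume fixes the scale, and independent
#' multiplicative lognormal noise (unit mean, configured CV) perturbs
#' each axis and the volume. If noise swaps the in-plane axes the larger
#' is relabelled as the maximal diameter, as a human measurer would; the
#' product, and hence every doubling-time ratio, is unaffected.
#'
#' All randomness flows from `config$seed` through R's default
#' generator; identical configs give byte-identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param n_de_novo Number of patients (taken from the start of the
#'   cohort) given an extra lesion-free scan before their baseline, to
#'   emulate nodules first appearing during follow-up.
#' @return An object of class `sclc_cohort`: a list with `$scans` (one
#'   row per scan: id, date, diameters, volume, covariates) and `$truth`
#'   (one row per patient: model, v0, k, carrying_volume, true_vdt).
#' @export
simulate_cohort <- function(config = cohort_config(), n_de_novo = 0L) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  # latent kinetics: lognormal true VDT; Bernoulli Gompertz assignment
  true_vdt <- stats::rlnorm(n, meanlog = log(config$vdt_log_median),
                            sdlog = config$vdt_log_sigma)
  is_gomp <- stats::runif(n) < config$frac_gompertz
  v0 <- exp(stats::runif(n, log(config$baseline_volume_range[1L]),
                         log(config$baseline_volume_range[2L])))
  carry_factor <- exp(stats::runif(n, log(config$carrying_factor_range[1L]),
                                   log(config$carrying_factor_range[2L])))
  carrying <- ifelse(is_gomp, v0 * carry_factor, NA_real_)
  # match the *initial* doubling time to true_vdt in both models
  k <- ifelse(is_gomp,
              log(2) / (true_vdt * log(carry_factor)),
              log(2) / true_vdt)

  # per-patient shape: in-plane perpendicular and z-axis ratios
  shape_y <- stats::runif(n, 0.70, 1.00)
  shape_z <- stats::runif(n, 0.70, 1.10)

  n_scans <- sample(2:4, n, replace = TRUE,
                    prob = config$scans_per_patient_probs)
  window <- as.Date(config$first_scan_window)
  baseline <- window[1L] +
    floor(stats::runif(n) * (as.numeric(window[2L] - window[1L]) + 1))

  covs <- lapply(config$covariate_freqs, function(f) sample_category(n, f))
  # smoking index (pack-years x 100 style): lognormal for smokers, 0 never
  smoking_index <- round(stats::rlnorm(n, log(600), 0.9))
  if (!is.null(covs$smoking_history)) {
    smoking_index[covs$smoking_history == "never"] <- 0
  }

  scan_rows <- vector("list", n)
  for (i in seq_len(n)) {
    traj <- latent_trajectory(
      model = if (is_gomp[i]) "gompertz" else "exponential",
      v0 = v0[i], k = k[i], carrying_volume = carrying[i])
    gaps <- floor(stats::runif(n_scans[i] - 1L, config$min_gap_days,
                               config$max_gap_days + 1))
    t_days <- c(0, cumsum(gaps))
    vol_true <- true_volume(traj, t_days)
    # ellipsoid axes consistent with the true volume
    dx <- (6 * vol_true / (pi * shape_y[i] * shape_z[i]))^(1 / 3)
    dy <- shape_y[i] * dx
    dz <- shape_z[i] * dx
    m <- length(t_days)
    dx_obs <- dx * rlnorm_cv(m, config$diameter_cv)
    dy_obs <- dy * rlnorm_cv(m, config$diameter_cv)
    dz_obs <- dz * rlnorm_cv(m, config$diameter_cv)
    vol_obs <- vol_true * rlnorm_cv(m, config$volume_cv)
    max_xy <- pmax(dx_obs, dy_obs)   # measurer labels the larger axis maximal
    perp_xy <- pmin(dx_obs, dy_obs)
    scan_rows[[i]] <- data.frame(
      patient_id = ids[i],
      scan_date = baseline[i] + t_days,
      max_diam_xy = max_xy,
      perp_diam_xy = perp_xy,
      max_diam_z = dz_obs,
      voxel_volume = vol_obs,
      stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, scan_rows)
  cov_df <- data.frame(sex = covs$sex, smoking_history = covs$smoking_history,
                       smoking_index = smoking_index,
                       stringsAsFactors = FALSE)
  for (nm in setdiff(names(covs), c("sex", "smoking_history"))) {
    cov_df[[nm]] <- covs[[nm]]
  }
  cov_df$patient_id <- ids
  scans <- merge(scans, cov_df, by = "patient_id", sort = FALSE)
  scans <- scans[order(scans$patient_id, scans$scan_date), , drop = FALSE]
  rownames(scans) <- NULL

  if (n_de_novo > 0L) {
    n_de_novo <- min(as.integer(n_de_novo), n)
    pre_gap <- floor(stats::runif(n_de_novo, config$min_gap_days,
                                  config$max_gap_days + 1))
    for (j in seq_len(n_de_novo)) {
      first <- scans[scans$patient_id == ids[j], ][1L, ]
      first$scan_date <- first$scan_date - pre_gap[j]
      first[c("max_diam_xy", "perp_diam_xy", "max_diam_z",
              "voxel_volume")] <- NA_real_
      scans <- rbind(first, scans)
    }
    scans <- scans[order(scans$patient_id, scans$scan_date), , drop = FALSE]
    rownames(scans) <- NULL
  }

  truth <- data.frame(
    patient_id = ids,
    model = ifelse(is_gomp, "gompertz", "exponential"),
    v0 = v0, k = k, carrying_volume = carrying,
    true_vdt = true_vdt,
    stringsAsFactors = FALSE)

  structure(list(scans = scans, truth = truth, config = config),
            class = "sclc_cohort")
}

#' @export
print.sclc_cohort <- function(x, ...) {
  cat(sprintf("Synthetic serial-CT cohort: %d patients, %d scans (%s)\n",
              nrow(x$truth), nrow(x$scans),
              paste(names(table(x$truth$model)),
                    table(x$truth$model), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Extract one patient's series from a cohort
#'
#' @param cohort An `sclc_cohort` or per-scan data.frame.
#' @param patient_id Patient identifier.
#' @return An object of class `patient_series` with `$patient_id`,
#'   `$scans` (date-ordered) and `$covariates`.
#' @export
patient_series <- function(cohort, patient_id) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  s <- scans[scans$patient_id == patient_id, , drop = FALSE]
  if (!nrow(s)) stop("patient_series: unknown patient_id", call. = FALSE)
  s$scan_date <- parse_scan_date(s$scan_date)
  s <- s[order(s$scan_date), , drop = FALSE]
  if (anyDuplicated(s$scan_date)) {
    stop("patient_series: duplicate scan dates", call. = FALSE)
  }
  cov_cols <- setdiff(names(s), c("patient_id", "scan_date", "max_diam_xy",
                                  "perp_diam_xy", "max_diam_z", "voxel_volume"))
  structure(list(patient_id = patient_id,
                 scans = s[, setdiff(names(s), cov_cols), drop = FALSE],
                 covariates = as.list(s[1L, cov_cols, drop = FALSE])),
            class = "patient_series")
}
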