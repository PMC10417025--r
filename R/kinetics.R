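#' Calendar interval between two scan dates
#'
#' Exact Gregorian calendar-day difference between two scans, the `t`
#' (or delta-T) entering every doubling-time formula.
#'
#' @param d1,d2 Scan dates (`Date`, or strings accepted by
#'   [parse_scan_date()]). `d2` must fall strictly after `d1`.
#' @return Integer number of days.
#' @examples
#' interval_days("2017-11-08", "2018-03-26")  # 138
#' interval_days("8 November 2017", "26 March 2018")
#' @export
interval_days <- function(d1, d2) {
  d1 <- parse_scan_date(d1)
  d2 <- parse_scan_date(d2)
  if (any(is.na(d1)) || any(is.na(d2))) {
    stop("interval_days: unparseable date", call. = FALSE)
  }
  if (any(d2 <= d1)) {
    stop("interval_days: second date must be after the first", call. = FALSE)
  }
  as.integer(round(as.numeric(difftime(d2, d1, units = "days"))))
}

#' Parse a scan date
#'
#' Accepts ISO-8601 (`"2018-03-26"`) as the machine interface and the
#' lenient `"26 March 2018"` form used in clinical tables. English month
#' names are matched case-insensitively regardless of locale.
#'
#' @param x Character vector or `Date`.
#' @return A `Date` vector; unparseable entries become `NA`.
#' @export
parse_scan_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  txt <- !iso & grepl("^\\d{1,2}\\s+[A-Za-z]+\\s+\\d{4}$", x)
  if (any(txt)) {
    months <- c("january", "february", "march", "april", "may", "june",
                "july", "august", "september", "october", "november",
                "december")
    parts <- strsplit(x[txt], "\\s+")
    out[txt] <- as.Date(vapply(parts, function(p) {
      m <- match(tolower(p[2]), months)
      if (is.na(m)) return(NA_character_)
      sprintf("%s-%02d-%02d", p[3], m, as.integer(p[1]))
    }, character(1)), format = "%Y-%m-%d")
  }
  out
}

new_vdt_result <- function(method, vdt, delta_t,
                           first_scan_date = NA, last_scan_date = NA,
                           flags = character(0)) {
  structure(
    list(method = method,
         vdt = vdt,
         gr = 1 / vdt,
         delta_t = delta_t,
         first_scan_date = first_scan_date,
         last_scan_date = last_scan_date,
         flags = flags),
    class = "vdt_result")
}

#' @export
print.vdt_result <- function(x, ...) {
  cat(sprintf("VDT (%s method): %.1f days  [GR = %s /day, over %d days]\n",
              x$method, x$vdt, format(round(x$gr, 4)), x$delta_t))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Volume-doubling time from three orthogonal diameters
#'
#' Calliper ("manual") method: the nodule volume is taken proportional to
#' the product of the maximal axial diameter, its in-plane perpendicular,
#' and the cranio-caudal diameter, so
#' \deqn{VDT = \frac{\ln 2 \cdot \Delta T}{\ln\left(\frac{X_2 Y_2 Z_2}{X_1 Y_1 Z_1}\right)}.}
#' The ellipsoid constant pi/6 cancels in the ratio.
#'
#' A shrinking nodule yields a negative VDT, which is returned with a
#' `"negative_vdt"` flag rather than raising: observational cohorts of
#' untreated cancers should contain none, but synthetic or edge inputs
#' must not crash the pipeline.
#'
#' @param s1,s2 Scan records: lists or one-row data.frames with fields
#'   `max_diam_xy`, `perp_diam_xy`, `max_diam_z` (mm).
#' @param delta_t Days between the scans (>= 1).
#' @return A `vdt_result` (method `"diameter"`).
#' @seealso [vdt_volume()], [series_vdt()]
#' @export
vdt_diameter <- function(s1, s2, delta_t) {
  need <- c("max_diam_xy", "perp_diam_xy", "max_diam_z")
  g1 <- unlist(s1[need])
  g2 <- unlist(s2[need])
  if (length(g1) < 3L || length(g2) < 3L || anyNA(g1) || anyNA(g2)) {
    stop("vdt_diameter: all three diameters must be present on both scans",
         call. = FALSE)
  }
  if (any(g1 <= 0) || any(g2 <= 0)) {
    stop("vdt_diameter: diameters must be positive", call. = FALSE)
  }
  if (delta_t < 1) stop("vdt_diameter: delta_t must be >= 1 day", call. = FALSE)
  lr <- sum(log(g2)) - sum(log(g1))  # log of the diameter-product ratio
  if (lr == 0) {
    stop("vdt_diameter: no measurable growth (equal diameter products)",
         call. = FALSE)
  }
  vdt <- log(2) * delta_t / lr
  flags <- if (vdt < 0) "negative_vdt" else character(0)
  new_vdt_result("diameter", vdt, delta_t, flags = flags)
}

#' Volume-doubling time by the modified Schwartz equation
#'
#' Segmentation-volume ("ROI") method:
#' \deqn{VDT = t \cdot \log 2 / \log(V_2 / V_1)}
#' for voxel volumes \eqn{V_1, V_2} (mm^3) separated by `t` days. The
#' logarithm base is irrelevant since only the ratio of logs enters.
#'
#' @param v1,v2 Voxel volumes in mm^3 (positive, `v1 != v2`).
#' @param t Days between the scans (>= 1).
#' @return A `vdt_result` (method `"volume"`).
#' @examples
#' vdt_volume(630.5, 3895.75, interval_days("2021-02-20", "2021-08-26"))
#' @export
vdt_volume <- function(v1, v2, t) {
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) {
    stop("vdt_volume: volumes must be positive and finite", call. = FALSE)
  }
  if (t < 1) stop("vdt_volume: t must be >= 1 day", call. = FALSE)
  if (v1 == v2) {
    stop("vdt_volume: no measurable growth (equal volumes)", call. = FALSE)
  }
  vdt <- t * log(2) / log(v2 / v1)
  flags <- if (vdt < 0) "negative_vdt" else character(0)
  new_vdt_result("volume", vdt, t, flags = flags)
}

#' Growth rate as the reciprocal of VDT
#'
#' GR = 1/VDT, in doublings per day. Human-readable outputs round GR to
#' 4 decimals (e.g. VDT 119 days -> 0.0084/day); full precision is kept
#' internally.
#'
#' @param vdt Doubling time in days (non-zero).
#' @param digits Rounding applied to the returned value; `NULL` for full
#'   precision.
#' @return Growth rate in 1/days.
#' @export
growth_rate <- function(vdt, digits = NULL) {
  if (any(!is.finite(vdt)) || any(vdt == 0)) {
    stop("growth_rate: vdt must be finite and non-zero", call. = FALSE)
  }
  gr <- 1 / vdt
  if (!is.null(digits)) gr <- round(gr, digits) else gr
}

#' Series-level VDT from the first and last scans
#'
#' For a patient with three or more scans, the doubling-time formula is
#' applied to the first and last scans only; intermediate scans inform
#' the growth-curve fit ([fit_exponential()], [fit_gompertz()]) but not
#' the headline VDT. With two scans this reduces to the pairwise
#' computation.
#'
#' @param series A `patient_series` or a data.frame of scans for one
#'   patient with columns `scan_date` and, depending on `method`,
#'   `max_diam_xy`/`perp_diam_xy`/`max_diam_z` or `voxel_volume`.
#' @param method `"diameter"` or `"volume"`.
#' @return A `vdt_result` carrying the first/last scan dates used.
#' @export
series_vdt <- function(series, method = c("diameter", "volume")) {
  method <- match.arg(method)
  scans <- if (inherits(series, "patient_series")) series$scans else series
  scans <- as.data.frame(scans)
  if (!"scan_date" %in% names(scans)) {
    stop("series_vdt: scans need a scan_date column", call. = FALSE)
  }
  scans$scan_date <- parse_scan_date(scans$scan_date)
  scans <- scans[order(scans$scan_date), , drop = FALSE]
  usable <- if (method == "diameter") {
    stats::complete.cases(scans[, c("max_diam_xy", "perp_diam_xy", "max_diam_z")]) &
      scans$max_diam_xy > 0
  } else {
    !is.na(scans$voxel_volume) & scans$voxel_volume > 0
  }
  scans <- scans[usable, , drop = FALSE]
  if (nrow(scans) < 2L) {
    stop(sprintf("series_vdt: fewer than 2 usable scans for the %s method",
                 method), call. = FALSE)
  }
  first <- scans[1L, ]
  last <- scans[nrow(scans), ]
  dt <- interval_days(first$scan_date, last$scan_date)
  res <- if (method == "diameter") {
    vdt_diameter(first, last, dt)
  } else {
    vdt_volume(first$voxel_volume, last$voxel_volume, dt)
  }
  res$first_scan_date <- first$scan_date
  res$last_scan_date <- last$scan_date
  res
}

#' Classify growth speed against a VDT cut-off
#'
#' Patients are split into fast- and slow-growing groups at a doubling
#' time cut-off (default 60 days). The boundary itself is classified
#' slow: `vdt >= cutoff` is `"slow"`, `vdt < cutoff` is `"fast"`.
#'
#' @param vdt Doubling time(s) in days, positive.
#' @param cutoff Cut-off in days (default 60).
#' @return Character vector, `"fast"` or `"slow"`.
#' @export
classify_speed <- function(vdt, cutoff = 60) {
  if (any(!is.finite(vdt)) || any(vdt <= 0)) {
    stop("classify_speed: vdt must be positive and finite", call. = FALSE)
  }
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("classify_speed: cutoff must be positive", call. = FALSE)
  }
  ifelse(vdt < cutoff, "fast", "slow")
}

#' Report lesions first appearing during follow-up
#'
#' A de-novo lesion is a nodule first visible on a follow-up scan after
#' an earlier lesion-free scan of the same patient. Lesion-free scans
#' are rows whose measurements are all absent or zero. For each such
#' patient the report lists the last lesion-free date, the first
#' lesion-bearing date, the interval in days, and the first measured
#' volume.
#'
#' @param cohort An `sclc_cohort`, or a per-scan data.frame with columns
#'   `patient_id`, `scan_date`, `voxel_volume` (and optionally the three
#'   diameters).
#' @return A data.frame with one row per de-novo lesion (zero rows if
#'   none).
#' @export
de_novo_report <- function(cohort) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  scans <- as.data.frame(scans)
  scans$scan_date <- parse_scan_date(scans$scan_date)
  meas_cols <- intersect(
    c("max_diam_xy", "perp_diam_xy", "max_diam_z", "voxel_volume"),
    names(scans))
  lesion_free <- apply(scans[, meas_cols, drop = FALSE], 1L, function(r) {
    all(is.na(r) | r == 0)
  })
  out <- lapply(split(seq_len(nrow(scans)), scans$patient_id), function(idx) {
    s <- scans[idx, , drop = FALSE]
    free <- lesion_free[idx]
    s <- s[order(s$scan_date), , drop = FALSE]
    free <- free[order(scans$scan_date[idx])]
    pos <- which(!free)
    if (!length(pos) || pos[1L] == 1L) return(NULL)  # never lesion-free first
    first_pos <- pos[1L]
    last_free <- max(which(free[seq_len(first_pos - 1L)]))
    vol <- s$voxel_volume[first_pos]
    data.frame(
      patient_id = s$patient_id[1L],
      last_negative_date = s$scan_date[last_free],
      first_positive_date = s$scan_date[first_pos],
      interval_days = interval_days(s$scan_date[last_free],
                                    s$scan_date[first_pos]),
      first_volume = if (is.null(vol)) NA_real_ else vol,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0),
                      last_negative_date = as.Date(character(0)),
                      first_positive_date = as.Date(character(0)),
                      interval_days = integer(0),
                      first_volume = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-patient kinetics table for a cohort
#'
#' Runs both doubling-time methods patient by patient (first and last
#' usable scans) and assembles the analysis table consumed by
#' [summarize_cohort()] and [univariate_speed_analysis()]. Patients for
#' whom a method cannot be computed get `NA` for that method and a flag;
#' de-novo lesion-free scans are ignored as unusable timepoints.
#'
#' @param cohort An `sclc_cohort` or per-scan data.frame (schema of
#'   [read_cohort()]).
#' @param cutoff_days Fast/slow cut-off in days passed to
#'   [classify_speed()]; the class is taken from the diameter-method VDT
#'   when available, else the volume method.
#' @return A data.frame with one row per patient: `patient_id`,
#'   `vdt_manual`, `vdt_roi`, `gr_manual`, `gr_roi`, `delta_t`,
#'   `n_scans`, `speed_class`, `flags`, plus the patient covariates.
#' @export
compute_kinetics <- function(cohort, cutoff_days = 60) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  scans <- as.data.frame(scans)
  scans$scan_date <- parse_scan_date(scans$scan_date)
  cov_cols <- setdiff(names(scans),
                      c("patient_id", "scan_date", "max_diam_xy",
                        "perp_diam_xy", "max_diam_z", "voxel_volume"))
  rows <- lapply(split(scans, scans$patient_id), function(s) {
    s <- s[order(s$scan_date), , drop = FALSE]
    flags <- character(0)
    vdt_of <- function(method) {
      tryCatch(series_vdt(s, method), error = function(e) NULL)
    }
    rd <- vdt_of("diameter")
    rv <- vdt_of("volume")
    if (is.null(rd)) flags <- c(flags, "diameter_method_unavailable")
    if (is.null(rv)) flags <- c(flags, "volume_method_unavailable")
    for (r in list(rd, rv)) if (!is.null(r)) flags <- c(flags, r$flags)
    primary <- if (!is.null(rd)) rd else rv
    speed <- NA_character_
    if (!is.null(primary) && primary$vdt > 0) {
      speed <- classify_speed(primary$vdt, cutoff_days)
    }
    out <- data.frame(
      patient_id = s$patient_id[1L],
      vdt_manual = if (!is.null(rd)) rd$vdt else NA_real_,
      vdt_roi = if (!is.null(rv)) rv$vdt else NA_real_,
      gr_manual = if (!is.null(rd)) rd$gr else NA_real_,
      gr_roi = if (!is.null(rv)) rv$gr else NA_real_,
      delta_t = if (!is.null(primary)) primary$delta_t else NA_integer_,
      n_scans = nrow(s),
      speed_class = speed,
      flags = paste(unique(flags), collapse = ";"),
      stringsAsFactors = FALSE)
    if (length(cov_cols)) out <- cbind(out, s[1L, cov_cols, drop = FALSE])
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
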