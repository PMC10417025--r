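#' Write a cohort to delimited text
#'
#' The per-scan table is written as CSV (one row per scan, ISO-8601
#' dates, covariates repeated on each row). When the cohort carries
#' ground truth, a sidecar CSV with the same stem and suffix `_truth` is
#' written next to it.
#'
#' @param cohort An `sclc_cohort` or a per-scan data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  scans <- as.data.frame(scans)
  scans$scan_date <- format(parse_scan_date(scans$scan_date), "%Y-%m-%d")
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  if (inherits(cohort, "sclc_cohort") && !is.null(cohort$truth)) {
    utils::write.csv(cohort$truth, truth_path(path),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

truth_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", "_truth\\1", path)
}

#' Read a cohort table
#'
#' Parses and validates the per-scan schema written by [write_cohort()].
#' A series carrying only volumes (no diameters) is usable by the
#' Schwartz-equation method alone and is flagged, not rejected;
#' lesion-free rows (all measurements absent/zero) are allowed and feed
#' [de_novo_report()]. Duplicate (patient, date) rows and nonpositive
#' measurements are rejected with the offending row number.
#'
#' @param path CSV path.
#' @param read_truth Also read the `_truth` sidecar if present.
#' @return An `sclc_cohort` (with `$truth = NULL` when no sidecar).
#' @export
read_cohort <- function(path, read_truth = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("read_cohort: no such file: %s", path), call. = FALSE)
  }
  scans <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "scan_date")
  missing <- setdiff(required, names(scans))
  if (length(missing)) {
    stop(sprintf("read_cohort: missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  diam_cols <- c("max_diam_xy", "perp_diam_xy", "max_diam_z")
  has_diam <- all(diam_cols %in% names(scans))
  has_vol <- "voxel_volume" %in% names(scans)
  if (!has_diam && !has_vol) {
    stop("read_cohort: need the three diameter columns and/or voxel_volume",
         call. = FALSE)
  }
  dates <- parse_scan_date(scans$scan_date)
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop(sprintf("read_cohort: unparseable scan_date at row %d", bad[1L]),
         call. = FALSE)
  }
  scans$scan_date <- dates
  key <- paste(scans$patient_id, format(dates), sep = "|")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("read_cohort: duplicate (patient_id, scan_date) at row %d",
                 dup[1L]), call. = FALSE)
  }
  meas <- intersect(c(diam_cols, "voxel_volume"), names(scans))
  for (cc in meas) {
    neg <- which(!is.na(scans[[cc]]) & scans[[cc]] < 0)
    if (length(neg)) {
      stop(sprintf("read_cohort: negative %s at row %d", cc, neg[1L]),
           call. = FALSE)
    }
  }
  flags <- character(0)
  if (!has_diam) flags <- c(flags, "volume_only")
  if (!has_vol) flags <- c(flags, "diameter_only")
  truth <- NULL
  tp <- truth_path(path)
  if (read_truth && file.exists(tp)) {
    truth <- utils::read.csv(tp, stringsAsFactors = FALSE)
  }
  structure(list(scans = scans, truth = truth, flags = flags, config = NULL),
            class = "sclc_cohort")
}
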