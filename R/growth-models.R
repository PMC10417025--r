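#' Fit an exponential growth curve
#'
#' Ordinary least squares on the log scale: a line through
#' `(t, ln V)` gives the growth rate `k` (slope) and baseline volume
#' `v0 = exp(intercept)`. Fitting in log space is the natural choice
#' under multiplicative measurement noise, and matches how serial
#' growth curves are read clinically: exponential growth is a straight
#' line on a log plot. The implied doubling time is `ln 2 / k`.
#'
#' @param times Days since baseline (length >= 2).
#' @param volumes Volumes in mm^3 (positive, same length).
#' @return An object of class `growth_fit` with `model`
#'   `"exponential"`, `params` (`v0`, `k`), `criterion` (SSE of log
#'   volumes), `implied_vdt`, `n_points` and `flags`.
#' @export
fit_exponential <- function(times, volumes) {
  check_fit_input(times, volumes, min_points = 2L)
  fit <- stats::lm(log(volumes) ~ times)
  k <- unname(stats::coef(fit)[2L])
  v0 <- exp(unname(stats::coef(fit)[1L]))
  sse <- sum(stats::residuals(fit)^2)
  flags <- character(0)
  if (abs(k) < .Machine$double.eps^0.5) {
    flags <- "zero_growth"
    k <- 0
  }
  new_growth_fit("exponential", list(v0 = v0, k = k), sse,
                 n_points = length(times),
                 implied_vdt = if (k == 0) Inf else log(2) / k, flags = flags)
}

#' Fit a Gompertz growth curve
#'
#' Nonlinear least squares on the log scale for
#' \deqn{\ln V(t) = \ln V_\infty + \ln(V_0/V_\infty)\, e^{-k t},}
#' using Levenberg-Marquardt with multi-start initialisation: `k`
#' seeded from the exponential fit and the carrying volume from
#' {2, 5, 20} times the largest observed volume.
#'
#' The exponential model is the `k -> 0` boundary of this family (in
#' log space every Gompertz curve is concave, a straight line being the
#' limit). On data with no log-scale deceleration the optimum sits at
#' that boundary and no interior stationary point beats the straight
#' line; the fit then degenerates toward an arbitrarily large carrying
#' volume. Such fits are returned with the exponential solution's
#' criterion, a very large `carrying_volume`, and the flag
#' `"degenerate_exponential_limit"`. Genuine optimiser failures are
#' flagged `"non_converged"`, never raised.
#'
#' @inheritParams fit_exponential
#' @return A `growth_fit` with `model` `"gompertz"` and `params`
#'   (`v0`, `k`, `carrying_volume`).
#' @export
fit_gompertz <- function(times, volumes) {
  check_fit_input(times, volumes, min_points = 3L)
  lv <- log(volumes)
  expfit <- fit_exponential(times, volumes)
  sse_exp <- expfit$criterion

  gomp_ll <- function(t, a, b, k) a + b * exp(-k * t)  # a = ln Vinf, b = ln(v0/Vinf)
  best <- NULL
  k0 <- max(expfit$params$k, 1e-4)
  for (mult in c(2, 5, 20)) {
    vinf0 <- mult * max(volumes)
    a0 <- log(vinf0)
    b0 <- lv[1L] - a0
    for (kstart in unique(c(k0, 2 * k0, 5 * k0))) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          lv ~ gomp_ll(times, a, b, k),
          start = list(a = a0, b = b0, k = kstart),
          lower = c(a = -Inf, b = -Inf, k = 1e-8),
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit)) next
      sse <- sum(stats::residuals(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(sse = sse, coef = stats::coef(fit))
      }
    }
  }

  # boundary candidate: the exponential limit (k -> 0, Vinf -> Inf).
  # Reported when no interior optimum improves on the straight line.
  if (is.null(best) || best$sse > sse_exp - 1e-12) {
    vinf <- 1e6 * max(volumes)
    # initial-rate match: k * ln(Vinf/v0) equals the exponential rate
    kb <- max(expfit$params$k, 1e-12) / log(vinf / expfit$params$v0)
    flags <- if (is.null(best)) c("non_converged",
                                  "degenerate_exponential_limit")
             else "degenerate_exponential_limit"
    return(new_growth_fit(
      "gompertz",
      list(v0 = expfit$params$v0, k = kb, carrying_volume = vinf),
      sse_exp, n_points = length(times),
      implied_vdt = expfit$implied_vdt, flags = flags))
  }

  a <- unname(best$coef["a"]); b <- unname(best$coef["b"])
  k <- unname(best$coef["k"])
  v0 <- exp(a + b)
  vinf <- exp(a)
  flags <- character(0)
  if (b >= 0) flags <- "carrying_volume_below_v0"
  init_rate <- k * max(-b, .Machine$double.eps)
  new_growth_fit("gompertz",
                 list(v0 = v0, k = k, carrying_volume = vinf),
                 best$sse, n_points = length(times),
                 implied_vdt = log(2) / init_rate, flags = flags)
}

check_fit_input <- function(times, volumes, min_points) {
  if (length(times) != length(volumes)) {
    stop("growth fit: times and volumes must have equal length", call. = FALSE)
  }
  if (length(times) < min_points) {
    stop(sprintf("growth fit: need at least %d points", min_points),
         call. = FALSE)
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("growth fit: volumes must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(times)) {
    stop("growth fit: duplicate time points", call. = FALSE)
  }
}

new_growth_fit <- function(model, params, criterion, n_points,
                           implied_vdt = NA_real_, pattern = NA_character_,
                           flags = character(0)) {
  structure(list(model = model, params = params, criterion = criterion,
                 implied_vdt = implied_vdt, n_points = n_points,
                 pattern = pattern, flags = flags),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  p <- vapply(x$params, function(v) format(signif(v, 5)), character(1))
  cat(sprintf("%s growth fit (n = %d): %s; log-SSE = %.4g\n", x$model,
              x$n_points, paste(names(p), p, sep = " = ", collapse = ", "),
              x$criterion))
  if (is.finite(x$implied_vdt)) {
    cat(sprintf("  implied initial VDT: %.1f days\n", x$implied_vdt))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Gaussian AICc of a log-space least-squares fit; Inf when the
# small-sample correction is undefined (n <= n_par + 1)
aicc_from_sse <- function(sse, n, n_par) {
  k <- n_par + 1L  # + residual variance
  if (n - k - 1L <= 0L) return(Inf)
  aic <- n * log(max(sse, 1e-300) / n) + 2 * k
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Classify a series' growth pattern
#'
#' Labels a serial-volume trajectory `"exponential-like"`,
#' `"gompertz-like"` or `"indeterminate"`. The discriminator is the
#' log-scale curvature: per-interval specific growth rates
#' `r_i = (ln V_{i+1} - ln V_i) / (t_{i+1} - t_i)` are compared across
#' consecutive intervals, giving second differences of `ln V` per
#' day^2. A series decelerating beyond tolerance on every interval pair
#' is Gompertz-like; one never decelerating beyond tolerance (constant
#' or accelerating log-growth) is exponential-like; mixed signs are
#' indeterminate. When enough points are available for the
#' small-sample-corrected AIC of both fitted models (n >= 6), the AICc
#' comparison must agree (margin 2) or the label degrades to
#' indeterminate; at the 3--4 scans typical of follow-up series the
#' curvature rule alone decides.
#'
#' The label is invariant to rescaling volumes by a positive constant
#' and to shifting all times.
#'
#' @inheritParams fit_exponential
#' @param tol Deceleration tolerance on second differences of `ln V`,
#'   per day^2; differences smaller than this are treated as zero.
#' @return Character label with attribute `"reason"`.
#' @export
classify_pattern <- function(times, volumes, tol = 1e-6) {
  if (length(times) < 3L) {
    return(structure("indeterminate", reason = "fewer than 3 points"))
  }
  check_fit_input(times, volumes, min_points = 3L)
  o <- order(times)
  times <- times[o]; volumes <- volumes[o]
  lv <- log(volumes)
  r <- diff(lv) / diff(times)                     # per-interval specific rates
  mid <- (times[-1L] + times[-length(times)]) / 2 # interval midpoints
  curv <- diff(r) / diff(mid)                     # d2 lnV / dt2, per day^2
  n <- length(times)

  decel <- curv < -tol
  nondec <- curv >= -tol
  label <- if (all(decel)) "gompertz-like"
           else if (all(nondec)) "exponential-like"
           else "indeterminate"
  reason <- "log-scale curvature rule"

  if (label != "indeterminate" && n >= 6L) {
    fe <- fit_exponential(times, volumes)
    fg <- fit_gompertz(times, volumes)
    d_aicc <- aicc_from_sse(fe$criterion, n, 2L) -
      aicc_from_sse(fg$criterion, n, 3L)   # > 0 favours Gompertz
    aicc_label <- if (d_aicc > 2) "gompertz-like"
                  else if (d_aicc < -2) "exponential-like"
                  else NA_character_
    if (!is.na(aicc_label) && aicc_label != label) {
      label <- "indeterminate"
      reason <- "curvature rule and AICc disagree"
    } else {
      reason <- "curvature rule, AICc consulted"
    }
  }
  structure(label, reason = reason)
}

#' Fit growth curves for every eligible patient in a cohort
#'
#' For each patient with at least three volume-bearing scans, fits both
#' the exponential and Gompertz models, classifies the pattern, and
#' returns one row per patient. Patients with fewer scans are skipped
#' (the headline VDT still covers them via [series_vdt()]).
#'
#' @param cohort An `sclc_cohort` or per-scan data.frame.
#' @param min_scans Minimum volume-bearing scans required (default 3).
#' @return data.frame: `patient_id`, `n_scans`, exponential `k` and
#'   `v0`, implied VDT, Gompertz `k`/`v0`/`carrying_volume`, both SSE
#'   criteria, `pattern`, `flags`.
#' @export
fit_cohort_curves <- function(cohort, min_scans = 3L) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  scans <- as.data.frame(scans)
  scans$scan_date <- parse_scan_date(scans$scan_date)
  rows <- lapply(split(scans, scans$patient_id), function(s) {
    s <- s[order(s$scan_date), , drop = FALSE]
    s <- s[!is.na(s$voxel_volume) & s$voxel_volume > 0, , drop = FALSE]
    if (nrow(s) < min_scans) return(NULL)
    t <- as.numeric(s$scan_date - s$scan_date[1L])
    v <- s$voxel_volume
    fe <- fit_exponential(t, v)
    fg <- fit_gompertz(t, v)
    pat <- classify_pattern(t, v)
    data.frame(patient_id = s$patient_id[1L], n_scans = nrow(s),
               exp_k = fe$params$k, exp_v0 = fe$params$v0,
               exp_vdt = fe$implied_vdt, exp_sse = fe$criterion,
               gomp_k = fg$params$k, gomp_v0 = fg$params$v0,
               gomp_carrying = fg$params$carrying_volume,
               gomp_sse = fg$criterion,
               pattern = as.character(pat),
               flags = paste(unique(c(fe$flags, fg$flags)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), n_scans = integer(0),
                      exp_k = numeric(0), exp_v0 = numeric(0),
                      exp_vdt = numeric(0), exp_sse = numeric(0),
                      gomp_k = numeric(0), gomp_v0 = numeric(0),
                      gomp_carrying = numeric(0), gomp_sse = numeric(0),
                      pattern = character(0), flags = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Growth-curve plot data for a cohort
#'
#' Long-format table of observed volumes against days since each
#' patient's first scan, with the log-volume column alongside, for
#' linear- and log-scale growth-curve figures.
#'
#' @inheritParams fit_cohort_curves
#' @return data.frame: `patient_id`, `day`, `volume`, `log10_volume`.
#' @export
growth_curve_data <- function(cohort, min_scans = 3L) {
  scans <- if (inherits(cohort, "sclc_cohort")) cohort$scans else cohort
  scans <- as.data.frame(scans)
  scans$scan_date <- parse_scan_date(scans$scan_date)
  rows <- lapply(split(scans, scans$patient_id), function(s) {
    s <- s[order(s$scan_date), , drop = FALSE]
    s <- s[!is.na(s$voxel_volume) & s$voxel_volume > 0, , drop = FALSE]
    if (nrow(s) < min_scans) return(NULL)
    data.frame(patient_id = s$patient_id[1L],
               day = as.numeric(s$scan_date - s$scan_date[1L]),
               volume = s$voxel_volume,
               log10_volume = log10(s$voxel_volume),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), day = numeric(0),
                      volume = numeric(0), log10_volume = numeric(0))
  }
  rownames(out) <- NULL
  out
}
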