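#' Intraclass correlation between two measurement methods
#'
#' Single-measure intraclass correlation from the two-way ANOVA mean
#' squares, for n subjects each measured by the same two methods
#' (raters). The default is the absolute-agreement form ICC(A,1)
#' (McGraw & Wong), which penalises systematic offsets between the
#' methods; the consistency form ICC(C,1) is also exposed.
#'
#' With subjects as rows and methods as columns,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' \deqn{ICC(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}}
#' where MS_R, MS_C, MS_E are the row (subject), column (method) and
#' residual mean squares and k = 2 methods.
#'
#' @param x,y Paired measurements of the same subjects by two methods
#'   (equal length, n >= 3, no NA).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return The ICC (a number <= 1).
#' @export
agreement_icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  if (length(x) != length(y)) {
    stop("agreement_icc: x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("agreement_icc: need at least 3 complete pairs",
                   call. = FALSE)
  k <- 2L
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Compare a measurement between two groups
#'
#' Two-sample location comparison with a normality gate: Shapiro-Wilk
#' on each group (alpha = 0.05) selects a two-sample t test when both
#' groups look normal, otherwise a two-sided Mann-Whitney U test (exact
#' for small tie-free samples, normal approximation with tie correction
#' otherwise, as in [stats::wilcox.test()]). Single-member groups are
#' computed but flagged low-power.
#'
#' @param values Numeric measurements (e.g. VDT in days).
#' @param group Two-level grouping vector, same length.
#' @param normality `"auto"` (Shapiro-Wilk gate), `"normal"` (force t
#'   test) or `"nonnormal"` (force Mann-Whitney).
#' @return List of class `group_test`: `test`, `statistic`, `p_value`,
#'   `n` (per-group sizes), `flags`.
#' @export
compare_groups <- function(values, group,
                           normality = c("auto", "normal", "nonnormal")) {
  normality <- match.arg(normality)
  ok <- is.finite(values) & !is.na(group)
  values <- values[ok]; group <- as.factor(as.character(group[ok]))
  lev <- levels(group)
  if (length(lev) != 2L) {
    stop("compare_groups: need exactly 2 non-empty groups", call. = FALSE)
  }
  n <- table(group)
  if (any(n == 0L)) stop("compare_groups: empty group", call. = FALSE)
  flags <- character(0)
  if (any(n < 2L)) flags <- c(flags, "single_member_group")
  use_t <- switch(normality,
    normal = TRUE,
    nonnormal = FALSE,
    auto = {
      shap_ok <- vapply(lev, function(g) {
        v <- values[group == g]
        if (length(unique(v)) < 3L) return(FALSE)
        stats::shapiro.test(v)$p.value >= 0.05
      }, logical(1))
      all(shap_ok)
    })
  res <- if (use_t) {
    ht <- stats::t.test(values ~ group)
    list(test = "t", statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values ~ group))
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value)
  }
  structure(c(res, list(n = as.integer(n), groups = lev, flags = flags)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s test (%s n=%d vs %s n=%d): statistic = %.4g, p = %.4g\n",
              x$test, x$groups[1L], x$n[1L], x$groups[2L], x$n[2L],
              x$statistic, x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho with tie-corrected (average) ranks and a two-sided
#' p-value, as used for VDT against continuous covariates such as
#' smoking index, baseline diameter, baseline volume, age and scan
#' interval. A constant input has no defined rank correlation and is
#' flagged rather than raised.
#'
#' @param x,y Equal-length numeric vectors (n >= 3 complete pairs).
#' @return List: `rho`, `p_value`, `n`, `flags`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) {
    stop("correlate: x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("correlate: need at least 3 complete pairs",
                           call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                flags = "undefined_correlation_constant_input"))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       flags = character(0))
}

#' Univariate analysis of factors influencing growth speed
#'
#' For each covariate, a single-predictor logistic regression of the
#' fast/slow class (fast = 1) with Wald odds ratio, 95% CI and p-value.
#' Covariates showing complete or quasi-complete separation -- or any
#' empty class-by-category cell -- are flagged and fall back to
#' Fisher's exact test (categorical predictors only). No multiplicity
#' correction is applied; p-values are reported raw.
#'
#' @param results Per-patient kinetics table from [compute_kinetics()]
#'   (needs `speed_class` plus the covariate columns).
#' @param covariates Character vector of covariate column names;
#'   default: every column that is not a kinetics output.
#' @return data.frame: `covariate`, `test`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `flags`.
#' @export
univariate_speed_analysis <- function(results, covariates = NULL) {
  results <- as.data.frame(results)
  if (!"speed_class" %in% names(results) || all(is.na(results$speed_class))) {
    stop("univariate_speed_analysis: speed_class must be assigned",
         call. = FALSE)
  }
  kin_cols <- c("patient_id", "vdt_manual", "vdt_roi", "gr_manual", "gr_roi",
                "delta_t", "n_scans", "speed_class", "flags")
  if (is.null(covariates)) covariates <- setdiff(names(results), kin_cols)
  y <- as.integer(results$speed_class == "fast")
  out <- lapply(covariates, function(cv) {
    xi <- results[[cv]]
    ok <- !is.na(xi) & !is.na(y)
    xi <- xi[ok]; yi <- y[ok]
    is_cat <- is.character(xi) || is.factor(xi)
    if (is_cat) xi <- factor(xi)
    flags <- character(0)
    if (is_cat && (nlevels(xi) < 2L || length(unique(yi)) < 2L)) {
      return(data.frame(covariate = cv, test = "none", odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, flags = "degenerate",
                        stringsAsFactors = FALSE))
    }
    sep <- FALSE
    if (is_cat) {
      tab <- table(xi, yi)
      sep <- any(tab == 0L)
    }
    fit <- suppressWarnings(stats::glm(yi ~ xi, family = stats::binomial()))
    co <- summary(fit)$coefficients
    slope <- co[2L, , drop = FALSE]
    if (!sep) sep <- abs(slope[1L, "Estimate"]) > 15 || slope[1L, "Std. Error"] > 100
    if (sep && is_cat) {
      flags <- c(flags, "separation_or_zero_cell", "fisher_exact_fallback")
      ft <- stats::fisher.test(table(xi, yi))
      or <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
      ci <- if (!is.null(ft$conf.int)) ft$conf.int else c(NA_real_, NA_real_)
      data.frame(covariate = cv, test = "fisher_exact", odds_ratio = or,
                 ci_low = ci[1L], ci_high = ci[2L], p_value = ft$p.value,
                 flags = paste(flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    } else {
      if (sep) flags <- c(flags, "possible_separation")
      est <- slope[1L, "Estimate"]; se <- slope[1L, "Std. Error"]
      data.frame(covariate = cv, test = "logistic",
                 odds_ratio = exp(est),
                 ci_low = exp(est - 1.96 * se),
                 ci_high = exp(est + 1.96 * se),
                 p_value = slope[1L, "Pr(>|z|)"],
                 flags = paste(flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(covariate = character(0), test = character(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_value = numeric(0),
                      flags = character(0))
  }
  rownames(out) <- NULL
  out
}

quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                         names = FALSE)

#' Summarise cohort growth kinetics
#'
#' Cohort-level report: per-method median VDT with interquartile range
#' (type-7 linear-interpolation quantiles), growth-rate mean and SD,
#' inter-method agreement (ICC, absolute agreement, on both VDT and
#' GR, over patients measured as growing by both methods -- negative
#' VDTs are flagged artifacts), fast/slow counts at the cut-off, and
#' growth-rate histogram bins
#' for the growth-distribution figure.
#'
#' @param results Per-patient table from [compute_kinetics()].
#' @param cutoff_days Fast/slow cut-off in days (default 60).
#' @param gr_breaks Histogram breaks for the GR distribution; default
#'   0.0025-wide bins covering the observed range.
#' @return Object of class `cohort_summary`.
#' @export
summarize_cohort <- function(results, cutoff_days = 60, gr_breaks = NULL) {
  results <- as.data.frame(results)
  has_any <- is.finite(results$vdt_manual) | is.finite(results$vdt_roi)
  if (!nrow(results) || !any(has_any)) {
    stop("summarize_cohort: no patients with a computable VDT", call. = FALSE)
  }
  one_method <- function(vdt) {
    v <- vdt[is.finite(vdt)]
    if (!length(v)) return(NULL)
    q <- quartiles(v)
    gr <- 1 / v
    list(n = length(v), median_vdt = q[2L], iqr_vdt = q[c(1L, 3L)],
         gr_mean = mean(gr), gr_sd = stats::sd(gr))
  }
  manual <- one_method(results$vdt_manual)
  roi <- one_method(results$vdt_roi)
  # agreement is assessed on growing lesions: a negative VDT is a
  # flagged measurement artifact (observed cohorts of untreated cancer
  # contain none) and one such value can dominate the variance terms
  both <- is.finite(results$vdt_manual) & is.finite(results$vdt_roi) &
    results$vdt_manual > 0 & results$vdt_roi > 0
  icc_vdt <- icc_gr <- NA_real_
  if (sum(both) >= 3L) {
    icc_vdt <- agreement_icc(results$vdt_manual[both], results$vdt_roi[both])
    icc_gr <- agreement_icc(1 / results$vdt_manual[both],
                            1 / results$vdt_roi[both])
  }
  primary_vdt <- ifelse(is.finite(results$vdt_manual), results$vdt_manual,
                        results$vdt_roi)
  pos <- is.finite(primary_vdt) & primary_vdt > 0
  speed <- classify_speed(primary_vdt[pos], cutoff_days)
  gr_all <- 1 / primary_vdt[pos]
  if (is.null(gr_breaks)) {
    gr_breaks <- seq(0, max(gr_all) + 0.0025, by = 0.0025)
  }
  h <- graphics::hist(gr_all, breaks = gr_breaks, plot = FALSE)
  structure(
    list(manual = manual, roi = roi,
         agreement_vdt = icc_vdt, agreement_gr = icc_gr,
         cutoff_days = cutoff_days,
         speed_counts = c(n_fast = sum(speed == "fast"),
                          n_slow = sum(speed == "slow")),
         gr_distribution = data.frame(bin_low = utils::head(h$breaks, -1L),
                                      bin_high = h$breaks[-1L],
                                      count = h$counts),
         n_patients = nrow(results)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(m, label) {
    if (is.null(m)) return(invisible(NULL))
    cat(sprintf("  %s: median VDT %.0f days (IQR %.0f-%.0f), GR %.4f +/- %.4f /day (n=%d)\n",
                label, m$median_vdt, m$iqr_vdt[1L], m$iqr_vdt[2L],
                m$gr_mean, m$gr_sd, m$n))
  }
  cat(sprintf("Cohort growth summary (%d patients):\n", x$n_patients))
  fmt(x$manual, "diameter method")
  fmt(x$roi, "volume method  ")
  if (is.finite(x$agreement_vdt)) {
    cat(sprintf("  method agreement: ICC %.2f (VDT), %.2f (GR)\n",
                x$agreement_vdt, x$agreement_gr))
  }
  cat(sprintf("  fast (< %g d) / slow: %d / %d\n", x$cutoff_days,
              x$speed_counts[["n_fast"]], x$speed_counts[["n_slow"]]))
  invisible(x)
}

#' Run the standard covariate comparisons on a kinetics table
#'
#' Applies [compare_groups()] per binary covariate and [correlate()]
#' per continuous covariate, for each VDT method, reproducing the
#' cohort's covariate screen (sex, smoking, shape, location, ... against
#' VDT; smoking index, baseline size, interval days against VDT).
#'
#' @param results Per-patient table from [compute_kinetics()].
#' @param binary_covariates,continuous_covariates Column names; defaults
#'   cover the standard clinical/imaging covariates present in the
#'   table.
#' @return data.frame with one row per covariate x method.
#' @export
covariate_screen <- function(results,
                             binary_covariates = NULL,
                             continuous_covariates = NULL) {
  results <- as.data.frame(results)
  std_bin <- c("sex", "smoking_history", "tumour_history", "family_history",
               "lobe_site", "shape", "spiculated", "lobulation",
               "pleural_retraction", "location_pleural_attached",
               "emphysema", "interstitial_pneumonia")
  std_cont <- c("smoking_index")
  if (is.null(binary_covariates)) {
    binary_covariates <- intersect(std_bin, names(results))
  }
  if (is.null(continuous_covariates)) {
    continuous_covariates <- intersect(std_cont, names(results))
  }
  methods <- c(vdt_manual = "manual", vdt_roi = "roi")
  rows <- list()
  for (col in names(methods)) {
    v <- results[[col]]
    for (cv in binary_covariates) {
      res <- tryCatch(compare_groups(v, results[[cv]]),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, method = methods[[col]],
        analysis = if (is.null(res)) "failed" else res$test,
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        estimate = NA_real_,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        flags = if (is.null(res)) "not_computable"
                else paste(res$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    for (cv in continuous_covariates) {
      res <- tryCatch(correlate(results[[cv]], v), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, method = methods[[col]],
        analysis = "spearman",
        statistic = NA_real_,
        estimate = if (is.null(res)) NA_real_ else res$rho,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        flags = if (is.null(res)) "not_computable"
                else paste(res$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(covariate = character(0), method = character(0),
                      analysis = character(0), statistic = numeric(0),
                      estimate = numeric(0), p_value = numeric(0),
                      flags = character(0))
  }
  rownames(out) <- NULL
  out
}
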