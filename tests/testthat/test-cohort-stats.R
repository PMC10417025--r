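test_that("ICC is exact on its boundary cases", {
  x <- c(61, 71, 49, 103, 55, 88, 120, 43)
  expect_equal(agreement_icc(x, x), 1, tolerance = 1e-12)
  expect_equal(agreement_icc(x, x, type = "consistency"), 1, tolerance = 1e-12)
  # symmetry in the two methods
  y <- x + c(2, -5, 4, 8, -3, 1, -6, 2)
  expect_equal(agreement_icc(x, y), agreement_icc(y, x), tolerance = 1e-12)
  expect_lte(agreement_icc(x, y), 1)
  expect_error(agreement_icc(x[1:2], y[1:2]), "at least 3")
})

test_that("ICC matches the ANOVA mean-squares oracle on a fixed 10-pair fixture", {
  x <- c(61, 71, 49, 104, 55, 88, 119, 43, 67, 95)
  y <- c(71, 66, 48, 103, 62, 81, 158, 49, 63, 92)
  expect_equal(agreement_icc(x, y), icc_oracle_aov(x, y), tolerance = 1e-9)
  expect_equal(agreement_icc(x, y, type = "consistency"),
               icc_oracle_aov(x, y, type = "consistency"), tolerance = 1e-9)
})

test_that("ICC of independent noise is near zero, of shared signal near one", {
  set.seed(99)
  a <- rnorm(2000); b <- rnorm(2000)
  expect_lt(abs(agreement_icc(a, b)), 0.08)
  s <- rnorm(2000, sd = 3)
  expect_gt(agreement_icc(s + rnorm(2000, sd = 0.3),
                          s + rnorm(2000, sd = 0.3)), 0.95)
})

test_that("group comparison picks Mann-Whitney or t by the normality gate", {
  set.seed(7)
  skewed <- c(rlnorm(15, 3, 1), rlnorm(12, 3.5, 1))
  g <- rep(c("a", "b"), c(15, 12))
  r <- compare_groups(skewed, g)
  expect_identical(r$test, "mann-whitney")
  normals <- c(rnorm(15, 10), rnorm(12, 10.5))
  r2 <- compare_groups(normals, g)
  expect_identical(r2$test, "t")
  # forcing works both ways
  expect_identical(compare_groups(skewed, g, normality = "normal")$test, "t")
  expect_identical(compare_groups(normals, g, normality = "nonnormal")$test,
                   "mann-whitney")
})

test_that("identical groups give p = 1 and single-member groups are flagged", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("x", "y"), each = 3)
  expect_equal(compare_groups(v, g, normality = "nonnormal")$p_value, 1)
  # one patient in a category (e.g. pleural retraction): computed, flagged
  v2 <- c(119, 67, 49, 100, 58, 81)
  g2 <- c("yes", "no", "no", "no", "no", "no")
  r <- compare_groups(v2, g2, normality = "nonnormal")
  expect_true("single_member_group" %in% r$flags)
  expect_true(is.finite(r$p_value))
  expect_error(compare_groups(v2, rep("no", 6)), "2 non-empty groups")
})

test_that("Mann-Whitney p equals exhaustive permutation for all small designs", {
  set.seed(11)
  for (n1 in 1:8) {
    for (n2 in seq_len(10 - n1)) {
      x <- sample(seq_len(100), n1)   # integer draws w/o replacement: no ties
      y <- setdiff(seq_len(100), x)[seq_len(n2)]
      y <- sample(y)
      r <- compare_groups(c(x, y), rep(c("g1", "g2"), c(n1, n2)),
                          normality = "nonnormal")
      expect_equal(r$p_value, mw_exact_perm_p(x, y), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("fully separated groups attain the minimal exact p", {
  # {1,2,3} vs {101,102,103}: the most extreme of the 20 assignments
  r <- compare_groups(c(1, 2, 3, 101, 102, 103),
                      rep(c("lo", "hi"), each = 3), normality = "nonnormal")
  expect_equal(r$p_value, mw_exact_perm_p(c(1, 2, 3), c(101, 102, 103)),
               tolerance = 1e-12)
  expect_equal(r$p_value, 2 / 20, tolerance = 1e-12)
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  # fixed 8-pair fixture with one tie
  x <- c(1.2, 3.4, 3.4, 5.0, 6.1, 7.7, 8.2, 9.9)
  y <- c(2.0, 1.1, 4.4, 3.9, 6.6, 6.0, 9.1, 8.8)
  r <- correlate(x, y)
  expect_equal(r$rho, spearman_oracle(x, y), tolerance = 1e-12)

  # monotone transforms give |rho| = 1
  xs <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(xs, exp(xs))$rho, 1, tolerance = 1e-12)
  expect_equal(correlate(xs, rev(xs))$rho, -1, tolerance = 1e-12)

  # invariance under strictly monotone transforms of either variable
  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(correlate(exp(a), b)$rho, correlate(a, b)$rho,
               tolerance = 1e-12)
  expect_true(abs(correlate(a, b)$rho) <= 1)

  # constant input flagged, not raised
  expect_identical(correlate(rep(1, 5), 1:5)$flags,
                   "undefined_correlation_constant_input")
})

test_that("univariate speed analysis flags separation and handles nulls", {
  set.seed(5)
  n <- 60
  speed <- rep(c("fast", "slow"), c(25, 35))
  res <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    vdt_manual = ifelse(speed == "fast", runif(n, 20, 59), runif(n, 60, 300)),
    vdt_roi = NA_real_, gr_manual = NA_real_, gr_roi = NA_real_,
    delta_t = 100L, n_scans = 2L, speed_class = speed, flags = "",
    indep = sample(c("a", "b"), n, replace = TRUE),
    mirror = ifelse(speed == "fast", "yes", "no"),
    stringsAsFactors = FALSE)
  tab <- univariate_speed_analysis(res, c("indep", "mirror"))
  expect_identical(nrow(tab), 2L)
  ind <- tab[tab$covariate == "indep", ]
  expect_identical(ind$test, "logistic")
  expect_true(is.finite(ind$odds_ratio))
  mir <- tab[tab$covariate == "mirror", ]
  expect_match(mir$flags, "separation")
  expect_identical(mir$test, "fisher_exact")
})

test_that("type-I error of the univariate screen is near nominal", {
  # covariate independent of class by construction; rejection rate at
  # alpha = 0.05 over replicates should be close to 5%
  set.seed(17)
  reps <- 400
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    n <- 40
    speed <- sample(rep(c("fast", "slow"), each = n / 2))
    cov <- sample(c("a", "b"), n, replace = TRUE)
    res <- data.frame(speed_class = speed, cov = cov,
                      stringsAsFactors = FALSE)
    p <- univariate_speed_analysis(res, "cov")$p_value
    rej[i] <- is.finite(p) && p < 0.05
  }
  # binomial 3-sigma band around 0.05 for 400 replicates (~ +/- 0.033)
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("a small synthetic cohort typically shows no significant covariate", {
  # covariates are generated independently of growth speed, so at n = 27
  # a typical draw has no p < 0.05 across the screen; assert as a
  # distribution over seeds rather than a single run
  frac_null <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_config(n_patients = 27, seed = s))
    res <- compute_kinetics(co)
    tab <- univariate_speed_analysis(res)
    mean(tab$p_value > 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(frac_null), 0.85)
})

test_that("cohort summary reports medians, IQRs, agreement and speed counts", {
  co <- simulate_cohort(cohort_config(n_patients = 40, seed = 33))
  res <- compute_kinetics(co)
  s <- summarize_cohort(res)
  expect_s3_class(s, "cohort_summary")
  # IQR brackets the median; quartile convention is type 7
  expect_lte(s$manual$iqr_vdt[1L], s$manual$median_vdt)
  expect_gte(s$manual$iqr_vdt[2L], s$manual$median_vdt)
  expect_equal(unname(s$manual$median_vdt),
               unname(quantile(res$vdt_manual, 0.5, type = 7)))
  expect_lte(s$agreement_vdt, 1)
  expect_identical(sum(s$speed_counts),
                   sum(is.finite(res$vdt_manual) & res$vdt_manual > 0))
  # GR histogram counts cover every patient once
  expect_identical(sum(s$gr_distribution$count), unname(sum(s$speed_counts)))

  # degenerate cases
  one <- res[7, ]
  s1 <- summarize_cohort(one)
  expect_equal(unname(s1$manual$median_vdt), one$vdt_manual)
  expect_equal(unname(diff(s1$manual$iqr_vdt)), 0)
  same <- res[1:4, ]
  same$vdt_manual <- same$vdt_roi <- 80
  s2 <- summarize_cohort(same)
  expect_equal(s2$manual$gr_sd, 0)
  expect_error(summarize_cohort(res[0, ]), "no patients")
})

test_that("summary speed counts respond monotonically to the cutoff", {
  # with slow defined as vdt >= cutoff, raising the cutoff can only
  # move patients from slow to fast, and the total stays fixed
  co <- simulate_cohort(cohort_config(n_patients = 50, seed = 44))
  res <- compute_kinetics(co)
  counts <- vapply(c(40, 60, 80, 120), function(ct) {
    summarize_cohort(res, cutoff_days = ct)$speed_counts
  }, numeric(2))
  expect_true(all(diff(counts["n_slow", ]) <= 0))
  expect_true(all(diff(counts["n_fast", ]) >= 0))
  expect_true(all(colSums(counts) == colSums(counts)[1L]))
})

test_that("covariate screen runs both methods over the standard covariates", {
  co <- simulate_cohort(cohort_config(n_patients = 35, seed = 55))
  res <- compute_kinetics(co)
  tab <- covariate_screen(res)
  expect_true(all(c("manual", "roi") %in% tab$method))
  expect_true("smoking_index" %in% tab$covariate)
  expect_true(all(tab$analysis %in% c("mann-whitney", "t", "spearman",
                                      "failed")))
  ok <- tab$analysis != "failed"
  expect_true(all(tab$p_value[ok] >= 0 & tab$p_value[ok] <= 1))
})
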