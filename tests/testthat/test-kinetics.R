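test_that("calendar intervals are exact Gregorian day counts", {
  expect_identical(interval_days("2020-08-12", "2020-11-07"), 87L)
  expect_identical(interval_days("8 November 2017", "26 March 2018"), 138L)
  expect_identical(interval_days("25 October 2019", "20 January 2020"), 87L)
  expect_identical(interval_days("24 December 2014", "24 March 2015"), 90L)
  expect_identical(interval_days("2016-02-28", "2016-03-01"), 2L)  # leap year
  expect_identical(interval_days("2021-06-01", "2021-06-02"), 1L)
  expect_error(interval_days("2021-06-02", "2021-06-02"), "after")
  expect_error(interval_days("2021-06-02", "2021-06-01"), "after")
})

test_that("lenient date parser handles clinical-table style dates", {
  expect_equal(parse_scan_date("7 November 2020"), as.Date("2020-11-07"))
  expect_equal(parse_scan_date(c("2020-01-02", "1 May 1999")),
               as.Date(c("2020-01-02", "1999-05-01")))
  expect_true(is.na(parse_scan_date("Novemberish 2020")))
})

test_that("diameter-product VDT matches the closed form and its symmetries", {
  s1 <- list(max_diam_xy = 10, perp_diam_xy = 8, max_diam_z = 9)
  s2 <- list(max_diam_xy = 12.6, perp_diam_xy = 10.1, max_diam_z = 11.3)
  # frozen 40-digit independent evaluation of the printed formula
  expect_equal(vdt_diameter(s1, s2, 90)$vdt, 90.17738001791909,
               tolerance = 1e-9)

  # cube scaling: all diameters doubled over 30 days -> VDT 10
  s2d <- lapply(s1, `*`, 2)
  expect_equal(vdt_diameter(s1, s2d, 30)$vdt, 10, tolerance = 1e-12)

  # shrinkage: halved diameters -> VDT = -dT/3, flagged not raised
  s2h <- lapply(s1, `/`, 2)
  r <- vdt_diameter(s1, s2h, 90)
  expect_equal(r$vdt, -30, tolerance = 1e-12)
  expect_true("negative_vdt" %in% r$flags)

  # no growth and missing data are errors
  expect_error(vdt_diameter(s1, s1, 30), "no measurable growth")
  expect_error(vdt_diameter(s1, list(max_diam_xy = 1, perp_diam_xy = 1), 30),
               "present")
})

test_that("Schwartz-equation VDT obeys doubling identities", {
  expect_equal(vdt_volume(100, 200, 100)$vdt, 100, tolerance = 1e-12)
  # two doublings over 2d days -> d
  expect_equal(vdt_volume(50, 200, 2 * 37)$vdt, 37, tolerance = 1e-12)
  expect_error(vdt_volume(100, 100, 30), "no measurable growth")
  expect_error(vdt_volume(-5, 100, 30), "positive")
})

test_that("VDT invariances hold over random measurement pairs", {
  set.seed(42)
  for (i in 1:25) {
    d1 <- runif(3, 5, 20)
    growth <- runif(3, 1.05, 2)
    dt <- sample(20:300, 1)
    s1 <- as.list(setNames(d1, c("max_diam_xy", "perp_diam_xy", "max_diam_z")))
    s2 <- as.list(setNames(d1 * growth,
                           c("max_diam_xy", "perp_diam_xy", "max_diam_z")))
    v1 <- pi / 6 * prod(d1)
    v2 <- pi / 6 * prod(d1 * growth)
    rd <- vdt_diameter(s1, s2, dt)
    rv <- vdt_volume(v1, v2, dt)
    # ellipsoid consistency: pi/6 cancels, methods agree
    expect_equal(rd$vdt, rv$vdt, tolerance = 1e-9)
    # scale invariance
    c0 <- runif(1, 0.1, 10)
    expect_equal(vdt_volume(c0 * v1, c0 * v2, dt)$vdt, rv$vdt,
                 tolerance = 1e-12)
    # time linearity and antisymmetry
    expect_equal(vdt_volume(v1, v2, 2 * dt)$vdt, 2 * rv$vdt,
                 tolerance = 1e-12)
    expect_equal(vdt_volume(v2, v1, dt)$vdt, -rv$vdt, tolerance = 1e-12)
    # GR * VDT = 1 on every emitted result
    expect_equal(rd$gr * rd$vdt, 1, tolerance = 1e-12)
    expect_equal(rv$gr * rv$vdt, 1, tolerance = 1e-12)
  }
})

test_that("growth rate is the reciprocal of VDT with 4-decimal reporting", {
  expect_equal(growth_rate(119, digits = 4), 0.0084)
  expect_equal(growth_rate(158, digits = 4), 0.0063)
  expect_equal(growth_rate(100), 0.01)
  expect_error(growth_rate(0), "non-zero")
})

test_that("series VDT uses the first and last scans only", {
  # three volume scans: middle value must not influence the result
  s <- data.frame(scan_date = as.Date(c("2021-02-20", "2021-07-23",
                                        "2021-08-26")),
                  voxel_volume = c(630.5, 2490.9, 3895.75))
  r <- series_vdt(s, "volume")
  expect_equal(r$vdt, vdt_volume(630.5, 3895.75, 187)$vdt, tolerance = 1e-12)
  s_perturbed <- s
  s_perturbed$voxel_volume[2L] <- 999
  expect_equal(series_vdt(s_perturbed, "volume")$vdt, r$vdt)
  expect_equal(r$first_scan_date, as.Date("2021-02-20"))
  expect_equal(r$last_scan_date, as.Date("2021-08-26"))

  # two scans degenerate to the pairwise operation
  s2 <- s[c(1, 3), ]
  expect_equal(series_vdt(s2, "volume")$vdt, r$vdt, tolerance = 1e-12)

  # insufficient data
  expect_error(series_vdt(s[1, ], "volume"), "fewer than 2")
})

test_that("4-scan noise-free exponential series recovers the true VDT", {
  dates <- as.Date("2020-01-01") + c(0, 45, 131, 200)
  v <- 500 * 2^(as.numeric(dates - dates[1L]) / 60)
  s <- data.frame(scan_date = dates, voxel_volume = v)
  expect_equal(series_vdt(s, "volume")$vdt, 60, tolerance = 1e-9)
})

test_that("speed classification puts the boundary in the slow group", {
  expect_identical(classify_speed(59), "fast")
  expect_identical(classify_speed(60), "slow")
  expect_identical(classify_speed(119), "slow")
  expect_identical(classify_speed(c(10, 60, 400)), c("fast", "slow", "slow"))
  expect_identical(classify_speed(60, cutoff = 61), "fast")
  expect_error(classify_speed(-3), "positive")
})

test_that("the speed split responds monotonically to the cutoff", {
  # slow means vdt >= cutoff, so raising the cutoff can only shrink the
  # slow group (equivalently, never shrink the fast group)
  set.seed(9)
  vdt <- rlnorm(100, log(61), 0.5)
  n_slow <- vapply(c(30, 60, 90, 150),
                   function(ct) sum(classify_speed(vdt, ct) == "slow"),
                   numeric(1))
  expect_true(all(diff(n_slow) <= 0))
  expect_identical(sum(classify_speed(vdt, 30) == "fast") +
                     n_slow[1L], 100)
})

test_that("de-novo report finds newly appearing lesions with intervals", {
  scans <- data.frame(
    patient_id = c("N1", "N1", "N2", "N2", "P1", "P1"),
    scan_date = c("2020-08-12", "2020-11-07", "2014-12-24", "2015-03-24",
                  "2019-01-01", "2019-04-01"),
    max_diam_xy = c(NA, 7.6, 0, 6.8, 10, 12),
    perp_diam_xy = c(NA, 6.9, 0, 6.1, 8, 10),
    max_diam_z = c(NA, 7.7, 0, 7.5, 9, 11),
    voxel_volume = c(NA, 230.5, 0, 162.5, 400, 700),
    stringsAsFactors = FALSE)
  rep <- de_novo_report(scans)
  rep <- rep[order(rep$patient_id), ]
  expect_identical(nrow(rep), 2L)  # all-positive P1 excluded
  expect_identical(rep$interval_days, c(87L, 90L))
  expect_equal(rep$first_volume, c(230.5, 162.5))
  expect_identical(format(rep$last_negative_date[1L]), "2020-08-12")

  # a cohort with no lesion-free scans gives an empty table
  expect_identical(nrow(de_novo_report(scans[5:6, ])), 0L)
})

test_that("per-patient kinetics table computes both methods side by side", {
  co <- make_fixture_cohort()
  res <- compute_kinetics(co)
  expect_identical(nrow(res), 3L)
  expect_true(all(c("vdt_manual", "vdt_roi", "gr_manual", "gr_roi",
                    "delta_t", "speed_class", "sex") %in% names(res)))
  # ellipsoid-consistent fixture: the two methods agree exactly
  expect_equal(res$vdt_manual, res$vdt_roi, tolerance = 1e-9)
  expect_equal(res$gr_manual * res$vdt_manual, rep(1, 3), tolerance = 1e-12)

  # volume-only input: diameter method flagged unavailable, not fatal
  vol_only <- co[, c("patient_id", "scan_date", "voxel_volume")]
  res2 <- compute_kinetics(vol_only)
  expect_true(all(is.na(res2$vdt_manual)))
  expect_equal(res2$vdt_roi, res$vdt_roi, tolerance = 1e-12)
  expect_true(all(grepl("diameter_method_unavailable", res2$flags)))
})
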