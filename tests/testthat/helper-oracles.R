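# Independent oracles used across the suite. Each re-derives a quantity
# by a different route than the implementation under test.

# Exhaustive-permutation two-sided Mann-Whitney p (no ties assumed):
# enumerate every assignment of the pooled sample to group 1.
mw_exact_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_idx <- utils::combn(length(pooled), n1)
  u_all <- apply(all_idx, 2L, u_of)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# ICC oracles from aov() mean squares (two-way, subjects x methods).
icc_oracle_aov <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_len(n), 2L)),
                  method = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + method, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  k <- 2
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Spearman rho by brute force: average-rank then Pearson product-moment.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Closed-form simple linear regression (sums of products), independent
# of lm().
ols_oracle <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  k <- sum((t - tb) * (y - yb)) / sum((t - tb)^2)
  list(slope = k, intercept = yb - k * tb)
}

# A tiny deterministic 3-patient cohort data.frame used by I/O and
# kinetics tests (diameters consistent with volume via pi/6 * XYZ).
make_fixture_cohort <- function() {
  mk <- function(id, dates, d1, d2, d3, sex) {
    data.frame(patient_id = id, scan_date = as.Date(dates),
               max_diam_xy = d1, perp_diam_xy = d2, max_diam_z = d3,
               voxel_volume = pi / 6 * d1 * d2 * d3,
               sex = sex, stringsAsFactors = FALSE)
  }
  rbind(
    mk("A", c("2020-01-01", "2020-03-01"), c(10, 12.6), c(8, 10.1),
       c(9, 11.3), "male"),
    mk("B", c("2019-05-10", "2019-07-19", "2019-10-01"),
       c(8, 9, 10.5), c(7, 8, 9.2), c(8, 9.1, 10.4), "female"),
    mk("C", c("2021-02-20", "2021-08-26"), c(11, 20), c(9, 16),
       c(10, 18), "male"))
}
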