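hourly_times <- function(n, start = "2019-01-25") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 3600
}

test_that("bin aggregation planning follows the greedy anchored rule", {
  # four identical series merge into one group at any attainable threshold
  base <- sin(seq_len(200)) + 2
  raw <- raw_pnsd(hourly_times(200), c(10, 20, 40, 80),
                  matrix(rep(base, each = 4), 4, 200))
  plan <- plan_bin_aggregation(raw, 0.97)
  expect_equal(plan$groups, list(1:4))

  # independent white noise: verify all pairwise correlations are below the
  # threshold, then expect all-singleton groups
  set.seed(42)
  vals <- matrix(rnorm(4 * 500, 10, 1), 4, 500)
  stopifnot(max(abs(cor(t(vals))[upper.tri(diag(4))])) < 0.97)
  raw2 <- raw_pnsd(hourly_times(500), c(10, 20, 40, 80), vals)
  plan2 <- plan_bin_aggregation(raw2, 0.97)
  expect_equal(plan2$groups, list(1L, 2L, 3L, 4L))

  # constructed pair: bin2 = bin1 + small noise, bin3 independent
  set.seed(7)
  b0 <- exp(rnorm(300, 3, 0.5))
  b1 <- b0 + rnorm(300, 0, 0.02 * sd(b0))
  b2 <- exp(rnorm(300, 3, 0.5))
  stopifnot(cor(b0, b1) >= 0.99, cor(b0, b2) < 0.5)
  raw3 <- raw_pnsd(hourly_times(300), c(10, 20, 40), rbind(b0, b1, b2))
  plan3 <- plan_bin_aggregation(raw3, 0.97)
  expect_equal(plan3$groups, list(1:2, 3L))

  # unattainable threshold keeps everything separate
  expect_equal(plan_bin_aggregation(raw, 1.01)$groups, list(1L, 2L, 3L, 4L))
})

test_that("bin pairs with fewer than two joint observations raise an error", {
  vals <- matrix(c(1, 2, 3, 4, NA, NA, NA, 8), 2, 4, byrow = TRUE)
  raw <- raw_pnsd(hourly_times(4), c(10, 20), vals)
  expect_error(plan_bin_aggregation(raw, 0.9), "fewer than 2")
})

test_that("bin aggregation sums concentrations and conserves total count", {
  raw <- raw_pnsd(hourly_times(2), c(10, 20, 40),
                  matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
  plan <- structure(list(axis = "bin", groups = list(1:2, 3L), tau = 0.9,
                         correlations = list(numeric(0), numeric(0))),
                    class = "aggregation_plan")
  agg <- apply_bin_aggregation(raw, plan)
  expect_equal(unname(agg$values), matrix(c(4, 5, 6, 6), 2, 2))
  expect_equal(colSums(agg$values), colSums(raw$values))
  # representative label is the geometric mean; endpoints retained
  expect_equal(agg$bin_labels[1], sqrt(10 * 20))
  expect_equal(attr(agg, "bin_lo"), c(10, 40))
  expect_equal(attr(agg, "bin_hi"), c(20, 40))

  singleton <- structure(list(axis = "bin", groups = list(1L, 2L, 3L),
                              tau = 0.9,
                              correlations = list(numeric(0), numeric(0),
                                                  numeric(0))),
                         class = "aggregation_plan")
  expect_equal(apply_bin_aggregation(raw, singleton)$values, raw$values)

  all_one <- structure(list(axis = "bin", groups = list(1:3), tau = 0,
                            correlations = list(numeric(0))),
                       class = "aggregation_plan")
  expect_equal(unname(apply_bin_aggregation(raw, all_one)$values[1, ]),
               colSums(raw$values))
})

test_that("hour aggregation planning handles degenerate and regime cases", {
  # identical days with constant hours collapse to a single 24-hour group
  vals <- matrix(5, 2, 72)
  raw <- raw_pnsd(hourly_times(72), c(10, 20), vals)
  expect_equal(plan_hour_aggregation(raw, 0.97)$groups, list(1:24))

  # two independent within-day regimes split into exactly two groups
  set.seed(11)
  n_days <- 100
  a <- exp(rnorm(n_days, 2, 0.5)); b <- exp(rnorm(n_days, 2, 0.5))
  day_mat <- matrix(0, n_days, 24)
  for (h in 1:12) day_mat[, h] <- a * exp(rnorm(n_days, 0, 0.01))
  for (h in 13:24) day_mat[, h] <- b * exp(rnorm(n_days, 0, 0.01))
  stopifnot(abs(cor(day_mat[, 1], day_mat[, 13])) < 0.5)
  series <- as.vector(t(day_mat))
  raw2 <- raw_pnsd(hourly_times(n_days * 24), c(10, 20),
                   rbind(series, series * 2))
  plan2 <- plan_hour_aggregation(raw2, 0.97)
  expect_equal(plan2$groups, list(1:12, 13:24))

  # unattainable threshold: 24 singletons
  plan3 <- plan_hour_aggregation(raw2, 1.01)
  expect_length(plan3$groups, 24)
  expect_true(all(lengths(plan3$groups) == 1))

  # under two days of data is an error
  expect_error(plan_hour_aggregation(raw_pnsd(hourly_times(20), c(10, 20),
                                              matrix(1, 2, 20)), 0.97),
               "2 days")
})

test_that("hour aggregation averages within groups and tracks missingness", {
  # one day, one bin, values 1..24, groups {0-5},{6-23}
  raw <- raw_pnsd(hourly_times(24), c(10, 20),
                  rbind(1:24, rep(1, 24)))
  plan <- structure(list(axis = "hour", groups = list(1:6, 7:24), tau = 0.9,
                         correlations = list(numeric(0), numeric(0))),
                    class = "aggregation_plan")
  m <- apply_hour_aggregation(raw, plan)
  expect_equal(unname(m$values[1, ]), c(mean(1:6), mean(7:24)))
  expect_equal(m$block, c(1L, 2L))
  expect_equal(m$block_labels, c("0-6h", "6-24h"))

  # all-singleton plan leaves hourly data unchanged
  sing <- structure(list(axis = "hour", groups = as.list(1:24), tau = 0.9,
                         correlations = rep(list(numeric(0)), 24)),
                    class = "aggregation_plan")
  m2 <- apply_hour_aggregation(raw, sing)
  expect_equal(unname(m2$values), unname(raw$values))

  # a fully missing day yields fully missing aggregated steps
  vals3 <- cbind(matrix(2, 2, 24), matrix(NA_real_, 2, 24))
  raw3 <- raw_pnsd(hourly_times(48), c(10, 20), vals3)
  m3 <- apply_hour_aggregation(raw3, plan)
  expect_equal(unname(m3$missing_mask),
               matrix(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                      2, 4))
})

test_that("hour aggregation preserves per-day per-bin means under group weights", {
  set.seed(3)
  raw <- raw_pnsd(hourly_times(48), c(10, 20),
                  matrix(exp(rnorm(2 * 48, 2, 0.4)), 2, 48))
  plan <- structure(list(axis = "hour", groups = list(1:6, 7:9, 10:24),
                         tau = 0.9,
                         correlations = rep(list(numeric(0)), 3)),
                    class = "aggregation_plan")
  m <- apply_hour_aggregation(raw, plan)
  wts <- lengths(plan$groups)
  for (d in 1:2) {
    idx <- (d - 1) * 3 + 1:3
    day_cols <- (d - 1) * 24 + 1:24
    expect_equal(as.numeric(m$values[, idx] %*% wts) / 24,
                 rowMeans(raw$values[, day_cols]))
  }
})

test_that("zero replacement substitutes half the bin minimum and nothing else", {
  m <- make_tiny_data(P = 2, Tt = 3)
  m$values <- matrix(c(0, 10, 2, 0, 4, 5), 2, 3, byrow = FALSE)
  # bin 1: (0, 2, 4) -> (1, 2, 4); bin 2: (10, 0, 5) -> (10, 2.5, 5)
  m$values <- rbind(c(0, 2, 4), c(10, 0, 5))
  out <- replace_zeros(m)
  expect_equal(unname(out$values), rbind(c(1, 2, 4), c(10, 2.5, 5)))
  expect_equal(attr(out, "n_replaced"), 2L)
  expect_true(all(out$values >= m$values, na.rm = TRUE))

  # no zeros: unchanged, count 0
  out2 <- replace_zeros(out)
  expect_equal(out2$values, out$values)
  expect_equal(attr(out2, "n_replaced"), 0L)

  # an all-zero bin cannot be repaired
  m$values[1, ] <- 0
  expect_error(replace_zeros(m), "non-zero")
})

test_that("covariate mean imputation fills speed and direction arithmetically", {
  w <- wind_series(ws = c(2, NA, 4), wd = c(350, NA, 10))
  out <- suppressWarnings(impute_covariates_mean(w))
  expect_equal(out$ws, c(2, 3, 4))
  expect_equal(out$wd, c(350, 180, 10))   # plain mean, non-circular convention
  expect_equal(attr(out, "n_imputed"), c(ws = 1L, wd = 1L))

  # circular option lands at the wrapped mean instead
  out_c <- suppressWarnings(impute_covariates_mean(w, circular = TRUE))
  circ_dist <- min(out_c$wd[2], 360 - out_c$wd[2])
  expect_lt(circ_dist, 1e-6)

  # identity on complete series
  w2 <- wind_series(ws = c(1, 2), wd = c(10, 20))
  expect_equal(impute_covariates_mean(w2)$ws, c(1, 2))

  expect_error(impute_covariates_mean(
    wind_series(ws = c(NA_real_, NA_real_), wd = c(1, 2))), "missing")
  expect_warning(impute_covariates_mean(
    wind_series(ws = c(rep(1, 5), NA), wd = rep(10, 6))), "5%")
})

test_that("replanning aggregated output yields no further merging", {
  set.seed(21)
  vals <- matrix(rnorm(6 * 400, 20, 2), 6, 400)
  vals[2, ] <- vals[1, ] + rnorm(400, 0, 0.05)
  vals[5, ] <- vals[4, ] + rnorm(400, 0, 0.05)
  raw <- raw_pnsd(hourly_times(400), c(10, 15, 30, 60, 90, 200), vals)
  plan <- plan_bin_aggregation(raw, 0.97)
  agg <- apply_bin_aggregation(raw, plan)
  replan <- plan_bin_aggregation(agg, 0.97)
  expect_true(all(lengths(replan$groups) == 1))
})

test_that("reduction bookkeeping computes cells and percent reduction", {
  red <- reduction_summary(100, 10, 50, 5)
  expect_equal(red$cells_pre, 1000)
  expect_equal(red$cells_post, 250)
  expect_equal(red$percent_reduction, 75)
})
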