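# Builds a minimal posterior_draws object by hand. Wind is pinned at the
# kernel modes with huge bandwidths so every kernel weight is exactly 1 and
# the mixing weights follow directly from the chosen break proportions.
# eta_list: list over draws of (K-1) x T matrices; lam_list: list of P x K
make_draws <- function(eta_list, lam_list, c_mat,
                       day0 = as.Date("2019-01-25"), blocks_per_day = 7) {
  n <- length(eta_list)
  Km1 <- nrow(eta_list[[1]]); K <- Km1 + 1L
  Tt <- ncol(eta_list[[1]])
  P <- nrow(lam_list[[1]])
  chain <- list(
    lam = do.call(rbind, lapply(lam_list, as.vector)),
    eta = do.call(rbind, lapply(eta_list, as.vector)),
    c = c_mat,
    sigma = matrix(0.1, n, P),
    mu_c = rep(0, n), sigma_c = rep(1, n), alpha = rep(1, n),
    nu1 = matrix(5, n, Km1), nu2 = matrix(180, n, Km1),
    h1 = matrix(1e6, n, Km1), h2 = matrix(1e6, n, Km1),
    imputed_y = matrix(0, n, 0),
    acceptance = c(block = 0.3), seed = 1)
  day <- day0 + (seq_len(Tt) - 1L) %/% blocks_per_day
  block <- ((seq_len(Tt) - 1L) %% blocks_per_day) + 1L
  structure(list(
    chains = list(chain), miss_idx = integer(0),
    P = P, K = K, T = Tt,
    meta = list(times = as.POSIXct(day, tz = "UTC") + block * 3600,
                day = day, block = block,
                block_labels = paste0("b", seq_len(blocks_per_day)),
                bin_labels = exp(seq(log(15), log(600), length.out = P))),
    wind = wind_series(ws = rep(5, Tt), wd = rep(180, Tt)),
    config = local({ cfg <- model_config(K = max(K, 2L)); cfg$K <- K; cfg }),
    settings = mcmc_settings(seed = 1)),
    class = "posterior_draws")
}

unit_lam <- function(P, K) {
  lam <- matrix(1 / P, P, K)
  lam
}

test_that("contribution shares average per-draw shares and sum to one", {
  # two draws with shares (0.6, 0.4) and (0.4, 0.6) -> (0.5, 0.5)
  Tt <- 5
  e1 <- matrix(0.6, 1, Tt); e2 <- matrix(0.4, 1, Tt)
  dr <- make_draws(list(e1, e2), list(unit_lam(4, 2), unit_lam(4, 2)),
                   matrix(10, 2, Tt))
  sh <- source_shares(dr)
  expect_equal(sh, c(0.5, 0.5))
  expect_equal(sum(sh), 1, tolerance = 1e-12)

  # a single-component model trivially owns everything
  dr1 <- make_draws(list(matrix(numeric(0), 0, Tt)),
                    list(unit_lam(4, 1)), matrix(3, 1, Tt))
  expect_equal(source_shares(dr1), 1)
})

test_that("the non-empty rule counts shares above the threshold", {
  shares <- c(0.30, 0.25, 0.20, 0.15, 0.09, 0.005, 0.005)
  expect_equal(count_nonempty(shares, 0.01), 5)
  expect_equal(count_nonempty(shares, 0), 7)
  expect_equal(count_nonempty(shares, 1), 0)
  expect_true(all(diff(vapply(seq(0, 0.3, by = 0.02), count_nonempty,
                              integer(1), shares = shares)) <= 0))
})

test_that("label alignment finds exact permutations and matches brute force", {
  set.seed(33)
  A <- matrix(rgamma(5 * 4, 1, 1), 5, 4)
  A <- sweep(A, 2, colSums(A), "/")
  perm_true <- c(3L, 1L, 4L, 2L)
  B <- A[, order(perm_true)]
  m <- match_profiles(A, B)
  expect_equal(m$perm, perm_true)
  expect_equal(m$similarity, rep(1, 4), tolerance = 1e-12)
  # identity when identical
  expect_equal(match_profiles(A, A)$perm, 1:4)

  # optimality against exhaustive search for K up to 6, square and
  # rectangular
  for (seed in 1:12) {
    set.seed(seed)
    KA <- sample(2:5, 1); KB <- KA + sample(0:2, 1)
    if (KB > 6) KB <- 6
    A <- matrix(runif(6 * KA), 6, KA)
    B <- matrix(runif(6 * KB), 6, KB)
    got <- match_profiles(A, B)
    ref <- brute_force_match(A, B)
    expect_equal(sum(got$similarity), ref$total, tolerance = 1e-12)
  }
})

test_that("aligning two runs uses posterior-mean profiles", {
  set.seed(44)
  lam <- matrix(rgamma(4 * 3, 1, 1), 4, 3)
  lam <- sweep(lam, 2, colSums(lam), "/")
  e <- matrix(0.5, 2, 6)
  d_a <- make_draws(list(e), list(lam), matrix(1, 1, 6))
  d_b <- make_draws(list(e), list(lam[, c(2, 3, 1)]), matrix(1, 1, 6))
  al <- align_labels(d_a, d_b)
  expect_equal(al$perm, c(3L, 1L, 2L))
  expect_equal(al$similarity, rep(1, 3), tolerance = 1e-12)
})

test_that("temporal summaries group by block, weekday and month", {
  Tt <- 28            # 4 days x 7 blocks
  e <- matrix(0.5, 1, Tt)
  c_row <- rep(2, Tt)
  dr <- make_draws(list(e), list(unit_lam(3, 2)), matrix(c_row, 1))
  ts <- temporal_summary(dr)
  tot_block <- ts[ts$series == "total" & ts$grouping == "block", ]
  expect_true(all(abs(tot_block$mean - 2) < 1e-12))
  expect_equal(sum(tot_block$n), Tt)

  # doubled weekday level shows up as a ratio of two
  day <- dr$meta$day
  wkday <- as.integer(format(day, "%u")) <= 5
  c_row2 <- ifelse(wkday, 4, 2)
  dr2 <- make_draws(list(e), list(unit_lam(3, 2)), matrix(c_row2, 1))
  ts2 <- temporal_summary(dr2)
  wk <- ts2[ts2$series == "total" & ts2$grouping == "weekday", ]
  mon <- wk$mean[wk$level == "Mon"]
  sat <- wk$mean[wk$level == "Sat"]
  expect_equal(mon / sat, 2)
})

test_that("pollutant correlations behave at the exact and null extremes", {
  Tt <- 1000
  set.seed(55)
  e <- matrix(plogis(rnorm(Tt, 0, 1)), 1, Tt)
  c_row <- exp(rnorm(Tt, 2, 0.4))
  dr <- make_draws(list(e), list(cbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))),
                   matrix(c_row, 1))
  f <- posterior_mean_f(dr)
  pol <- data.frame(mirror = f[1, ], noise = rnorm(Tt))
  pc <- pollutant_correlations(dr, pol)
  expect_equal(pc["source_1", "mirror"], 1, tolerance = 1e-12)
  expect_lt(abs(pc["source_1", "noise"]), 0.1)
  expect_true(all(pc >= -1 & pc <= 1))
  pol_bad <- data.frame(x = rep(NA_real_, Tt))
  expect_error(pollutant_correlations(dr, pol_bad), "entirely missing")
})

test_that("inter-source correlations are symmetric with unit diagonal", {
  Tt <- 50
  set.seed(66)
  e <- matrix(plogis(rnorm(2 * Tt)), 2, Tt)
  lam <- matrix(rgamma(4 * 3, 1, 1), 4, 3)
  lam <- sweep(lam, 2, colSums(lam), "/")
  dr <- make_draws(list(e), list(lam), matrix(exp(rnorm(Tt)), 1))
  ic <- intersource_correlations(dr)
  expect_equal(ic, t(ic), tolerance = 1e-12)
  expect_equal(unname(diag(ic)), rep(1, 3))

  dr1 <- make_draws(list(matrix(numeric(0), 0, Tt)), list(unit_lam(3, 1)),
                    matrix(exp(rnorm(Tt)), 1))
  expect_equal(unname(intersource_correlations(dr1)), matrix(1, 1, 1))
})

test_that("kernel surfaces are bounded, periodic, and peak at tight modes", {
  Tt <- 10
  e <- matrix(0.5, 2, Tt)
  dr <- make_draws(list(e), list(unit_lam(3, 3)), matrix(1, 1, Tt))
  # posterior concentrated at nu1 = 5, nu2 = 180 with broad bandwidths
  surf <- kernel_surface(dr, 1, ws_grid = c(0, 5, 10),
                         wd_grid = c(0, 90, 180, 270, 360))
  expect_true(all(surf$surface > 0 & surf$surface <= 1))
  expect_equal(surf$surface[, 1], surf$surface[, 5], tolerance = 1e-12)
  expect_equal(surf$surface[2, 3], 1, tolerance = 1e-9)
  expect_error(kernel_surface(dr, 3), "no wind kernel")
})

test_that("summarize_sources bundles the panel outputs coherently", {
  Tt <- 14
  set.seed(9)
  e <- matrix(plogis(rnorm(2 * Tt)), 2, Tt)
  lam <- matrix(rgamma(4 * 3, 1, 1), 4, 3)
  lam <- sweep(lam, 2, colSums(lam), "/")
  dr <- make_draws(list(e, e), list(lam, lam), matrix(exp(rnorm(2 * Tt)), 2))
  sm <- summarize_sources(dr)
  expect_s3_class(sm, "source_summary")
  expect_equal(sum(sm$shares), 1, tolerance = 1e-6)
  expect_equal(nrow(sm$profiles), 4 * 3)
  expect_true(all(sm$profiles$lower <= sm$profiles$mean + 1e-12))
  expect_null(sm$pollutant_cor)
})
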