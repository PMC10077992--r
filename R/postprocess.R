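# contribution shares per draw: share_k = sum_t f[k,t] / sum_t c_t
.shares_by_draw <- function(draws, chain = 1L) {
  cc <- draws$chains[[chain]]
  n <- nrow(cc$c); K <- draws$K; Tt <- draws$T
  out <- matrix(0, n, K)
  for (i in seq_len(n)) {
    f <- .draw_f(draws, cc, i)
    out[i, ] <- rowSums(f) / sum(cc$c[i, ])
  }
  out
}

.draw_f <- function(draws, cc, i) {
  K <- draws$K; Tt <- draws$T
  eta <- matrix(cc$eta[i, ], K - 1L, Tt)
  w <- matrix(0, K - 1L, Tt)
  for (k in seq_len(K - 1L))
    w[k, ] <- wind_kernel(draws$wind$ws, draws$wind$wd,
                          cc$nu1[i, k], cc$nu2[i, k],
                          cc$h1[i, k], cc$h2[i, k])
  xi <- rbind(w * eta, rep(1, Tt))
  s <- .stick_break_mat(xi)
  s * rep(cc$c[i, ], each = K)
}

#' Posterior mean of the source contributions f
#'
#' @param draws a `posterior_draws` object.
#' @return K x T matrix of posterior-mean contributions, pooled over chains.
#' @export
posterior_mean_f <- function(draws) {
  acc <- matrix(0, draws$K, draws$T)
  n_tot <- 0L
  for (cc in draws$chains) {
    n <- nrow(cc$c)
    for (i in seq_len(n)) acc <- acc + .draw_f(draws, cc, i)
    n_tot <- n_tot + n
  }
  acc / n_tot
}

#' Posterior mean contribution share of each component
#'
#' Per draw, the share of the total concentration attributed to component k
#' is `sum_t f[k,t] / sum_t c_t`; shares are averaged over draws (so they sum
#' to one exactly per draw, and to one up to Monte Carlo rounding after
#' averaging).
#'
#' @param draws a `posterior_draws` object.
#' @return numeric vector of length K summing to 1.
#' @export
source_shares <- function(draws) {
  sh <- do.call(rbind, lapply(seq_along(draws$chains),
                              function(ch) .shares_by_draw(draws, ch)))
  colMeans(sh)
}

#' Count the non-empty sources
#'
#' The number of components whose contribution share exceeds the threshold --
#' the empirical rule by which the actual number of sources is read off a
#' truncated fit (the headline figure uses a 1% limit).
#'
#' @param shares vector of contribution shares (from [source_shares()]).
#' @param threshold share threshold in `[0, 1]` (0 counts every component,
#'   1 none).
#' @return integer count.
#' @export
count_nonempty <- function(shares, threshold = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1)
  sum(shares > threshold)
}

.cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Optimal matching of source profiles
#'
#' Assigns each column of `A` a distinct column of `B` maximizing the total
#' cosine similarity between the matched columns (an exact assignment solved
#' by dynamic programming over subsets). `A` may have fewer columns than `B`.
#'
#' @param A P x KA matrix (e.g. true or reference profiles).
#' @param B P x KB matrix with `KB >= KA`.
#' @return list with `perm` (for each column j of `A`, the matched column of
#'   `B`) and `similarity` (the matched cosine similarities).
#' @export
match_profiles <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  KA <- ncol(A); KB <- ncol(B)
  stopifnot(nrow(A) == nrow(B), KA <= KB, KB <= 20L)
  C <- matrix(0, KA, KB)
  for (j in seq_len(KA)) for (b in seq_len(KB)) C[j, b] <- .cosine(A[, j], B[, b])
  # DP over subsets of B's columns: a state is the set of used B columns;
  # its size equals the number of A columns already assigned (in order).
  nS <- bitwShiftL(1L, KB)
  sizes <- vapply(seq_len(nS) - 1L,
                  function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(KB - 1))) > 0L),
                  integer(1))
  best <- rep(-Inf, nS); best[1L] <- 0
  parent <- integer(nS)
  for (m in order(sizes)) {
    mask <- m - 1L
    sz <- sizes[m]
    if (sz >= KA || !is.finite(best[m])) next
    j <- sz + 1L
    for (b in seq_len(KB)) {
      bit <- bitwShiftL(1L, b - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      m2 <- bitwOr(mask, bit) + 1L
      val <- best[m] + C[j, b]
      if (val > best[m2]) {
        best[m2] <- val
        parent[m2] <- b
      }
    }
  }
  full <- which(sizes == KA)
  m_star <- full[which.max(best[full])] - 1L
  perm <- integer(KA)
  for (j in rev(seq_len(KA))) {
    b <- parent[m_star + 1L]
    perm[j] <- b
    m_star <- bitwAnd(m_star, bitwNot(bitwShiftL(1L, b - 1L)))
  }
  list(perm = perm, similarity = C[cbind(seq_len(KA), perm)])
}

#' Align component labels between two runs
#'
#' Finds the permutation of run `b`'s component labels that maximizes the
#' total cosine similarity between the posterior-mean profile columns of the
#' two runs (exact assignment), as needed to compare independent fits of the
#' same data.
#'
#' @param draws_a,draws_b `posterior_draws` objects with equal P and K.
#' @return list with `perm` (column of `b` matched to each column of `a`)
#'   and `similarity` per matched pair.
#' @export
align_labels <- function(draws_a, draws_b) {
  stopifnot(draws_a$P == draws_b$P, draws_a$K == draws_b$K)
  match_profiles(profile_mean(draws_a), profile_mean(draws_b))
}

#' Posterior mean profiles
#'
#' @param draws a `posterior_draws` object.
#' @return P x K matrix of posterior-mean profile columns (pooled chains).
#' @export
profile_mean <- function(draws) {
  lam <- do.call(rbind, lapply(draws$chains, `[[`, "lam"))
  matrix(colMeans(lam), draws$P, draws$K)
}

#' Posterior profile summaries per source
#'
#' Posterior mean, central 95% interval and logit-transformed mean of each
#' profile column.
#'
#' @param draws a `posterior_draws` object.
#' @return data.frame with columns `source`, `bin_nm`, `mean`, `lower`,
#'   `upper`, `logit_mean`.
#' @export
profile_summary <- function(draws) {
  lam <- do.call(rbind, lapply(draws$chains, `[[`, "lam"))
  m <- colMeans(lam)
  lo <- apply(lam, 2, stats::quantile, probs = 0.025)
  hi <- apply(lam, 2, stats::quantile, probs = 0.975)
  lam_m <- pmin(pmax(m, 1e-12), 1 - 1e-12)
  data.frame(source = rep(seq_len(draws$K), each = draws$P),
             bin_nm = rep(draws$meta$bin_labels, draws$K),
             mean = m, lower = lo, upper = hi,
             logit_mean = log(lam_m / (1 - lam_m)),
             row.names = NULL)
}

#' Temporal summaries of total and per-source contributions
#'
#' Groups the posterior-mean total concentration series and each
#' posterior-mean contribution series by within-day block, weekday and
#' month, reporting per-group boxplot statistics (mean and quartiles across
#' the time steps in the group).
#'
#' @param draws a `posterior_draws` object (carries the time metadata of the
#'   panel it was fitted to).
#' @return data.frame with columns `series` (`"total"` or `"source_k"`),
#'   `grouping` (`"block"`, `"weekday"`, `"month"`), `level`, `n`, `mean`,
#'   `q25`, `median`, `q75`.
#' @export
temporal_summary <- function(draws) {
  f <- posterior_mean_f(draws)
  c_mean <- colMeans(do.call(rbind, lapply(draws$chains, `[[`, "c")))
  meta <- draws$meta
  wk <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  groupings <- list(
    block = factor(meta$block_labels[meta$block],
                   levels = meta$block_labels),
    weekday = factor(wk[as.integer(format(meta$day, "%u"))], levels = wk),
    month = factor(month.abb[as.integer(format(meta$day, "%m"))],
                   levels = month.abb))
  series <- c(list(total = c_mean),
              stats::setNames(lapply(seq_len(draws$K), function(k) f[k, ]),
                              paste0("source_", seq_len(draws$K))))
  rows <- list()
  for (sn in names(series)) {
    x <- series[[sn]]
    for (gn in names(groupings)) {
      g <- droplevels(groupings[[gn]])
      qs <- tapply(x, g, stats::quantile, probs = c(0.25, 0.5, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        series = sn, grouping = gn, level = levels(g),
        n = as.integer(table(g)),
        mean = as.numeric(tapply(x, g, mean)),
        q25 = vapply(qs, `[[`, numeric(1), 1L),
        median = vapply(qs, `[[`, numeric(1), 2L),
        q75 = vapply(qs, `[[`, numeric(1), 3L),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Correlation of source contributions with external pollutants
#'
#' Pearson correlation between each posterior-mean contribution series and
#' each pollutant series, pairwise-complete over pollutant missingness.
#'
#' @param draws a `posterior_draws` object.
#' @param pollutants data.frame or matrix of aligned pollutant series
#'   (T rows).
#' @return K x J matrix of correlations.
#' @export
pollutant_correlations <- function(draws, pollutants) {
  pol <- as.matrix(pollutants)
  stopifnot(nrow(pol) == draws$T)
  if (any(colSums(!is.na(pol)) == 0))
    stop(sprintf("pollutant entirely missing: %s",
                 paste(colnames(pol)[colSums(!is.na(pol)) == 0], collapse = ", ")))
  f <- posterior_mean_f(draws)
  out <- stats::cor(t(f), pol, use = "pairwise.complete.obs")
  rownames(out) <- paste0("source_", seq_len(draws$K))
  out
}

#' Correlation matrix between the sources over time
#'
#' Pearson correlations between the posterior-mean contribution series;
#' symmetric with unit diagonal.
#'
#' @param draws a `posterior_draws` object.
#' @return K x K correlation matrix.
#' @export
intersource_correlations <- function(draws) {
  f <- posterior_mean_f(draws)
  out <- stats::cor(t(f))
  diag(out) <- 1
  dimnames(out) <- list(paste0("source_", seq_len(draws$K)),
                        paste0("source_", seq_len(draws$K)))
  out
}

#' Posterior-mean wind-kernel surface of one source
#'
#' Posterior mean of the wind kernel of component `k` over a wind speed by
#' wind direction grid. The K-th component takes the remaining stick and has
#' no kernel.
#'
#' @param draws a `posterior_draws` object.
#' @param k component index, `1 <= k <= K-1`.
#' @param ws_grid,wd_grid grid vectors (m/s; degrees).
#' @return list with `ws`, `wd` and `surface` (length(ws) x length(wd)).
#' @export
kernel_surface <- function(draws, k,
                           ws_grid = seq(0, max(draws$wind$ws), length.out = 25),
                           wd_grid = seq(0, 360, by = 15)) {
  if (k >= draws$K || k < 1)
    stop(sprintf(paste("component %d has no wind kernel: under the finite",
                       "truncation only components 1..%d carry kernels and",
                       "component %d takes the remaining probability"),
                 k, draws$K - 1L, draws$K))
  grid_ws <- matrix(rep(ws_grid, length(wd_grid)), length(ws_grid))
  grid_wd <- matrix(rep(wd_grid, each = length(ws_grid)), length(ws_grid))
  acc <- matrix(0, length(ws_grid), length(wd_grid))
  n_tot <- 0L
  for (cc in draws$chains) {
    n <- nrow(cc$c)
    for (i in seq_len(n))
      acc <- acc + wind_kernel(grid_ws, grid_wd, cc$nu1[i, k], cc$nu2[i, k],
                               cc$h1[i, k], cc$h2[i, k])
    n_tot <- n_tot + n
  }
  list(ws = ws_grid, wd = wd_grid, surface = acc / n_tot)
}

#' Full source characterization
#'
#' Bundles the postprocessing outputs: shares and non-empty count, profile
#' summaries, temporal summaries, inter-source correlations, and (when
#' pollutant series are supplied) source-pollutant correlations.
#'
#' @param draws a `posterior_draws` object.
#' @param pollutants optional aligned pollutant data.frame.
#' @param threshold share threshold for the non-empty rule.
#' @return list of class `source_summary` with elements `shares`,
#'   `n_sources`, `profiles`, `temporal`, `intersource_cor`,
#'   `pollutant_cor` (or `NULL`).
#' @export
summarize_sources <- function(draws, pollutants = NULL,
                              threshold = draws$config$source_threshold) {
  shares <- source_shares(draws)
  structure(list(
    shares = shares,
    n_sources = count_nonempty(shares, threshold),
    threshold = threshold,
    profiles = profile_summary(draws),
    temporal = temporal_summary(draws),
    intersource_cor = intersource_correlations(draws),
    pollutant_cor = if (!is.null(pollutants))
      pollutant_correlations(draws, pollutants)), class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat(sprintf("<source_summary> %d non-empty sources at %.1f%% threshold\n",
              x$n_sources, 100 * x$threshold))
  sh <- sort(x$shares, decreasing = TRUE)
  cat("  shares:", paste(sprintf("%.1f%%", 100 * sh), collapse = " "), "\n")
  invisible(x)
}
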