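# Independent oracles: scalar, loop-based reimplementations of the model
# densities from the textbook formulas, kept deliberately naive so they share
# no code path with the package internals.

oracle_stick <- function(xi) {
  K <- length(xi)
  s <- numeric(K)
  for (k in seq_len(K)) {
    prod_term <- 1
    if (k > 1) for (l in seq_len(k - 1)) prod_term <- prod_term * (1 - xi[l])
    s[k] <- xi[k] * prod_term
  }
  s
}

oracle_loglik <- function(state, data, wind) {
  P <- nrow(data$values); Tt <- ncol(data$values); K <- ncol(state$lam)
  total <- 0
  for (t in seq_len(Tt)) {
    xi <- numeric(K)
    for (k in seq_len(K - 1)) {
      wk <- exp(-(state$nu1[k] - wind$ws[t])^2 / (2 * state$h1[k])) *
        exp(-sin((state$nu2[k] - wind$wd[t]) * pi / 360)^2 / (2 * state$h2[k]))
      xi[k] <- wk * state$eta[k, t]
    }
    xi[K] <- 1
    s <- oracle_stick(xi)
    for (p in seq_len(P)) {
      if (data$missing_mask[p, t]) next
      mu_pt <- 0
      for (k in seq_len(K)) mu_pt <- mu_pt + state$lam[p, k] * s[k] * state$c_tot[t]
      z <- (log(data$values[p, t]) - log(mu_pt)) / state$sigma[p]
      total <- total - log(state$sigma[p]) - 0.5 * log(2 * pi) - 0.5 * z^2
    }
  }
  total
}

oracle_logprior <- function(state, config, wind) {
  nu1_upper <- config$nu1_upper
  if (is.na(nu1_upper)) nu1_upper <- max(wind$ws)
  lgamma_d <- function(x, shape, rate)
    shape * log(rate) - lgamma(shape) + (shape - 1) * log(x) - rate * x
  lnorm_d <- function(x, m, s) -log(s) - 0.5 * log(2 * pi) - (x - m)^2 / (2 * s^2)
  lp <- lnorm_d(state$mu_c, config$prior_mu_c[1], config$prior_mu_c[2])
  lp <- lp + lgamma_d(state$sigma_c, config$prior_sigma_c[1], config$prior_sigma_c[2])
  for (p in seq_along(state$sigma))
    lp <- lp + lgamma_d(state$sigma[p]^2, config$prior_sigma_sq[1],
                        config$prior_sigma_sq[2])
  a <- config$prior_lambda
  P <- nrow(state$lam)
  for (k in seq_len(ncol(state$lam))) {
    lp <- lp + lgamma(P * a) - P * lgamma(a)
    for (p in seq_len(P)) lp <- lp + (a - 1) * log(state$lam[p, k])
  }
  lp <- lp + lgamma_d(state$alpha, config$prior_alpha[1], config$prior_alpha[2])
  # Beta(1, alpha) density: alpha * (1 - x)^(alpha - 1)
  for (k in seq_len(nrow(state$eta)))
    for (t in seq_len(ncol(state$eta)))
      lp <- lp + log(state$alpha) + (state$alpha - 1) * log(1 - state$eta[k, t])
  # Gamma on 1/h evaluated in h-space (Jacobian 1/h^2)
  for (h in c(state$h1, state$h2))
    lp <- lp + lgamma_d(1 / h, config$prior_inv_h[1], config$prior_inv_h[2]) -
      2 * log(h)
  lp <- lp - length(state$nu1) * log(nu1_upper) - length(state$nu2) * log(360)
  for (t in seq_along(state$c_tot))
    lp <- lp + lnorm_d(log(state$c_tot[t]), state$mu_c, state$sigma_c)
  lp
}

# all permutations of 1..n, as a list
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# brute-force optimal assignment of A's columns to distinct columns of B
brute_force_match <- function(A, B) {
  KA <- ncol(A); KB <- ncol(B)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  best <- -Inf; best_perm <- NULL
  idx_sets <- utils::combn(KB, KA, simplify = FALSE)
  for (set in idx_sets) {
    for (pm in all_perms(KA)) {
      perm <- set[pm]
      val <- sum(vapply(seq_len(KA), function(j) cosv(A[, j], B[, perm[j]]),
                        numeric(1)))
      if (val > best) { best <- val; best_perm <- perm }
    }
  }
  list(perm = best_perm, total = best)
}

make_tiny_state <- function(P = 3, K = 3, Tt = 4, seed = 1) {
  set.seed(seed)
  lam <- matrix(rgamma(P * K, 1, 1), P, K)
  lam <- sweep(lam, 2, colSums(lam), "/")
  parameter_state(
    lam = lam,
    eta = matrix(runif((K - 1) * Tt, 0.05, 0.95), K - 1, Tt),
    c_tot = exp(rnorm(Tt, 5, 0.3)),
    mu_c = rnorm(1, 5, 1), sigma_c = runif(1, 0.3, 1),
    sigma = runif(P, 0.1, 0.6), alpha = runif(1, 0.5, 3),
    nu1 = runif(K - 1, 0.5, 3), nu2 = runif(K - 1, 0, 359),
    h1 = runif(K - 1, 0.5, 4), h2 = runif(K - 1, 0.2, 2))
}

make_tiny_data <- function(P = 3, Tt = 4, seed = 2, missing = NULL) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(P * Tt, 4, 0.5)), P, Tt)
  mask <- matrix(FALSE, P, Tt)
  if (!is.null(missing)) mask[missing] <- TRUE
  pnsd_matrix(times = as.POSIXct("2019-01-25", tz = "UTC") + (seq_len(Tt) - 1) * 3600,
              bin_labels = exp(seq(log(15), log(600), length.out = P)),
              values = vals, block = rep(1L, Tt), missing_mask = mask)
}

make_tiny_wind <- function(Tt = 4, seed = 3) {
  set.seed(seed)
  wind_series(ws = runif(Tt, 0.5, 4), wd = runif(Tt, 0, 359.9))
}
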