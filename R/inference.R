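#' MCMC settings
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded (and during which proposal scales
#'   adapt; adaptation is frozen afterwards so the kept draws come from a
#'   fixed kernel).
#' @param thin keep one draw in `thin` after burn-in.
#' @param seed master integer seed; chain `i` uses `seed + (i-1)*1000`.
#' @param n_chains number of independent chains.
#' @param adapt_batch iterations per adaptation batch during burn-in.
#' @param n_sweeps full update sweeps composing one iteration (several
#'   sweeps per iteration improve mixing along the likelihood ridges of the
#'   truncated mixture at fixed iteration counts).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 4000L, burn_in = 2000L, thin = 2L,
                          seed = 1L, n_chains = 1L, adapt_batch = 50L,
                          n_sweeps = 3L) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_chains >= 1L, adapt_batch >= 10L,
            n_sweeps >= 1L)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 n_chains = as.integer(n_chains),
                 adapt_batch = as.integer(adapt_batch),
                 n_sweeps = as.integer(n_sweeps)),
            class = "mcmc_settings")
}

.clip_eta <- function(e) pmin(pmax(e, 1e-12), 1 - 1e-12)

#' Data-driven initial state
#'
#' Builds a valid starting [parameter_state()] from the data. Total
#' concentrations come from observed column totals (missing columns take
#' the geometric mean of observed totals). Profiles and allocations are
#' obtained by seeding diverse observed columns (furthest-point archetypes),
#' refining them with multiplicative Kullback-Leibler nonnegative
#' factorization at every rank up to K, and selecting the rank by BIC under
#' the model's log-normal error; the largest component is placed in the
#' remainder slot, the others fill the leading slots, and unused slots
#' start empty with narrow kernels. Break proportions are recovered by
#' inverting the allocation through the stick-breaking map; kernels of
#' active components are moment-matched to their allocation over the wind
#' series; measurement sds come from per-bin sds of log concentrations.
#' Starting parsimonious matters: a mass split between components with the
#' same profile is likelihood-neutral and hard to undo with local moves.
#'
#' @param data a [pnsd_matrix()].
#' @param wind a [wind_series()].
#' @param config a [model_config()].
#' @param seed integer seed (the returned state is a deterministic function
#'   of data and seed).
#' @return a [parameter_state()] with finite posterior density.
#' @export
initialize_state <- function(data, wind, config, seed) {
  if (all(data$missing_mask)) stop("cannot initialize from all-missing data")
  set.seed(seed)
  P <- nrow(data$values); Tt <- ncol(data$values); K <- config$K
  obs <- !data$missing_mask
  v0 <- data$values; v0[!obs] <- 0
  ctot <- colSums(v0)
  full <- colSums(obs) > 0
  gm <- exp(mean(log(ctot[full & ctot > 0])))
  ctot[!full | ctot <= 0] <- gm
  rowm <- rowSums(v0) / pmax(rowSums(obs), 1)
  rowm[rowm <= 0] <- min(rowm[rowm > 0]) / 2
  meanprof <- rowm / sum(rowm)
  # seed the K profile columns with diverse observed columns (furthest-point
  # archetypes on the simplex), blended with the mean profile to stay in the
  # interior, then lightly perturbed; near-identical starting columns leave
  # the sampler in blend modes where one component carries a mixture of
  # sources
  cand <- data$values[, full, drop = FALSE]
  cand <- sweep(cand, 2, colSums(cand), "/")
  picks <- integer(0)
  d2mean <- colSums((cand - meanprof)^2)
  picks[1] <- which.max(d2mean)
  while (length(picks) < min(K, ncol(cand))) {
    dmin <- rep(Inf, ncol(cand))
    for (j in picks)
      dmin <- pmin(dmin, colSums((cand - cand[, j])^2))
    picks <- c(picks, which.max(dmin))
  }
  picks <- rep_len(picks, K)
  lam <- matrix(0, P, K)
  for (k in seq_len(K)) {
    col <- (0.75 * cand[, picks[k]] + 0.25 * meanprof) *
      exp(stats::rnorm(P, 0, 0.05))
    lam[, k] <- col / sum(col)
  }
  # refine profiles and allocations with multiplicative (KL) nonnegative
  # factorization from the archetype seed, at every rank r = 1..K; choose
  # the rank by BIC under the model's log-normal error so the chain starts
  # with a parsimonious set of active components. A mass split between two
  # components with the same profile is likelihood-neutral and hard to undo
  # by local moves, so starting with surplus active components leaves the
  # sampler in mass-split configurations.
  Y <- v0
  Y[, !full] <- outer(meanprof, ctot[!full])
  nmf_fit <- function(r, iters = 200L) {
    W <- matrix(0, P, r)
    for (k in seq_len(r)) {
      col <- 0.75 * cand[, picks[k]] + 0.25 * meanprof
      W[, k] <- col / sum(col)
    }
    Hr <- matrix(rep(ctot / r, each = r), r, Tt)
    for (it in seq_len(iters)) {
      WH <- pmax(W %*% Hr, 1e-12)
      Hr <- Hr * (t(W) %*% (Y / WH))
      WH <- pmax(W %*% Hr, 1e-12)
      W <- W * ((Y / WH) %*% t(Hr)) /
        pmax(matrix(rowSums(Hr), P, r, byrow = TRUE), 1e-12)
      cs <- colSums(W)
      Hr <- Hr * cs
      W <- sweep(W, 2, pmax(cs, 1e-12), "/")
    }
    list(W = W, H = Hr)
  }
  n_obs_cols <- sum(full)
  best <- NULL; best_bic <- Inf
  for (r in seq_len(K)) {
    fit <- nmf_fit(r)
    lres <- log(data$values[, full, drop = FALSE]) -
      log(pmax((fit$W %*% fit$H)[, full, drop = FALSE], 1e-12))
    sig_r <- pmax(sqrt(rowMeans(lres^2, na.rm = TRUE)), 1e-4)
    ll <- sum(stats::dnorm(lres, 0, sig_r, log = TRUE), na.rm = TRUE)
    npar <- r * (P - 1) + r * n_obs_cols + P
    bic <- -2 * ll + npar * log(P * n_obs_cols)
    if (bic < best_bic) { best_bic <- bic; best <- fit }
  }
  r_star <- ncol(best$W)
  # assemble the K slots: the largest active component lands in the
  # remainder slot K (it needs neither kernel nor breaks there), the rest
  # fill the leading kerneled slots in decreasing order, and unused slots
  # sit just before the remainder with no allocation
  ord <- order(rowSums(best$H), decreasing = TRUE)
  lam <- matrix(meanprof, P, K)
  lam <- lam * exp(stats::rnorm(P * K, 0, 0.05))
  lam <- sweep(lam, 2, colSums(lam), "/")
  H <- matrix(0, K, Tt)
  if (r_star > 1L)
    for (i in seq_len(r_star - 1L)) {
      lam[, i] <- best$W[, ord[i + 1L]]
      H[i, ] <- best$H[ord[i + 1L], ]
    }
  lam[, K] <- best$W[, ord[1L]]
  H[K, ] <- best$H[ord[1L], ]
  # keep profiles in the simplex interior (multiplicative updates can
  # underflow entries to zero)
  lam <- pmax(lam, 1e-10)
  lam <- sweep(lam, 2, colSums(lam), "/")
  tot <- rowSums(H)
  S <- sweep(pmax(H, 1e-12), 2, colSums(pmax(H, 1e-12)), "/")
  S <- pmax(S, 1e-6)
  S <- sweep(S, 2, colSums(S), "/")
  sigma <- apply(log(data$values), 1, stats::sd, na.rm = TRUE)
  sigma[!is.finite(sigma) | sigma < 0.05] <- 0.5
  # kernels: moment-matched to each active component's allocation over the
  # wind series; near-empty components get narrow kernels (the shapes the
  # vague inverse-bandwidth prior favors), which keeps them locked off
  active <- tot[seq_len(K - 1L)] > 0.01 * sum(tot)
  nu1 <- numeric(K - 1L); nu2 <- numeric(K - 1L)
  h1 <- numeric(K - 1L); h2 <- numeric(K - 1L)
  spread2 <- seq(0, 360, length.out = K)[-K]
  for (k in seq_len(K - 1L)) {
    if (active[k]) {
      wt <- H[k, ] / sum(H[k, ])
      nu1[k] <- sum(wt * wind$ws)
      h1[k] <- max(sum(wt * (wind$ws - nu1[k])^2), 1)
      rad <- wind$wd * pi / 180
      nu2[k] <- (atan2(sum(wt * sin(rad)), sum(wt * cos(rad))) * 180 / pi) %% 360
      h2[k] <- max(sum(wt * sin((nu2[k] - wind$wd) * pi / 360)^2), 0.5)
    } else {
      nu1[k] <- stats::quantile(wind$ws, 0.5)
      nu2[k] <- spread2[k]
      h1[k] <- 0.01
      h2[k] <- 0.01
    }
  }
  # invert the allocation through the stick-breaking map and the initial
  # kernels to obtain starting break proportions
  eta <- matrix(0, K - 1L, Tt)
  rem <- rep(1, Tt)
  for (k in seq_len(K - 1L)) {
    xi_k <- .clip_eta(pmin(ifelse(rem > 1e-9, S[k, ] / rem, 0.5), 1 - 1e-6))
    w_k <- wind_kernel(wind$ws, wind$wd, nu1[k], nu2[k], h1[k], h2[k])
    eta[k, ] <- .clip_eta(pmin(xi_k / w_k, 1 - 1e-6))
    rem <- rem * (1 - xi_k)
  }
  parameter_state(lam = lam, eta = eta, c_tot = ctot,
                  mu_c = mean(log(ctot)),
                  sigma_c = max(stats::sd(log(ctot)), 0.1),
                  sigma = sigma, alpha = 1,
                  nu1 = nu1, nu2 = nu2, h1 = h1, h2 = h2)
}

#' Posterior sampling by adaptive Metropolis-within-Gibbs
#'
#' Samples the full parameter state by blockwise updates targeting
#' `log_likelihood + log_prior`: random-walk Metropolis on additive
#' log-ratio coordinates for each profile column, componentwise logit-scale
#' proposals for the break proportions `eta[k,t]` (accepted per time step,
#' exploiting the factorization of the likelihood over time), whole-row
#' logit shifts and mass-transfer moves between components (which merge
#' duplicated components along the likelihood ridge; see the methods
#' vignette), log-scale proposals for `c_t`, `sigma_p`, `sigma_c` and the
#' bandwidths, a circular random walk for the direction modes `nu2`, a
#' plain walk for `nu1`, exact conjugate Gibbs draws for `mu_c` and
#' `alpha`, and independence refreshes of profiles and kernels from their
#' priors that lock empty components off. Proposal scales adapt in batches
#' during burn-in only. Missing observations are imputed at every kept
#' iteration from `Normal(log mu[p,t], sigma_p)` on the log scale and
#' exponentiated.
#'
#' @param data a [pnsd_matrix()], preprocessed (observed values strictly
#'   positive).
#' @param wind a [wind_series()] aligned to `data` (no missing values).
#' @param config a [model_config()].
#' @param settings an [mcmc_settings()].
#' @param init optional explicit initial [parameter_state()]; by default
#'   [initialize_state()] is used. Supplying one allows prior-only runs on
#'   fully masked panels.
#' @return A `posterior_draws` object: per-chain thinned post-burn-in draws
#'   of every parameter, imputed values for missing cells, acceptance rates
#'   per block, plus the data/time metadata needed by the postprocessing
#'   functions.
#' @export
run_mcmc <- function(data, wind, config, settings, init = NULL) {
  stopifnot(inherits(data, "pnsd_matrix"), inherits(wind, "wind_series"),
            inherits(config, "model_config"), inherits(settings, "mcmc_settings"))
  if (anyNA(wind$ws) || anyNA(wind$wd))
    stop("wind series must be complete; run impute_covariates_mean() first")
  if (any(data$values[!data$missing_mask] <= 0))
    stop("observed values must be strictly positive; run replace_zeros() first")
  config$nu1_upper <- if (is.na(config$nu1_upper)) max(wind$ws) else config$nu1_upper
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    chain_seed <- settings$seed + (ch - 1L) * 1000L
    st0 <- if (is.null(init)) {
      initialize_state(data, wind, config, seed = chain_seed)
    } else init
    chains[[ch]] <- .run_chain(data, wind, config, settings, st0, chain_seed)
  }
  structure(list(chains = chains,
                 miss_idx = which(data$missing_mask),
                 P = nrow(data$values), K = config$K,
                 T = ncol(data$values),
                 meta = list(times = data$times, day = data$day,
                             block = data$block,
                             block_labels = data$block_labels,
                             bin_labels = data$bin_labels),
                 wind = wind, config = config, settings = settings),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  n <- nrow(x$chains[[1]]$c)
  cat(sprintf("<posterior_draws> %d chain(s) x %d draws; P=%d bins, K=%d components, T=%d steps\n",
              length(x$chains), n, x$P, x$K, x$T))
  invisible(x)
}

#' Number of stored draws per chain
#' @param draws a `posterior_draws` object.
#' @return integer.
#' @export
n_draws <- function(draws) nrow(draws$chains[[1]]$c)

#' Reconstruct one stored parameter state
#'
#' @param draws a `posterior_draws` object.
#' @param i draw index.
#' @param chain chain index.
#' @return a [parameter_state()].
#' @export
draw_state <- function(draws, i, chain = 1L) {
  cc <- draws$chains[[chain]]
  parameter_state(lam = matrix(cc$lam[i, ], draws$P, draws$K),
                  eta = matrix(cc$eta[i, ], draws$K - 1L, draws$T),
                  c_tot = cc$c[i, ], mu_c = cc$mu_c[i],
                  sigma_c = cc$sigma_c[i], sigma = cc$sigma[i, ],
                  alpha = cc$alpha[i], nu1 = cc$nu1[i, ], nu2 = cc$nu2[i, ],
                  h1 = cc$h1[i, ], h2 = cc$h2[i, ])
}

# One chain of the sampler. Maintains the current latents (w, s, f, mu on
# the log scale) and the per-time-step log-likelihood so that block updates
# only pay for what they change.
.run_chain <- function(data, wind, config, settings, st, chain_seed) {
  set.seed(chain_seed)
  P <- nrow(data$values); Tt <- ncol(data$values); K <- config$K
  Km1 <- K - 1L
  OBSn <- 1 - data$missing_mask
  LY0 <- log(data$values); LY0[data$missing_mask] <- 0
  miss_idx <- which(data$missing_mask)
  nu1_upper <- config$nu1_upper
  a_sq <- config$prior_sigma_sq; a_al <- config$prior_alpha
  a_sc <- config$prior_sigma_c; a_ih <- config$prior_inv_h
  m0 <- config$prior_mu_c[1]; sd0 <- config$prior_mu_c[2]
  dir_a <- config$prior_lambda

  lam <- st$lam; eta <- .clip_eta(st$eta); c_tot <- st$c_tot
  mu_c <- st$mu_c; sigma_c <- st$sigma_c; sigma <- st$sigma
  alpha <- st$alpha; nu1 <- st$nu1; nu2 <- st$nu2; h1 <- st$h1; h2 <- st$h2

  w <- matrix(0, Km1, Tt)
  for (k in seq_len(Km1))
    w[k, ] <- wind_kernel(wind$ws, wind$wd, nu1[k], nu2[k], h1[k], h2[k])
  xi <- rbind(w * eta, rep(1, Tt))
  s <- .stick_break_mat(xi)
  f <- s * rep(c_tot, each = K)
  mu <- lam %*% f
  lmu <- log(mu)
  inv_sig <- 1 / sigma
  cst <- -log(sigma) - 0.5 * log(2 * pi)
  ll_cols <- function(lmu_) {
    z2 <- ((LY0 - lmu_) * inv_sig)^2
    colSums(OBSn * (cst - 0.5 * z2))
  }
  cll <- ll_cols(lmu)
  if (!all(is.finite(cll)))
    stop("non-finite likelihood at initialization (observation block)")

  ldir <- function(x) sum((dir_a - 1) * log(x))  # constant terms cancel

  # proposal scales and acceptance bookkeeping, one slot per adaptive block
  blocks <- c(paste0("lam", seq_len(K)), paste0("eta", seq_len(Km1)),
              paste0("etashift", seq_len(Km1)),
              paste0("etascale", seq_len(Km1)),
              "c", "sigma", "sigma_c",
              paste0("nu1_", seq_len(Km1)), paste0("nu2_", seq_len(Km1)),
              paste0("h1_", seq_len(Km1)), paste0("h2_", seq_len(Km1)))
  sc <- stats::setNames(rep(0.2, length(blocks)), blocks)
  sc[paste0("lam", seq_len(K))] <- 0.05
  sc[paste0("nu2_", seq_len(Km1))] <- 20
  sc[paste0("nu1_", seq_len(Km1))] <- 0.5
  targ <- stats::setNames(rep(0.44, length(blocks)), blocks)
  targ[paste0("lam", seq_len(K))] <- 0.234
  acc_n <- acc_s <- stats::setNames(rep(0, length(blocks)), blocks)
  rep_n <- rep_s <- acc_n  # post burn-in reporting
  note <- function(block, rate, adapting) {
    if (adapting) {
      acc_n[block] <<- acc_n[block] + 1
      acc_s[block] <<- acc_s[block] + rate
    } else {
      rep_n[block] <<- rep_n[block] + 1
      rep_s[block] <<- rep_s[block] + rate
    }
  }

  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  out <- list(lam = matrix(0, n_keep, P * K), eta = matrix(0, n_keep, Km1 * Tt),
              c = matrix(0, n_keep, Tt), sigma = matrix(0, n_keep, P),
              mu_c = numeric(n_keep), sigma_c = numeric(n_keep),
              alpha = numeric(n_keep),
              nu1 = matrix(0, n_keep, Km1), nu2 = matrix(0, n_keep, Km1),
              h1 = matrix(0, n_keep, Km1), h2 = matrix(0, n_keep, Km1),
              imputed_y = matrix(0, n_keep, length(miss_idx)))

  refresh_kernel_row <- function(k) {
    wind_kernel(wind$ws, wind$wd, nu1[k], nu2[k], h1[k], h2[k])
  }
  # recompute s, f, mu, cll from a candidate row replacement of xi
  candidate_from_xi <- function(xi_new) {
    s_new <- .stick_break_mat(xi_new)
    f_new <- s_new * rep(c_tot, each = K)
    mu_new <- lam %*% f_new
    list(s = s_new, f = f_new, mu = mu_new, lmu = log(mu_new))
  }

  kernel_scalar_update <- function(k, which_par, adapting) {
    block <- paste0(which_par, "_", k)
    cur <- switch(which_par, nu1 = nu1[k], nu2 = nu2[k],
                  h1 = h1[k], h2 = h2[k])
    lp_extra_old <- 0; lp_extra_new <- 0
    if (which_par == "nu1") {
      prop <- cur + stats::rnorm(1, 0, sc[block])
      if (prop < 0 || prop > nu1_upper) { note(block, 0, adapting); return(invisible()) }
    } else if (which_par == "nu2") {
      prop <- (cur + stats::rnorm(1, 0, sc[block])) %% 360
    } else {
      prop <- cur * exp(stats::rnorm(1, 0, sc[block]))
      # Gamma prior on 1/h in h-space plus log-scale proposal Jacobian
      lp_extra_old <- stats::dgamma(1 / cur, a_ih[1], rate = a_ih[2], log = TRUE) - log(cur)
      lp_extra_new <- stats::dgamma(1 / prop, a_ih[1], rate = a_ih[2], log = TRUE) - log(prop)
    }
    nu1k <- nu1[k]; nu2k <- nu2[k]; h1k <- h1[k]; h2k <- h2[k]
    assign(switch(which_par, nu1 = "nu1k", nu2 = "nu2k", h1 = "h1k", h2 = "h2k"),
           prop)
    w_new <- wind_kernel(wind$ws, wind$wd, nu1k, nu2k, h1k, h2k)
    xi_new <- xi; xi_new[k, ] <- w_new * eta[k, ]
    cand <- candidate_from_xi(xi_new)
    if (any(cand$mu <= 0)) { note(block, 0, adapting); return(invisible()) }
    cll_new <- ll_cols(cand$lmu)
    d <- sum(cll_new) - sum(cll) + lp_extra_new - lp_extra_old
    if (is.finite(d) && log(stats::runif(1)) < d) {
      if (which_par == "nu1") nu1[k] <<- prop
      if (which_par == "nu2") nu2[k] <<- prop
      if (which_par == "h1") h1[k] <<- prop
      if (which_par == "h2") h2[k] <<- prop
      w[k, ] <<- w_new; xi <<- xi_new
      s <<- cand$s; f <<- cand$f; mu <<- cand$mu; lmu <<- cand$lmu
      cll <<- cll_new
      note(block, 1, adapting)
    } else note(block, 0, adapting)
  }

  ## independence proposals from the priors: a profile refresh and a kernel
  ## refresh per component (the prior and proposal densities cancel, so the
  ## acceptance ratio is the likelihood ratio alone). For a near-empty
  ## component these are accepted freely, so its profile decouples from the
  ## data and its kernel collapses to the narrow shapes the vague
  ## inverse-bandwidth prior favors -- which locks the component empty. For
  ## a component duplicating another's profile, a narrow kernel proposal
  ## re-routes its mass to later sticks almost likelihood-neutrally: the
  ## move that merges duplicated sources.
  profile_refresh <- function(k) {
    g <- stats::rgamma(P, dir_a, 1)
    if (sum(g) == 0) return(invisible())
    lamp <- g / sum(g)
    if (any(lamp == 0)) return(invisible())
    lamk <- lam[, k]
    mu_new <- mu + outer(lamp - lamk, f[k, ])
    if (any(mu_new <= 0)) return(invisible())
    lmu_new <- log(mu_new)
    cll_new <- ll_cols(lmu_new)
    d <- sum(cll_new) - sum(cll)
    if (is.finite(d) && log(stats::runif(1)) < d) {
      lam[, k] <<- lamp; mu <<- mu_new; lmu <<- lmu_new; cll <<- cll_new
    }
    invisible()
  }
  kernel_refresh <- function(k) {
    prop <- c(stats::runif(1, 0, nu1_upper), stats::runif(1, 0, 360),
              1 / stats::rgamma(1, a_ih[1], rate = a_ih[2]),
              1 / stats::rgamma(1, a_ih[1], rate = a_ih[2]))
    if (any(!is.finite(prop)) || any(prop[3:4] <= 0)) return(invisible())
    w_new <- wind_kernel(wind$ws, wind$wd, prop[1], prop[2], prop[3], prop[4])
    xi_new <- xi; xi_new[k, ] <- w_new * eta[k, ]
    cand <- candidate_from_xi(xi_new)
    if (any(cand$mu <= 0)) return(invisible())
    cll_new <- ll_cols(cand$lmu)
    d <- sum(cll_new) - sum(cll)
    if (is.finite(d) && log(stats::runif(1)) < d) {
      nu1[k] <<- prop[1]; nu2[k] <<- prop[2]
      h1[k] <<- prop[3]; h2[k] <<- prop[4]
      w[k, ] <<- w_new; xi <<- xi_new
      s <<- cand$s; f <<- cand$f; mu <<- cand$mu; lmu <<- cand$lmu
      cll <<- cll_new
    }
    invisible()
  }

  ## mass-transfer move between component j and a later component m:
  ## eta[j,] is scaled by a common factor, the break proportions of rows
  ## between j and m are adjusted so their mixing weights stay exactly
  ## fixed, and the change in component j's mass is absorbed entirely by
  ## component m (automatic when m = K, the remainder). When the profiles
  ## of j and m are aligned the move is likelihood-neutral, so a component
  ## duplicating another drains into it geometrically fast -- the merge
  ## move for mass-split configurations. Accepted per time step with the
  ## triangular-map Jacobian.
  eta_transfer <- function(j, adapting) {
    block <- paste0("etascale", j)
    m <- if (j + 1L >= K) K else sample(seq.int(j + 1L, K), 1L)
    g <- exp(stats::rnorm(1, 0, sc[block]))
    # with prob 1/2, also redraw component j's kernel from the prior (the
    # proposal density cancels against the prior in the acceptance ratio);
    # a narrow kernel draw empties the whole row at once, which -- combined
    # with the downstream compensation -- merges component j into m in a
    # single likelihood-neutral step
    new_kernel <- stats::runif(1) < 0.5
    if (new_kernel) {
      kprop <- c(stats::runif(1, 0, nu1_upper), stats::runif(1, 0, 360),
                 1 / stats::rgamma(1, a_ih[1], rate = a_ih[2]),
                 1 / stats::rgamma(1, a_ih[1], rate = a_ih[2]))
      if (any(!is.finite(kprop)) || any(kprop[3:4] <= 0)) {
        note(block, 0, adapting); return(invisible())
      }
      wj_new <- wind_kernel(wind$ws, wind$wd, kprop[1], kprop[2],
                            kprop[3], kprop[4])
    } else {
      wj_new <- w[j, ]
    }
    ok <- rep(TRUE, Tt)
    ljac <- rep(log(g), Tt)
    eta_new <- eta
    xi_new <- xi
    R <- rep(1, Tt)                      # prod_{l<j} (1 - xi_l), unchanged rows
    if (j > 1L) for (l in seq_len(j - 1L)) R <- R * (1 - xi[l, ])
    ej <- g * eta[j, ]
    ok <- ok & ej > 1e-12 & ej < 1 - 1e-12
    eta_new[j, ] <- ej
    xi_new[j, ] <- wj_new * ej
    ok <- ok & xi_new[j, ] < 1
    R_old <- R * (1 - xi[j, ])
    R_new <- R * (1 - xi_new[j, ])
    if (m > j + 1L) {
      for (l in seq.int(j + 1L, m - 1L)) {
        ratio <- R_old / R_new
        xl <- xi[l, ] * ratio
        el <- xl / pmax(w[l, ], 1e-300)
        ok <- ok & is.finite(xl) & xl < 1 & el > 1e-12 & el < 1 - 1e-12
        ljac <- ljac + log(pmax(ratio, 1e-300))
        eta_new[l, ] <- el
        xi_new[l, ] <- xl
        # s_l is held fixed, so the remaining-stick gap R_old - R_new is
        # carried downstream unchanged
        R_old <- R_old * (1 - xi[l, ])
        R_new <- R_new * (1 - xl)
      }
    }
    if (m < K) {
      # absorb the full mass change at row m, leaving all later rows fixed
      ratio <- R_old / R_new
      s_m <- xi[m, ] * R_old
      xm <- (s_m - (R_old - R_new)) / R_new
      em <- xm / pmax(w[m, ], 1e-300)
      ok <- ok & is.finite(xm) & xm > 0 & xm < 1 & em > 1e-12 & em < 1 - 1e-12
      ljac <- ljac + log(pmax(ratio, 1e-300))
      eta_new[m, ] <- em
      xi_new[m, ] <- xm
    }
    if (!any(ok)) { note(block, 0, adapting); return(invisible()) }
    eta_new <- .clip_eta(eta_new)
    xi_new[seq_len(Km1), ] <- pmin(pmax(xi_new[seq_len(Km1), ], 0), 1 - 1e-15)
    cand <- candidate_from_xi(xi_new)
    cll_new <- ll_cols(cand$lmu)
    rows <- seq.int(j, min(m, Km1))
    dprior <- (alpha - 1) *
      colSums(log1p(-eta_new[rows, , drop = FALSE]) -
                log1p(-eta[rows, , drop = FALSE]))
    # all-or-nothing acceptance: the whole row moves coherently, so the
    # transfer acts as a directed merge rather than 150 uncoordinated walks
    if (!all(ok)) { note(block, 0, adapting); return(invisible()) }
    d <- sum(cll_new - cll + dprior + ljac)
    if (is.finite(d) && log(stats::runif(1)) < d) {
      eta <<- eta_new; xi <<- xi_new
      s <<- cand$s; f <<- cand$f; mu <<- cand$mu; lmu <<- cand$lmu
      cll <<- cll_new
      if (new_kernel) {
        nu1[j] <<- kprop[1]; nu2[j] <<- kprop[2]
        h1[j] <<- kprop[3]; h2[j] <<- kprop[4]
        w[j, ] <<- wj_new
      }
      note(block, 1, adapting)
    } else note(block, 0, adapting)
    invisible()
  }

  keep_i <- 0L
  batch_no <- 0L
  for (iter in seq_len(settings$n_iter)) {
    adapting <- iter <= settings$burn_in
    for (sweep in seq_len(settings$n_sweeps)) {

    ## profile columns: additive log-ratio random walk on the simplex
    for (k in seq_len(K)) {
      block <- paste0("lam", k)
      lamk <- lam[, k]
      z <- log(lamk[-P] / lamk[P]) + stats::rnorm(P - 1L, 0, sc[block])
      zm <- c(z, 0); zm <- zm - max(zm)
      lamp <- exp(zm); lamp <- lamp / sum(lamp)
      if (any(lamp == 0)) { note(block, 0, adapting); next }
      mu_new <- mu + outer(lamp - lamk, f[k, ])
      if (any(mu_new <= 0)) { note(block, 0, adapting); next }
      lmu_new <- log(mu_new)
      cll_new <- ll_cols(lmu_new)
      d <- sum(cll_new) - sum(cll) + ldir(lamp) - ldir(lamk) +
        sum(log(lamp)) - sum(log(lamk))        # ALR Jacobian
      if (is.finite(d) && log(stats::runif(1)) < d) {
        lam[, k] <- lamp; mu <- mu_new; lmu <- lmu_new; cll <- cll_new
        note(block, 1, adapting)
      } else note(block, 0, adapting)
    }

    ## break proportions: logit walk, accepted per time step
    for (k in seq_len(Km1)) {
      block <- paste0("eta", k)
      ek <- eta[k, ]
      ep <- .clip_eta(stats::plogis(stats::qlogis(ek) +
                                      stats::rnorm(Tt, 0, sc[block])))
      xi_new <- xi; xi_new[k, ] <- w[k, ] * ep
      cand <- candidate_from_xi(xi_new)
      cll_new <- ll_cols(cand$lmu)
      d <- cll_new - cll +
        (alpha - 1) * (log1p(-ep) - log1p(-ek)) +
        log(ep) + log1p(-ep) - log(ek) - log1p(-ek)   # logit Jacobian
      acc <- is.finite(d) & log(stats::runif(Tt)) < d
      if (any(acc)) {
        eta[k, acc] <- ep[acc]; xi[k, acc] <- xi_new[k, acc]
        s[, acc] <- cand$s[, acc]; f[, acc] <- cand$f[, acc]
        mu[, acc] <- cand$mu[, acc]; lmu[, acc] <- cand$lmu[, acc]
        cll[acc] <- cll_new[acc]
      }
      note(block, mean(acc), adapting)
    }

    ## whole-row shift of each break-proportion row on the logit scale:
    ## moves a component's entire mass profile coherently, so a duplicated
    ## component can drain into (or fill from) later sticks along the
    ## likelihood ridge in few steps
    for (k in seq_len(Km1)) {
      block <- paste0("etashift", k)
      ek <- eta[k, ]
      ep <- .clip_eta(stats::plogis(stats::qlogis(ek) +
                                      stats::rnorm(1, 0, sc[block])))
      xi_new <- xi; xi_new[k, ] <- w[k, ] * ep
      cand <- candidate_from_xi(xi_new)
      cll_new <- ll_cols(cand$lmu)
      d <- sum(cll_new) - sum(cll) +
        sum((alpha - 1) * (log1p(-ep) - log1p(-ek)) +
              log(ep) + log1p(-ep) - log(ek) - log1p(-ek))
      if (is.finite(d) && log(stats::runif(1)) < d) {
        eta[k, ] <- ep; xi <- xi_new
        s <- cand$s; f <- cand$f; mu <- cand$mu; lmu <- cand$lmu
        cll <- cll_new
        note(block, 1, adapting)
      } else note(block, 0, adapting)
    }

    ## mass-transfer merge moves
    for (k in seq_len(Km1)) eta_transfer(k, adapting)

    ## total concentrations: log walk, accepted per time step
    {
      lc <- log(c_tot)
      dlc <- stats::rnorm(Tt, 0, sc["c"])
      lmu_new <- lmu + rep(dlc, each = P)
      cll_new <- ll_cols(lmu_new)
      d <- cll_new - cll +
        stats::dnorm(lc + dlc, mu_c, sigma_c, log = TRUE) -
        stats::dnorm(lc, mu_c, sigma_c, log = TRUE)
      # keep log-concentrations inside the representable range (relevant
      # only for prior-only runs under the vague sigma_c prior)
      acc <- abs(lc + dlc) < 700 & is.finite(d) & log(stats::runif(Tt)) < d
      if (any(acc)) {
        ratio <- exp(dlc[acc])
        c_tot[acc] <- c_tot[acc] * ratio
        f[, acc] <- f[, acc] * rep(ratio, each = K)
        mu[, acc] <- mu[, acc] * rep(ratio, each = P)
        lmu[, acc] <- lmu_new[, acc]
        cll[acc] <- cll_new[acc]
      }
      note("c", mean(acc), adapting)
    }

    ## measurement sds: log walk, accepted per bin
    {
      nobs_p <- rowSums(OBSn)
      ssr_p <- rowSums(OBSn * (LY0 - lmu)^2)
      rowll <- function(sg) nobs_p * (-log(sg) - 0.5 * log(2 * pi)) -
        0.5 * ssr_p / sg^2
      lsp <- log(sigma) + stats::rnorm(P, 0, sc["sigma"])
      sigp <- exp(lsp)
      d <- rowll(sigp) - rowll(sigma) +
        stats::dgamma(sigp^2, a_sq[1], rate = a_sq[2], log = TRUE) -
        stats::dgamma(sigma^2, a_sq[1], rate = a_sq[2], log = TRUE) +
        2 * (lsp - log(sigma))                 # d(sigma^2)/d(log sigma)
      acc <- is.finite(d) & log(stats::runif(P)) < d
      if (any(acc)) {
        sigma[acc] <- sigp[acc]
        inv_sig <- 1 / sigma
        cst <- -log(sigma) - 0.5 * log(2 * pi)
        cll <- ll_cols(lmu)
      }
      note("sigma", mean(acc), adapting)
    }

    ## mu_c: conjugate normal Gibbs draw given log c
    {
      lc <- log(c_tot)
      prec <- Tt / sigma_c^2 + 1 / sd0^2
      mean_post <- (sum(lc) / sigma_c^2 + m0 / sd0^2) / prec
      mu_c <- stats::rnorm(1, mean_post, sqrt(1 / prec))
    }

    ## sigma_c: log-scale walk
    {
      lc <- log(c_tot)
      prop <- sigma_c * exp(stats::rnorm(1, 0, sc["sigma_c"]))
      d <- sum(stats::dnorm(lc, mu_c, prop, log = TRUE)) -
        sum(stats::dnorm(lc, mu_c, sigma_c, log = TRUE)) +
        stats::dgamma(prop, a_sc[1], rate = a_sc[2], log = TRUE) -
        stats::dgamma(sigma_c, a_sc[1], rate = a_sc[2], log = TRUE) +
        log(prop) - log(sigma_c)
      if (is.finite(d) && log(stats::runif(1)) < d) {
        sigma_c <- prop
        note("sigma_c", 1, adapting)
      } else note("sigma_c", 0, adapting)
    }

    ## alpha: conjugate gamma Gibbs draw given eta
    {
      S <- sum(log1p(-eta))
      alpha <- stats::rgamma(1, a_al[1] + Km1 * Tt, rate = a_al[2] - S)
    }

    ## kernel modes and bandwidths
    for (k in seq_len(Km1)) {
      kernel_scalar_update(k, "nu1", adapting)
      kernel_scalar_update(k, "nu2", adapting)
      kernel_scalar_update(k, "h1", adapting)
      kernel_scalar_update(k, "h2", adapting)
    }

    ## prior-independence refreshes (see above)
    for (k in seq_len(K)) profile_refresh(k)
    for (k in seq_len(Km1)) kernel_refresh(k)

    }  # end sweeps

    ## periodic full refresh against floating-point drift of increments
    if (iter %% 250L == 0L) {
      mu <- lam %*% f
      lmu <- log(mu)
      cll <- ll_cols(lmu)
    }

    ## adaptation in batches during burn-in only
    if (adapting && iter %% settings$adapt_batch == 0L) {
      batch_no <- batch_no + 1L
      gain <- min(0.5, 2 / sqrt(batch_no))
      rate <- ifelse(acc_n > 0, acc_s / acc_n, targ)
      sc <- sc * exp(gain * (rate - targ))
      acc_n[] <- 0; acc_s[] <- 0
    }

    ## store thinned post-burn-in draws
    if (iter > settings$burn_in &&
        (iter - settings$burn_in) %% settings$thin == 0L) {
      keep_i <- keep_i + 1L
      out$lam[keep_i, ] <- lam
      out$eta[keep_i, ] <- eta
      out$c[keep_i, ] <- c_tot
      out$sigma[keep_i, ] <- sigma
      out$mu_c[keep_i] <- mu_c
      out$sigma_c[keep_i] <- sigma_c
      out$alpha[keep_i] <- alpha
      out$nu1[keep_i, ] <- nu1; out$nu2[keep_i, ] <- nu2
      out$h1[keep_i, ] <- h1; out$h2[keep_i, ] <- h2
      if (length(miss_idx))
        out$imputed_y[keep_i, ] <-
          exp(stats::rnorm(length(miss_idx), lmu[miss_idx],
                           sigma[((miss_idx - 1L) %% P) + 1L]))
    }
  }
  out$acceptance <- ifelse(rep_n > 0, rep_s / rep_n, NA_real_)
  out$seed <- chain_seed
  out
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Splits a single chain into two halves and computes the potential scale
#' reduction factor `sqrt(((n-1)/n W + B/n) / W)` with `B` and `W` the
#' between- and within-half variances and `n` the half length. Values near 1
#' indicate the two halves explore the same distribution; the conventional
#' convergence cut-off is 1.1.
#'
#' @param chain numeric vector of length >= 4.
#' @return scalar R-hat.
#' @export
gelman_rubin_split <- function(chain) {
  chain <- as.numeric(chain)
  if (length(chain) < 4L) stop("chain length must be at least 4")
  n <- length(chain) %/% 2L
  h1 <- chain[seq_len(n)]
  h2 <- chain[seq.int(length(chain) - n + 1L, length(chain))]
  W <- mean(c(stats::var(h1), stats::var(h2)))
  if (W == 0) stop("constant chain: within-half variance is zero")
  B <- n * stats::var(c(mean(h1), mean(h2)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence table for the monitored scalar summaries
#'
#' Split-chain R-hat for `mu_c`, `sigma_c`, `alpha`, each `sigma_p` and each
#' source share, per chain.
#'
#' @param draws a `posterior_draws` object.
#' @return data.frame with columns `parameter`, `chain`, `rhat`.
#' @export
rhat_table <- function(draws) {
  rows <- list()
  for (ch in seq_along(draws$chains)) {
    cc <- draws$chains[[ch]]
    shares <- .shares_by_draw(draws, ch)
    vals <- c(list(mu_c = cc$mu_c, sigma_c = cc$sigma_c, alpha = cc$alpha),
              stats::setNames(lapply(seq_len(draws$P), function(p) cc$sigma[, p]),
                              paste0("sigma_", seq_len(draws$P))),
              stats::setNames(lapply(seq_len(draws$K), function(k) shares[, k]),
                              paste0("share_", seq_len(draws$K))))
    rh <- vapply(vals, function(v) {
      tryCatch(gelman_rubin_split(v), error = function(e) NA_real_)
    }, numeric(1))
    rows[[ch]] <- data.frame(parameter = names(vals), chain = ch, rhat = rh,
                             row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Posterior-predictive summary of the missing cells
#'
#' Per missing cell, the posterior-predictive mean and central 95% interval
#' of the imputed concentration, pooled over chains.
#'
#' @param draws a `posterior_draws` object.
#' @param data the [pnsd_matrix()] the draws were fitted to.
#' @return data.frame with columns `p`, `t`, `bin_nm`, `time`, `mean`,
#'   `lower`, `upper`; zero rows when nothing is missing.
#' @export
impute_missing <- function(draws, data) {
  idx <- draws$miss_idx
  if (length(idx) == 0L)
    return(data.frame(p = integer(0), t = integer(0), bin_nm = numeric(0),
                      time = as.POSIXct(character(0)), mean = numeric(0),
                      lower = numeric(0), upper = numeric(0)))
  imp <- do.call(rbind, lapply(draws$chains, `[[`, "imputed_y"))
  p <- ((idx - 1L) %% draws$P) + 1L
  t <- ((idx - 1L) %/% draws$P) + 1L
  data.frame(p = p, t = t,
             bin_nm = draws$meta$bin_labels[p],
             time = draws$meta$times[t],
             mean = colMeans(imp),
             lower = apply(imp, 2, stats::quantile, probs = 0.025),
             upper = apply(imp, 2, stats::quantile, probs = 0.975),
             row.names = NULL)
}
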