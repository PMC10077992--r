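#' Model configuration and priors
#'
#' Collects the truncation level and the (minimally informative) prior
#' hyperparameters of the hierarchical model. All Gamma distributions are
#' shape-rate, so `Gamma(1, 0.001)` has mean 1000 (vague).
#'
#' Priors (defaults): `mu_c ~ Normal(0, sd 10)`; `sigma_c ~ Gamma(1, 0.001)`;
#' `sigma_p^2 ~ Gamma(1, 1)` per bin; each profile column
#' `lambda_k ~ Dirichlet(0.5, ..., 0.5)` (Jeffreys); `alpha ~ Gamma(1, 1)`
#' with more/less informative options `(1, 10)` / `(1, 0.1)`;
#' `1/h1, 1/h2 ~ Gamma(1, 0.001)`; `nu1 ~ Uniform(0, max ws)`;
#' `nu2 ~ Uniform(0, 360)`; `eta ~ Beta(1, alpha)`.
#'
#' @param K truncation level: maximum number of sources (integer >= 2). The
#'   K-th component takes the probability left after K-1 breaks and carries no
#'   wind kernel.
#' @param prior_mu_c `c(mean, sd)` of the Normal prior on `mu_c`.
#' @param prior_sigma_c `c(shape, rate)` Gamma prior on `sigma_c`.
#' @param prior_sigma_sq `c(shape, rate)` Gamma prior on each `sigma_p^2`.
#' @param prior_lambda symmetric Dirichlet concentration for profile columns.
#' @param prior_alpha `c(shape, rate)` Gamma prior on the DP concentration.
#' @param prior_inv_h `c(shape, rate)` Gamma prior on each inverse bandwidth.
#' @param nu1_upper upper limit of the Uniform prior on the wind-speed modes;
#'   `NA` means "use the maximum observed wind speed" (resolved at fit time).
#' @param source_threshold minimum contribution share for a component to
#'   count as a non-empty source (fraction in (0,1); the headline figure uses
#'   1%).
#' @return An object of class `model_config`.
#' @export
model_config <- function(K = 10L,
                         prior_mu_c = c(mean = 0, sd = 10),
                         prior_sigma_c = c(shape = 1, rate = 0.001),
                         prior_sigma_sq = c(shape = 1, rate = 1),
                         prior_lambda = 0.5,
                         prior_alpha = c(shape = 1, rate = 1),
                         prior_inv_h = c(shape = 1, rate = 0.001),
                         nu1_upper = NA_real_,
                         source_threshold = 0.01) {
  K <- as.integer(K)
  stopifnot(K >= 2L, prior_mu_c[2] > 0, all(prior_sigma_c > 0),
            all(prior_sigma_sq > 0), prior_lambda > 0, all(prior_alpha > 0),
            all(prior_inv_h > 0),
            source_threshold > 0, source_threshold < 1)
  structure(list(K = K, prior_mu_c = unname(prior_mu_c),
                 prior_sigma_c = unname(prior_sigma_c),
                 prior_sigma_sq = unname(prior_sigma_sq),
                 prior_lambda = unname(prior_lambda),
                 prior_alpha = unname(prior_alpha),
                 prior_inv_h = unname(prior_inv_h),
                 nu1_upper = unname(nu1_upper),
                 source_threshold = unname(source_threshold)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> K=%d, alpha~Gamma(%g,%g), source threshold %g%%\n",
              x$K, x$prior_alpha[1], x$prior_alpha[2], 100 * x$source_threshold))
  invisible(x)
}

#' Write / read a model configuration as YAML
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `read_model_config` returns a `model_config`.
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_config, raw)
}

#' Gaussian wind kernel
#'
#' Kernel weight in `(0, 1]` linking a source's contribution to wind:
#' Gaussian in wind speed around the mode `nu1` (bandwidth `h1`) times
#' Gaussian in a sine transform of the angular distance between wind
#' direction and the mode `nu2` (bandwidth `h2`):
#' `exp(-(nu1-ws)^2/(2 h1)) * exp(-sin((nu2-wd) pi/360)^2 / (2 h2))`.
#' The weight equals 1 exactly at the mode (required for the stick-breaking
#' construction to remain valid) and is periodic in `wd` with period 360.
#'
#' @param ws wind speed (m/s); vectorized.
#' @param wd wind direction (degrees); vectorized.
#' @param nu1 wind-speed mode (m/s).
#' @param nu2 wind-direction mode (degrees).
#' @param h1,h2 positive bandwidths.
#' @return numeric weights in `(0, 1]`.
#' @export
wind_kernel <- function(ws, wd, nu1, nu2, h1, h2) {
  if (any(h1 <= 0) || any(h2 <= 0)) stop("bandwidths must be positive")
  exp(-(nu1 - ws)^2 / (2 * h1)) *
    exp(-sin((nu2 - wd) * pi / 360)^2 / (2 * h2))
}

#' Stick-breaking map from break proportions to mixing weights
#'
#' `s_1 = xi_1`, `s_k = xi_k prod_{l<k}(1 - xi_l)`; the last break proportion
#' must be 1 so the final component consumes the remaining stick and the
#' weights sum to one exactly.
#'
#' @param xi numeric vector in `[0,1]` with last entry exactly 1.
#' @return probability vector of the same length.
#' @export
stick_break <- function(xi) {
  K <- length(xi)
  if (xi[K] != 1) stop("last break proportion must equal 1")
  if (any(xi < 0 | xi > 1)) stop("break proportions must lie in [0,1]")
  rem <- c(1, cumprod(1 - xi[-K]))
  xi * rem
}

# columnwise stick-breaking for a K x T matrix of break proportions whose
# last row is 1
.stick_break_mat <- function(xi) {
  K <- nrow(xi); Tt <- ncol(xi)
  s <- matrix(0, K, Tt)
  rem <- rep(1, Tt)
  for (k in seq_len(K)) {
    s[k, ] <- xi[k, ] * rem
    rem <- rem * (1 - xi[k, ])
  }
  s
}

#' One full realization of the model unknowns
#'
#' @param lam P x K matrix; each column a source profile on the size-bin
#'   simplex.
#' @param eta (K-1) x T matrix of base break proportions in (0,1).
#' @param c_tot length-T positive vector of total concentrations.
#' @param mu_c,sigma_c mean and sd of `log(c_t)`.
#' @param sigma length-P positive vector of measurement sds.
#' @param alpha positive DP concentration.
#' @param nu1,nu2 length-(K-1) kernel modes (m/s; degrees in `[0,360)`).
#' @param h1,h2 length-(K-1) positive bandwidths.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(lam, eta, c_tot, mu_c, sigma_c, sigma, alpha,
                            nu1, nu2, h1, h2) {
  st <- structure(list(lam = as.matrix(lam), eta = as.matrix(eta),
                       c_tot = as.numeric(c_tot), mu_c = mu_c,
                       sigma_c = sigma_c, sigma = as.numeric(sigma),
                       alpha = alpha, nu1 = as.numeric(nu1),
                       nu2 = as.numeric(nu2), h1 = as.numeric(h1),
                       h2 = as.numeric(h2)),
                  class = "parameter_state")
  validate_parameter_state(st)
  st
}

#' Validate a parameter state against the model's support constraints
#'
#' @param st a `parameter_state`.
#' @param tol tolerance for the simplex constraint on profile columns.
#' @return `st`, invisibly; errors on violation.
#' @export
validate_parameter_state <- function(st, tol = 1e-10) {
  K <- ncol(st$lam)
  stopifnot(nrow(st$eta) == K - 1L, length(st$nu1) == K - 1L,
            length(st$nu2) == K - 1L, length(st$h1) == K - 1L,
            length(st$h2) == K - 1L)
  if (any(st$lam < 0)) stop("profile entries must be nonnegative")
  if (any(abs(colSums(st$lam) - 1) > tol))
    stop("profile columns must sum to 1")
  if (any(st$eta <= 0 | st$eta >= 1))
    stop("eta must lie strictly inside (0,1)")
  if (any(st$c_tot <= 0) || any(st$sigma <= 0) || st$sigma_c <= 0 ||
      st$alpha <= 0 || any(st$h1 <= 0) || any(st$h2 <= 0))
    stop("positivity constraint violated")
  if (any(st$nu2 < 0 | st$nu2 >= 360))
    stop("nu2 must lie in [0,360)")
  invisible(st)
}

#' Derived latent quantities of a state
#'
#' Computes, for a parameter state and wind series: the kernel weights
#' `w[k,t]`, break proportions `xi[k,t] = w[k,t] eta[k,t]` (with
#' `xi[K,t] = 1`), mixing weights `s` (columns sum to 1), source
#' contributions `f[k,t] = s[k,t] c_t`, and the model mean
#' `mu[p,t] = sum_k lam[p,k] f[k,t]`. With all kernel weights equal to 1 the
#' construction reduces to a standard time-varying DP.
#'
#' @param state a [parameter_state()].
#' @param wind a [wind_series()] of length T.
#' @return list with elements `w`, `xi`, `s`, `f`, `mu`.
#' @export
compute_latents <- function(state, wind) {
  K <- ncol(state$lam); Tt <- length(wind$ws)
  stopifnot(ncol(state$eta) == Tt, length(state$c_tot) == Tt)
  w <- matrix(0, K - 1L, Tt)
  for (k in seq_len(K - 1L))
    w[k, ] <- wind_kernel(wind$ws, wind$wd, state$nu1[k], state$nu2[k],
                          state$h1[k], state$h2[k])
  xi <- rbind(w * state$eta, rep(1, Tt))
  s <- .stick_break_mat(xi)
  f <- s * rep(state$c_tot, each = K)
  mu <- state$lam %*% f
  list(w = w, xi = xi, s = s, f = f, mu = mu)
}

#' Observation log-likelihood
#'
#' Sum over observed cells of the normal log-density of `log y[p,t]` with
#' mean `log mu[p,t]` and standard deviation `sigma_p` (a multiplicative,
#' log-normal error structure). Missing cells contribute zero.
#'
#' @param state a [parameter_state()].
#' @param data a [pnsd_matrix()] with strictly positive observed values.
#' @param wind a [wind_series()].
#' @param latents optional precomputed [compute_latents()] result.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, data, wind, latents = NULL) {
  if (is.null(latents)) latents <- compute_latents(state, wind)
  mu <- latents$mu
  if (any(mu <= 0)) stop("model mean must be strictly positive")
  obs <- !data$missing_mask
  if (!any(obs)) return(0)
  ly <- log(data$values[obs])
  lmu <- log(mu)[obs]
  sig <- state$sigma[row(mu)[obs]]
  sum(stats::dnorm(ly, lmu, sig, log = TRUE))
}

# log-density of a Dirichlet(a,...,a) vector
.ldirichlet_sym <- function(x, a) {
  lgamma(length(x) * a) - length(x) * lgamma(a) + sum((a - 1) * log(x))
}

#' Joint log prior density
#'
#' Sum of the prior log-densities of all unknowns at the given state, in the
#' coordinates listed in [model_config()]: Normal on `mu_c`; Gamma on
#' `sigma_c`; Gamma on each `sigma_p^2` (evaluated in variance coordinates);
#' symmetric Dirichlet on each profile column; Gamma on `alpha`;
#' `Beta(1, alpha)` on each `eta[k,t]`; Gamma on each inverse bandwidth with
#' the change-of-variables term for evaluating in bandwidth space; Uniform on
#' the kernel modes; and `Normal(mu_c, sigma_c)` on each `log c_t` (the
#' hierarchical layer, evaluated in log coordinates). States outside the
#' support return `-Inf` (not an error).
#'
#' @param state a [parameter_state()].
#' @param config a [model_config()].
#' @param wind a [wind_series()]; supplies the upper limit `max(ws)` of the
#'   Uniform prior on `nu1` when `config$nu1_upper` is `NA`.
#' @return scalar log prior density, possibly `-Inf`.
#' @export
log_prior <- function(state, config, wind) {
  nu1_upper <- config$nu1_upper
  if (is.na(nu1_upper)) nu1_upper <- max(wind$ws)
  # support checks -> -Inf
  if (any(state$lam <= 0) || any(state$eta <= 0) || any(state$eta >= 1) ||
      any(state$c_tot <= 0) || any(state$sigma <= 0) || state$sigma_c <= 0 ||
      state$alpha <= 0 || any(state$h1 <= 0) || any(state$h2 <= 0) ||
      any(state$nu1 < 0) || any(state$nu1 > nu1_upper) ||
      any(state$nu2 < 0) || any(state$nu2 >= 360))
    return(-Inf)
  lp <- stats::dnorm(state$mu_c, config$prior_mu_c[1], config$prior_mu_c[2],
                     log = TRUE)
  lp <- lp + stats::dgamma(state$sigma_c, config$prior_sigma_c[1],
                           rate = config$prior_sigma_c[2], log = TRUE)
  lp <- lp + sum(stats::dgamma(state$sigma^2, config$prior_sigma_sq[1],
                               rate = config$prior_sigma_sq[2], log = TRUE))
  lp <- lp + sum(apply(state$lam, 2, .ldirichlet_sym, a = config$prior_lambda))
  lp <- lp + stats::dgamma(state$alpha, config$prior_alpha[1],
                           rate = config$prior_alpha[2], log = TRUE)
  # Beta(1, alpha) on each eta entry
  lp <- lp + sum(stats::dbeta(state$eta, 1, state$alpha, log = TRUE))
  # Gamma on 1/h, evaluated in h-space: dgamma(1/h) * h^(-2)
  inv_h <- c(1 / state$h1, 1 / state$h2)
  lp <- lp + sum(stats::dgamma(inv_h, config$prior_inv_h[1],
                               rate = config$prior_inv_h[2], log = TRUE)) -
    2 * sum(log(c(state$h1, state$h2)))
  # Uniform kernel modes
  lp <- lp - length(state$nu1) * log(nu1_upper) -
    length(state$nu2) * log(360)
  # hierarchical layer on log c_t, in log coordinates
  lp <- lp + sum(stats::dnorm(log(state$c_tot), state$mu_c, state$sigma_c,
                              log = TRUE))
  lp
}

#' Closed-form stick-breaking summaries for Beta(1, alpha) breaks
#'
#' For a single break proportion `X ~ Beta(1, alpha)`: the median break-off
#' distance `1 - 0.5^(1/alpha)` and the probability `P(X < x) =
#' 1 - (1 - x)^alpha` of breaking off less than a fraction `x` of the
#' remaining stick.
#'
#' @param alpha positive concentration parameter.
#' @param x break fraction in (0,1).
#' @return list with `median` and `prob`.
#' @export
beta_stick_summary <- function(alpha, x = 0.66) {
  stopifnot(alpha > 0, x > 0, x < 1)
  list(median = 1 - 0.5^(1 / alpha), prob = 1 - (1 - x)^alpha)
}
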