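# The synthetic recovery benchmark (three log-normal sources, 15 bins, 150
# time steps, truncation 6) is expensive to fit, so the fitted runs are
# cached in this environment and shared across test files.

.bench <- new.env(parent = emptyenv())

bench_sim <- function() {
  if (is.null(.bench$sim)) {
    .bench$sim <- generate_dataset(benchmark_truth(), T = 150, seed = 7)
    .bench$data <- replace_zeros(.bench$sim$data)
    .bench$config <- model_config(K = 6)
  }
  .bench
}

bench_full <- function() {
  e <- bench_sim()
  if (is.null(e$full))
    e$full <- run_mcmc(e$data, e$sim$wind, e$config,
                       mcmc_settings(n_iter = 4000, burn_in = 2000, thin = 2,
                                     seed = 11))
  e$full
}

bench_half <- function() {
  e <- bench_sim()
  if (is.null(e$half))
    e$half <- run_mcmc(e$data, e$sim$wind, e$config,
                       mcmc_settings(n_iter = 2000, burn_in = 1000, thin = 1,
                                     seed = 12))
  e$half
}
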