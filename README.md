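# ddpsa

Bayesian nonparametric source apportionment of particle number size
distributions (PNSD), with wind-dependent source allocation.

## What problem this solves

A PNSD monitor counts airborne particles per cm³ in ~100 diameter bins
every hour. Distinct emission sources (aircraft, fresh/aged traffic, urban
background, secondary aerosol) have distinct size signatures, so the panel
is approximately a nonnegative mixture of source *profiles* times
time-varying source *contributions*. Classical receptor models (positive
matrix factorization) require the number of sources to be fixed in
advance, ignore covariates, and give no uncertainty. `ddpsa` fits instead
a dependent Dirichlet-process mixture:

$$\log y_{p,t} \sim \mathcal N(\log \mu_{p,t}, \sigma_p), \qquad
\mu_{p,t} = \sum_{k=1}^{K} \lambda_{p,k}\, s_{k,t}\, c_t ,$$

where the profiles $\lambda_{\cdot,k}$ live on the size-bin simplex, $c_t$
is the log-normal total concentration, and the mixing weights $s_{k,t}$
come from a truncated stick-breaking construction whose break proportions
$\xi_{k,t} = w_{k,t}\eta_{k,t}$, $\eta_{k,t}\sim\mathrm{Beta}(1,\alpha)$,
are modulated by a Gaussian wind kernel

$$w_{k,t} = \exp\!\Big(-\tfrac{(\nu_{1,k}-\mathrm{ws}_t)^2}{2h_{1,k}}\Big)
\exp\!\Big(-\tfrac{\sin^2((\nu_{2,k}-\mathrm{wd}_t)\pi/360)}{2h_{2,k}}\Big).$$

$K$ is only a truncation level: the number of *actual* sources is read off
the posterior as the number of components whose contribution share exceeds
a threshold (1% by default). Missing observations are imputed inside the
MCMC from the posterior predictive distribution.

The package covers the full workflow: correlation-driven aggregation of
size bins and hours (`plan_bin_aggregation()`, `plan_hour_aggregation()`),
zero replacement and wind imputation (`replace_zeros()`,
`impute_covariates_mean()`), an adaptive Metropolis-within-Gibbs sampler
(`run_mcmc()`), split-chain Gelman–Rubin diagnostics
(`gelman_rubin_split()`), a ground-truth synthetic generator
(`generate_dataset()`), and postprocessing into shares, profiles, wind
kernel surfaces, temporal summaries and correlation panels
(`summarize_sources()`). A thin command line lives at `inst/cli/ddpsa`
with subcommands `preprocess`, `simulate`, `fit`, `summarize`.

## Worked example

Simulate the benchmark panel (three log-normal sources over 15 bins, 150
reduced time steps, 2% below-detection zeros, three missing events), clean
it, fit with truncation level 6, and summarize:

```r
library(ddpsa)

sim  <- generate_dataset(benchmark_truth(), T = 150, seed = 7)
data <- replace_zeros(sim$data)
draws <- run_mcmc(data, sim$wind, model_config(K = 6),
                  mcmc_settings(n_iter = 4000, burn_in = 2000, thin = 2,
                                seed = 11))
summarize_sources(draws)
#> <source_summary> 3 non-empty sources at 1.0% threshold
#>   shares: 40.6% 35.5% 23.9% 0.0% 0.0% 0.0%
```

Three of the six components carry essentially all of the concentration —
the model found the right number of sources on its own. Comparing against
the known truth:

```r
m <- match_profiles(sim$truth$spec$profiles, profile_mean(draws))
round(m$similarity, 4)                         # cosine similarity per source
#> [1] 1.0000 0.9997 0.9999
round(rowSums(sim$truth$f) / sum(sim$truth$c), 3)   # generating shares
#> [1] 0.354 0.243 0.404
round(source_shares(draws)[m$perm], 3)              # recovered shares
#> [1] 0.355 0.239 0.406
```

The 180 cells hidden by the simulated instrument downtime are summarized by
their posterior predictive distribution; 91.7% of the held-out true values
fall inside their 95% intervals:

```r
imp <- impute_missing(draws, data)
mean(sim$truth$y_clean[draws$miss_idx] >= imp$lower &
     sim$truth$y_clean[draws$miss_idx] <= imp$upper)
#> [1] 0.9166667
```

Closed-form stick-breaking summaries at a concentration of 2.7 (a typical
posterior value at large truncation levels):

```r
beta_stick_summary(2.7, x = 0.66)
#> $median
#> [1] 0.2264068     # median break-off distance, ~22.6%
#> $prob
#> [1] 0.9456793     # P(break < 0.66), ~95%
```

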