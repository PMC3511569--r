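# firekrige

Fine-scale spatial analysis of soil and microbial variables on burned
forest plots: Bayesian model-based geostatistics for nested post-fire
sampling grids, phospholipid fatty acid (PLFA) community metrics,
isotope pool-dilution net-rate arithmetic, and stepwise-AIC prediction
of *in situ* net nitrogen mineralization. It is written for soil and
fire ecologists who sample intensively within plots (here, 81 cores on a
50 m × 50 m grid with 2/4/8 m nested spacings) and want posterior — not
just point — estimates of how far their variables are autocorrelated.

## The model

For a response Y observed at planar locations, the package fits the
hierarchical Gaussian spatial linear model

- Level 1: `Y(u) = Xβ + S(u) + ε(u)` — linear trend in the coordinates
  (`X = (1, x, y)`, intercept-only optional),
- Level 2: `S(u) ~ N(0, σ² R(h; φ))` with exponential correlation
  `R(h; φ) = exp(−h/φ)`; the autocorrelation range is `3φ`,
- Level 3: flat priors on β and φ, a reciprocal prior on the sill σ²,
  and a relative nugget `τ²rel = τ²/σ²` for the noise `ε`.

β and σ² are conjugate and integrate out analytically; the joint
posterior of `(φ, τ²rel)` is computed on a discrete grid (100 × 100 by
default, one eigendecomposition per φ shared across the τ²rel grid),
from which exact draws — default 100,000 — of all four parameters are
sampled without MCMC. On top of that sit kriged posterior-predictive
surfaces, parameter summaries as mean (5%, 95%) of range, sill, nugget,
and the noise ratio `τ²/(τ² + σ²)`, and deterministic leave-one-out
cross-validation with adjusted R².

Everything downstream of data collection is included: PLFA filtering
rules (cores lacking 16:0 removed; chain lengths ≥ 20 dropped), mole
percents, fungi-to-bacteria ratio, Gram-positive/negative marker sums,
the i15:0/a15:0 stress ratio, net rates from pool-dilution components
(`gross − consumption`), Welch plot comparisons, bidirectional
stepwise-AIC model selection, a synthetic-data generator with known
ground truth that emulates the 81-core design, and a YAML-configured
pipeline driver. See the vignette in `vignettes/` for the methods in
full.

## Worked example

Simulate one 81-core plot under known truth (trend intercept 20, sill
σ² = 400, φ = 3 m so range = 9 m, relative nugget 0.7), then recover the
parameters:

```r
library(firekrige)

design <- generate_design()                      # 81 cores, nested 2/4/8 m lags
truth  <- simulation_truth(beta = c(20, 0.1, 0), sigma2 = 400,
                           phi = 3, tau2_rel = 0.7)
obs    <- simulate_field(design, truth, seed = 42)

post  <- compute_posterior(obs, prior_spec(n_phi = 50, n_tau = 50))
draws <- sample_posterior(post, n_draws = 100000, seed = 43)
summarize_posterior(draws)
#>       quantity    mean      q05     q95
#> 1        trend  27.587   8.4194  49.554
#> 2      range_m  15.991   1.7347  64.030
#> 3         sill 378.491 138.5750 800.547
#> 4       nugget 381.474  66.1973 630.464
#> 5 nugget_ratio   0.518   0.0755   0.786

loo_cross_validate(obs)
#> Leave-one-out CV: n = 81, R2 = 0.082, adjusted R2 = 0.046
```

Reading the output: the posterior mean range (16 m) has a wide 90%
interval containing the true 9 m — with 81 cores and a noise ratio of
0.41, range estimates are honest but diffuse, which is exactly why the
credible intervals matter. The nugget ratio (posterior mean 0.52)
brackets the truth, and the near-zero cross-validation R² reflects a
deliberately noise-dominated simulation: most of the variance here is
nugget, so point predictions carry little skill even though the model is
correctly specified.

Community metrics from a simulated lipid table built on a bundled
plot-mean profile:

```r
profile <- plot_lipid_profiles()$mean[, "glade_crown"]
lip <- simulate_lipid_table(design, profile, total_mean = 205.25,
                            total_sd = 140.9,
                            spatial = simulation_truth(phi = 3, tau2_rel = 0.7),
                            profile_conc = 200, seed = 7)
flt <- filter_cores(lip)          # removes cores lacking 16:0
met <- community_metrics(flt$table)
plot_metrics_summary(met)
#>           metric    mean       se  n
#> 1 abundance_nmol 275.941 14.33997 80
#> 2       fb_ratio   0.808  0.01982 80
#> 3         gm_pos   0.106  0.00207 80
#> 4         gm_neg   0.241  0.00344 80
#> 5   stress_ratio   1.263  0.08323 80
```

A complete run — design, simulation, metrics, kriging, selection,
manifest — comes from one config:

```r
run_pipeline(firekrige_example("demo_config.yaml"), output_dir = "demo_out")
```

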