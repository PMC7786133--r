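# crossguild

Joint species distribution modelling for **paired microbial guilds** —
typically fungal and bacterial OTU tables sequenced from the same samples,
such as cores drilled from decomposing deadwood.  `crossguild` asks two
questions of such data:

1. **Which species-to-species associations survive once the environment is
   accounted for?**  Co-occurrence can reflect shared habitat use or
   residual (potentially biotic) association; contrasting a depth-only
   *null* model with a covariate-rich *full* model separates the two.
2. **Which guild carries information about the other?**  Conditional
   cross-validation measures how much better one guild is predicted when
   the other guild's composition is treated as known — a directional
   statistic for guild-to-guild influence.

## The model

Sequence counts are zero-inflated, so each OTU enters a hurdle model twice:

* occurrence: probit regression on the liability
  `L_ij = x_i' beta_j + eta_i' lambda_j`;
* abundance given presence: per-OTU standardized `log` counts, normal with
  mean `x_i' beta'_j + eta_i' lambda'_j` and variance `sigma_j^2`; zeros
  are missing, not imputed.

All species of both guilds and both model parts share sample-level latent
factors `eta_i ~ N(0, I_K)`.  The loadings induce the residual covariance
`Omega = Lambda Lambda'`, whose correlation form `R` is the residual
association matrix.  Inference is a blocked Gibbs sampler (Albert–Chib
probit augmentation, conjugate coefficient updates, multiplicative-gamma
shrinkage on loadings), with split-chain PSRF and effective-sample-size
diagnostics.  The fixed effects of the full model are the wood chemistry
block (water, pH, C, log N, lignin), the physical block (tree species,
decay class, DBH) and log sequencing depth; the null model keeps only the
depth term.

A generative simulator (`simulate_community()`) mirrors the fitted model
with known ground truth, including an asymmetric-loading scenario in which
one guild's composition is genuinely informative about the other — the
test bed for the directionality statistic.

## Worked example

Simulate a small paired-guild study with a built-in fungi-to-bacteria
asymmetry, fit the full model, and inspect the headline outputs:

```r
library(crossguild)

cfg <- make_asymmetric_scenario(simulation_config(
  n_samples = 80, n_species = c(fungi = 15, bacteria = 15),
  n_factors = 2, seed = 1))
sim <- simulate_community(cfg)
tables <- lapply(sim$tables, filter_otus)   # prevalence > 10% screen

fit <- fit_jsdm(
  responses = lapply(tables, assemble_hurdle_response),
  designs = lapply(setNames(names(tables), names(tables)),
                   function(g) build_design_matrix(sim$meta, "full", g)),
  n_factors = 2,
  mcmc = mcmc_control(n_chains = 2, n_iter = 1000, n_burn = 500, thin = 10))
fit
#> <jsdm_fit> 80 samples, 27 species (fungi: 13, bacteria: 14), 2 factors, 2 chains x 50 draws
```

The residual association network and the variance partition:

```r
compute_association_network(fit, support_level = 0.95, part = "occurrence")
#> <association_network> occurrence part: 27 species, 163/351 supported edges at 0.95 support

subset(guild_summary(variance_partition(fit)), part == "both_parts")
#> # A tibble: 8 × 4
#>   guild    part       group    proportion
#>   <chr>    <chr>      <chr>         <dbl>
#> 1 bacteria both_parts chemical     0.221
#> 2 bacteria both_parts depth        0.0650
#> 3 bacteria both_parts physical     0.288
#> 4 bacteria both_parts random       0.427
#> 5 fungi    both_parts chemical     0.395
#> 6 fungi    both_parts depth        0.0627
#> 7 fungi    both_parts physical     0.380
#> 8 fungi    both_parts random       0.163
```

The simulation gave bacteria strong factor loadings, and the partition
recovers exactly that: the random effect (the association network) carries
43% of explained bacterial variance but only 16% of fungal variance.  The
directional statistic tells the same story from the prediction side —
knowing fungi helps predict bacteria roughly twice as much as the reverse:

```r
report <- two_fold_cv(
  tables, sim$meta, models = "full", n_factors = 2,
  mcmc = mcmc_control(n_chains = 1, n_iter = 800, n_burn = 400, thin = 8),
  cv = cv_spec(seed = 1, n_outer = 20, n_inner = 20, n_inner_burn = 10),
  regimes = c("unconditional", "conditional"))
subset(directionality_gain(report), part == "occurrence")
#> # A tibble: 2 × 6
#>   guild    part       model conditional unconditional   gain
#>   <chr>    <chr>      <chr>       <dbl>         <dbl>  <dbl>
#> 1 bacteria occurrence full        0.590         0.529 0.0612
#> 2 fungi    occurrence full        0.712         0.678 0.0336
```

`gain` is the conditional-minus-unconditional guild-mean AUC: +0.061 AUC
points for bacteria given fungi versus +0.034 for fungi given bacteria.
`run_pipeline()` sequences the whole analysis (filtering, both model fits,
convergence reports, networks and their contrast, variance partitioning,
all cross-validation regimes) from one YAML or in-code configuration, with
cached stages and a JSON manifest; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper.  `tidy()`, `glance()` and `autoplot()` methods cover
the fitted model, networks, variance partitions and evaluation reports.

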