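# thermoplast

Tools for asking where, across a species' range, plant populations are most
thermally plastic — and what about their home sites predicts it.

The package implements a three-stage analysis for multi-population
common-garden experiments in which plants are grown under several
temperature treatments:

1. **Quantify plasticity.** For each species × trait, a random-regression
   mixed model is fitted,

   `y_ij = (β0 + u0_k) + (β1 + u1_k) · T_scaled + r_j + ε_ij`,

   with correlated population-level random intercepts `u0_k` and slopes
   `u1_k`, a replicate (chamber) random intercept `r_j`, a Gaussian error
   for continuous traits and a binomial-logit error for germination
   (`p = exp(η)/(1+exp(η))`). Thermal plasticity of population *k* is the
   absolute total slope `|β1 + u1_k|`, back-transformed to trait units per
   °C. Support for among-population slope variation is assessed by
   ΔAIC = AIC(random intercept only) − AIC(intercept + slope), with
   ΔAIC > 2 read as support.
2. **Characterize the sites.** Two range-position metrics — DRE, the
   distance (km) from a site to the nearer of the northern/southern range
   boundary, and DCE, the distance in climatic PC1–PC2 space to the edge of
   the convex hull of range-cell climates — and three heterogeneity metrics
   computed in a 500-m square buffer: Shannon diversity of land cover
   (SHDI), mean perimeter–area ratio of land-cover patches (PAR, 1/m), and
   average elevation roughness (ARE, m; the Sa statistic).
3. **Relate the two.** All 12 combinations of one range-position metric ×
   one heterogeneity metric × (with/without interaction) are fitted to
   per-population plasticity by OLS and ranked by AIC; the selected model's
   explained variance is partitioned over its terms by LMG relative
   importance (average sequential R² increment over all regressor
   orderings).

A synthetic-data generator (`synthetic_config()`, `simulate_study()`, and
friends) produces range polygons, climate grids, land-cover/elevation
rasters, and individual-level trait data with known ground truth, so every
stage is testable without any external data.

## Worked example

Simulate 40 populations whose slope magnitudes are driven by elevation
roughness (`gamma_eh = 0.4`) and its interaction with climatic edge
distance (`gamma_int = 0.25`), fit the reaction norms, and scan the driver
models:

```r
library(thermoplast)

cfg <- synthetic_config(n_populations = 40, fixed_slope = 1,
                        gamma_eh = 0.4, gamma_int = 0.25,
                        sigma_slope = 0.15, sigma_resid = 1, rng_seed = 2024)
met   <- simulate_driver_metrics(40, seed = 2024)
sites <- data.frame(population = met$population, rp = met$dce, eh = met$are)
sim   <- simulate_trait_data(sites, cfg, family = "gaussian",
                             trait = "plant_height", seed = 2024)

fit <- fit_reaction_norm(sim$observations, "gaussian",
                         trait = "plant_height", species = "H. synthetica")
random_slope_support(sim$observations, "gaussian")
#> Random-slope support: dAIC = 10071.65 (intercept-only 19638.03 - full 9566.38);
#> supported (dAIC > 2)

pl   <- plasticity(fit)      # |slope| per population, units/°C
scan <- fit_plasticity_drivers(assemble_driver_table(pl, met))
summary(scan)
#> Selected driver model (n = 40): plasticity ~ are * dce
#>         term estimate      se statistic   p_value signif
#>  (Intercept)  1.01638 0.02476   41.0415 7.892e-32 < 0.01
#>          are  0.36735 0.02498   14.7070 8.538e-17 < 0.01
#>          dce -0.01038 0.02542   -0.4083 6.854e-01
#>      are:dce  0.23485 0.02861    8.2087 9.145e-10 < 0.01
#> LMG variance shares (of total variance):
#>     are     dce are:dce
#>  0.6671  0.0205  0.2018
#> R2 = 0.8893, unexplained = 0.1107
```

The scan recovers the generating structure: the model on (DCE, ARE) with
interaction wins by ~40 AIC units, the ARE and interaction coefficients are
close to the generator's 0.4 and 0.25 (per z-scaled driver unit), and
roughness plus the interaction jointly explain ~87% of plasticity variance.

For a germination reaction norm on the logit scale, slopes convert to an
interpretable probability change; e.g. a log-odds intercept of 1.307 with a
temperature slope of −0.078 per °C:

```r
logit_slope_to_percentage_points(1.307, -0.078)
#> [1] -1.278211   # ≈ a 1.3 percentage-point decrease per +1 °C
```

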