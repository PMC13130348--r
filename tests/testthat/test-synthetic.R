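test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(n_populations = 1), "n_populations")
  expect_error(synthetic_config(sigma_slope = -1), "sigma_slope")
  expect_error(synthetic_config(slope_intercept_corr = 1.5), "\\[-1, 1\\]")
  expect_error(synthetic_config(treatments_C = c(20, 20)), "distinct")
  expect_error(synthetic_config(heterogeneity_knob = 2), "knob")
})

test_that("range and climate generation is deterministic with sane shapes", {
  cfg <- synthetic_config(rng_seed = 42)
  a <- generate_range_and_climate(cfg, n_climate_vars = 5)
  b <- generate_range_and_climate(cfg, n_climate_vars = 5)
  expect_identical(a, b)
  expect_gte(nrow(a$range_map$cells), 200)
  clim <- a$climate[paste0("clim", 1:5)]
  expect_equal(dim(clim), c(nrow(a$range_map$cells), 5))
  expect_false(anyNA(clim))
  expect_true(all(thermoplast:::.in_polygon(a$range_map$cells,
                                            a$range_map$boundary)))
  expect_error(generate_range_and_climate(cfg, n_vertices = 2), "vertices")
})

test_that("zero climate noise makes every variable an exact function of latitude", {
  cfg <- synthetic_config(rng_seed = 7)
  g <- generate_range_and_climate(cfg, climate_noise_sd = 0)
  for (v in grep("^clim", names(g$climate), value = TRUE)) {
    fit <- lm(g$climate[[v]] ~ g$climate$y)
    expect_lt(max(abs(resid(fit))), 1e-10)
  }
})

test_that("population placement spans the boundary-distance gradient", {
  cfg <- synthetic_config(rng_seed = 9)
  g <- generate_range_and_climate(cfg)
  s1 <- place_populations(g$range_map, 50, seed = 4)
  s2 <- place_populations(g$range_map, 50, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(unique(s1[c("x", "y")])), 50)
  d_all <- thermoplast:::.points_to_ring_distance(g$range_map$cells,
                                                  g$range_map$boundary)
  expect_lte(min(s1$edge_dist_km), quantile(d_all, 0.10))
  expect_gte(max(s1$edge_dist_km), quantile(d_all, 0.90))
  # brute-force check of the stored boundary distances
  for (i in c(1, 25, 50)) {
    oracle <- dense_boundary_distance(c(s1$x[i], s1$y[i]),
                                      g$range_map$boundary)$d_all
    expect_equal(s1$edge_dist_km[i], oracle, tolerance = 1e-3)
  }
  s3 <- place_populations(g$range_map, 2, seed = 1)
  expect_equal(nrow(unique(s3[c("x", "y")])), 2)
  expect_error(place_populations(g$range_map, 1e6), "too small")
})

test_that("landscapes honor the heterogeneity knob", {
  cfg <- synthetic_config(rng_seed = 3, raster_size = 128)
  flat <- generate_landscape(config = cfg, knob = 0)
  expect_equal(length(unique(as.vector(flat$land_cover$values))), 1L)
  expect_equal(shannon_diversity(extract_square_buffer(flat$land_cover,
                                                       c(0, 0))), 0)
  expect_equal(average_roughness(extract_square_buffer(flat$elevation,
                                                       c(0, 0))), 0)
  a <- generate_landscape(config = cfg, seed = 5, knob = 0.7)
  b <- generate_landscape(config = cfg, seed = 5, knob = 0.7)
  expect_identical(a, b)
  small <- synthetic_config(raster_size = 50)
  expect_error(generate_landscape(config = small), "buffer")
})

test_that("mean SHDI and ARE increase with the heterogeneity knob", {
  cfg <- synthetic_config(rng_seed = 1, raster_size = 110)
  knobs <- c(0.1, 0.55, 1)
  reps <- 40
  shdi <- are <- matrix(NA_real_, reps, length(knobs))
  for (r in seq_len(reps)) {
    for (k in seq_along(knobs)) {
      land <- generate_landscape(config = cfg, seed = 1000 * k + r,
                                 knob = knobs[k])
      shdi[r, k] <- shannon_diversity(extract_square_buffer(land$land_cover,
                                                            c(0, 0)))
      are[r, k] <- average_roughness(extract_square_buffer(land$elevation,
                                                           c(0, 0)))
    }
  }
  expect_true(all(diff(colMeans(shdi)) > 0))
  expect_true(all(diff(colMeans(are)) > 0))
  # knob 0 sits below everything
  expect_gt(mean(shdi[, 1]), 0)
})

test_that("simulated trait data is deterministic and respects binomial bounds", {
  cfg <- synthetic_config(rng_seed = 8, fixed_intercept = 0.5,
                          fixed_slope = -0.05, n_populations = 10)
  sites <- data.frame(population = sprintf("P%02d", 1:10),
                      rp = rnorm(10), eh = rnorm(10))
  a <- simulate_trait_data(sites, cfg, family = "binomial", seed = 8)
  b <- simulate_trait_data(sites, cfg, family = "binomial", seed = 8)
  expect_identical(a, b)
  obs <- a$observations
  expect_true(all(obs$n_germinated >= 0))
  expect_true(all(obs$n_germinated <= obs$n_viable))
  expect_true(all(obs$value >= 0 & obs$value <= 1, na.rm = TRUE))
  expect_equal(nrow(a$truth), 10)
  expect_true(all(is.finite(a$truth$slope_true)))
})

test_that("zeroed noise makes every population slope equal the fixed slope", {
  cfg <- synthetic_config(sigma_slope = 0, sigma_resid = 0,
                          sigma_intercept = 0, sigma_replicate = 0,
                          fixed_slope = 0.7, n_populations = 6, rng_seed = 2)
  sites <- data.frame(population = sprintf("P%02d", 1:6), rp = 0, eh = 0)
  sim <- simulate_trait_data(sites, cfg, family = "gaussian", seed = 2)
  expect_true(all(abs(abs(sim$truth$slope_true) - 0.7) < 1e-12))
  fit <- fit_reaction_norm(sim$observations, "gaussian")
  expect_true(all(abs(abs(coef(fit)$slope_per_C) - 0.7) < 1e-6))
})

test_that("expected |slope| is linear in the drivers with the configured gammas", {
  n <- 300
  cfg <- synthetic_config(gamma_eh = 0.5, fixed_slope = 2, sigma_slope = 0.05,
                          n_populations = n, rng_seed = 31)
  set.seed(99)
  sites <- data.frame(population = sprintf("P%03d", 1:n),
                      rp = rnorm(n), eh = rnorm(n))
  sim <- simulate_trait_data(sites, cfg, family = "gaussian", seed = 31)
  fit <- lm(plasticity_true ~ rp + eh + rp:eh, data = sim$truth)
  est <- coef(summary(fit))
  expect_lt(abs(est["eh", "Estimate"] - 0.5), 3 * est["eh", "Std. Error"])
  expect_lt(abs(est["rp", "Estimate"]), 3 * est["rp", "Std. Error"])
  # full three-driver surface at larger magnitudes
  cfg2 <- synthetic_config(gamma_rp = 0.3, gamma_eh = 0.4, gamma_int = 0.25,
                           fixed_slope = 3, sigma_slope = 0.05,
                           n_populations = n, rng_seed = 32)
  sim2 <- simulate_trait_data(sites, cfg2, family = "gaussian", seed = 32)
  fit2 <- lm(plasticity_true ~ rp * eh, data = sim2$truth)
  est2 <- coef(summary(fit2))
  expect_lt(abs(est2["rp", "Estimate"] - 0.3), 3 * est2["rp", "Std. Error"])
  expect_lt(abs(est2["eh", "Estimate"] - 0.4), 3 * est2["eh", "Std. Error"])
  expect_lt(abs(est2["rp:eh", "Estimate"] - 0.25),
            3 * est2["rp:eh", "Std. Error"])
})

test_that("the full synthetic study chains the analysis modules end to end", {
  cfg <- synthetic_config(n_populations = 8, rng_seed = 21,
                          gamma_eh = 0.3, fixed_slope = 1)
  study <- simulate_study(cfg)
  expect_equal(nrow(study$sites), 8)
  expect_equal(mean(study$sites$rp), 0, tolerance = 1e-9)
  expect_equal(sd(study$sites$eh), 1, tolerance = 1e-9)
  expect_equal(sort(unique(study$observations$population)),
               sort(study$sites$population))
})
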