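#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator into a validated list.
#' Defaults emulate a three-species common-garden experiment: populations
#' grown at four daytime temperatures (16/20/24/28 degrees C) in two
#' replicate chambers, with up to 10 potted plants per population and
#' treatment, and 25-seed germination dishes.
#'
#' The population-level reaction-norm slope is driven by range position (RP)
#' and environmental heterogeneity (EH) through
#' `|slope| = |fixed_slope| + gamma_rp * RP + gamma_eh * EH +
#' gamma_int * RP * EH + e`, with `e ~ Normal(0, sigma_slope)`, the magnitude
#' floored at zero, and a random sign so that plasticity (an absolute value)
#' is the driven quantity while both response directions occur.
#'
#' @param n_species number of species.
#' @param n_populations populations per species.
#' @param treatments_C daytime treatment temperatures in degrees C
#'   (at least two distinct values).
#' @param n_replicates replicate chambers per treatment.
#' @param n_individuals potted plants per population x treatment x replicate.
#' @param seeds_per_dish seeds sown per germination dish.
#' @param fixed_intercept,fixed_slope fixed-effect intercept (trait units at
#'   the mean temperature) and slope (trait units per degree C; logit units
#'   per degree C for germination).
#' @param sigma_intercept,sigma_slope SDs of the population-level random
#'   intercept and of the slope noise `e`.
#' @param slope_intercept_corr correlation between intercept and slope
#'   random deviations, in `[-1, 1]`.
#' @param gamma_rp,gamma_eh,gamma_int true driver coefficients of `|slope|`
#'   on range position, heterogeneity, and their interaction (slope units per
#'   z-scaled driver unit).
#' @param sigma_resid residual SD of Gaussian traits.
#' @param sigma_replicate SD of the replicate (chamber) random intercept.
#' @param raster_size land-cover/elevation raster side length in cells.
#' @param raster_resolution_m raster resolution in meters.
#' @param n_landcover_classes number of land-cover classes.
#' @param heterogeneity_knob value in `[0, 1]` controlling landscape
#'   heterogeneity around a site: 0 gives a uniform landscape and flat
#'   terrain, 1 gives fine-grained land cover and maximal relief.
#' @param elev_relief_m elevation-field amplitude (meters) at knob = 1.
#' @param rng_seed integer seed; all generator functions derive their
#'   randomness from it so identical configurations reproduce bit-identical
#'   outputs.
#' @return an object of class `"synthetic_config"` (a named list).
#' @export
synthetic_config <- function(n_species = 3L,
                             n_populations = 13L,
                             treatments_C = c(16, 20, 24, 28),
                             n_replicates = 2L,
                             n_individuals = 10L,
                             seeds_per_dish = 25L,
                             fixed_intercept = 10,
                             fixed_slope = 0.5,
                             sigma_intercept = 1,
                             sigma_slope = 0.1,
                             slope_intercept_corr = 0,
                             gamma_rp = 0,
                             gamma_eh = 0,
                             gamma_int = 0,
                             sigma_resid = 1,
                             sigma_replicate = 0.2,
                             raster_size = 128L,
                             raster_resolution_m = 10,
                             n_landcover_classes = 5L,
                             heterogeneity_knob = 0.5,
                             elev_relief_m = 100,
                             rng_seed = 1L) {
  cfg <- list(
    n_species = .check_count(n_species, "n_species"),
    n_populations = .check_count(n_populations, "n_populations", min = 2L),
    treatments_C = as.numeric(treatments_C),
    n_replicates = .check_count(n_replicates, "n_replicates"),
    n_individuals = .check_count(n_individuals, "n_individuals"),
    seeds_per_dish = .check_count(seeds_per_dish, "seeds_per_dish"),
    fixed_intercept = as.numeric(fixed_intercept),
    fixed_slope = as.numeric(fixed_slope),
    sigma_intercept = .check_nonneg(sigma_intercept, "sigma_intercept"),
    sigma_slope = .check_nonneg(sigma_slope, "sigma_slope"),
    slope_intercept_corr = as.numeric(slope_intercept_corr),
    gamma_rp = as.numeric(gamma_rp),
    gamma_eh = as.numeric(gamma_eh),
    gamma_int = as.numeric(gamma_int),
    sigma_resid = .check_nonneg(sigma_resid, "sigma_resid"),
    sigma_replicate = .check_nonneg(sigma_replicate, "sigma_replicate"),
    raster_size = .check_count(raster_size, "raster_size", min = 8L),
    raster_resolution_m = .check_nonneg(raster_resolution_m, "raster_resolution_m"),
    n_landcover_classes = .check_count(n_landcover_classes, "n_landcover_classes"),
    heterogeneity_knob = as.numeric(heterogeneity_knob),
    elev_relief_m = .check_nonneg(elev_relief_m, "elev_relief_m"),
    rng_seed = .check_count(rng_seed, "rng_seed", min = 0L)
  )
  if (length(unique(cfg$treatments_C)) < 2L) {
    .stopf("`treatments_C` needs at least 2 distinct temperatures")
  }
  if (abs(cfg$slope_intercept_corr) > 1) {
    .stopf("`slope_intercept_corr` must lie in [-1, 1]")
  }
  if (any(cfg$heterogeneity_knob < 0 | cfg$heterogeneity_knob > 1)) {
    .stopf("`heterogeneity_knob` must lie in [0, 1]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic species range with a climate grid
#'
#' Builds a star-shaped, convex-ish range polygon (a noisy ellipse in planar
#' km coordinates) and a regular grid of cell centers inside it, each cell
#' carrying `n_climate_vars` climate variables that follow a monotone
#' north--south gradient plus independent Gaussian noise, so that a climatic
#' niche structure exists.
#'
#' @param config a [synthetic_config()].
#' @param n_climate_vars number of climate variables (>= 2).
#' @param cell_spacing_km grid spacing of climate cells, km.
#' @param climate_noise_sd SD of the per-cell noise added to each variable
#'   (gradient units); 0 makes every variable an exact function of latitude.
#' @param n_vertices number of polygon vertices (>= 3).
#' @param semi_axes_km ellipse semi-axes (east-west, north-south), km.
#' @param seed RNG seed; defaults to `config$rng_seed`.
#' @return list with elements `range_map` (class `"range_map"`: `boundary`,
#'   an open ring of vertices in km, and `cells`, interior cell centers) and
#'   `climate` (data frame: `cell`, `x`, `y`, `clim1..climk`).
#' @export
generate_range_and_climate <- function(config,
                                       n_climate_vars = 4L,
                                       cell_spacing_km = 25,
                                       climate_noise_sd = 0.3,
                                       n_vertices = 72L,
                                       semi_axes_km = c(500, 300),
                                       seed = config$rng_seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n_climate_vars <- .check_count(n_climate_vars, "n_climate_vars", min = 2L)
  if (n_vertices < 3L) .stopf("range polygon needs at least 3 vertices")
  set.seed(.child_seed(seed, 101L))

  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  # low-order Fourier perturbation of the radius keeps the ring simple
  mult <- rep(1, n_vertices)
  for (h in 2:5) {
    mult <- mult + stats::runif(1, 0, 0.04) *
      cos(h * theta + stats::runif(1, 0, 2 * pi))
  }
  boundary <- cbind(
    x = semi_axes_km[1L] * mult * cos(theta),
    y = semi_axes_km[2L] * mult * sin(theta)
  )

  xs <- seq(min(boundary[, 1L]), max(boundary[, 1L]), by = cell_spacing_km)
  ys <- seq(min(boundary[, 2L]), max(boundary[, 2L]), by = cell_spacing_km)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  inside <- .in_polygon(grid, boundary)
  cells <- grid[inside, , drop = FALSE]

  range_map <- structure(list(boundary = boundary, cells = cells),
                         class = "range_map")

  # each climate variable: gradient in latitude (sign alternates) + noise
  k <- n_climate_vars
  grad <- stats::runif(k, 0.5, 1.5) * rep_len(c(1, -1), k)
  clim <- vapply(seq_len(k), function(j) {
    grad[j] * cells[, 2L] / 100 +
      stats::rnorm(nrow(cells), 0, climate_noise_sd)
  }, numeric(nrow(cells)))
  colnames(clim) <- paste0("clim", seq_len(k))
  climate <- data.frame(cell = seq_len(nrow(cells)),
                        x = cells[, 1L], y = cells[, 2L], clim)
  list(range_map = range_map, climate = climate)
}

#' Place population sites inside a range
#'
#' Samples `n` distinct interior sites spanning the full gradient of
#' distances to the range boundary: one site is drawn from the lowest decile
#' of interior boundary distances, one from the top decile, and the rest are
#' stratified over the remaining quantiles.
#'
#' @param range_map a `"range_map"` from [generate_range_and_climate()].
#' @param n number of sites (>= 2).
#' @param seed RNG seed.
#' @return data frame: `population`, `x`, `y` (km), `edge_dist_km`.
#' @export
place_populations <- function(range_map, n, seed = 1L) {
  stopifnot(inherits(range_map, "range_map"))
  n <- .check_count(n, "n", min = 2L)
  cand <- range_map$cells
  if (nrow(cand) < n) {
    .stopf("range polygon too small: %d candidate cells for %d sites",
           nrow(cand), n)
  }
  set.seed(.child_seed(seed, 202L))
  d <- .points_to_ring_distance(cand, range_map$boundary)
  q10 <- stats::quantile(d, 0.10)
  q90 <- stats::quantile(d, 0.90)
  near <- which(d <= q10)
  far <- which(d >= q90)
  pick <- c(sample(near, 1L), sample(far, 1L))
  if (n > 2L) {
    rest <- setdiff(order(d), pick)
    bins <- split(rest, cut(seq_along(rest), n - 2L, labels = FALSE))
    pick <- c(pick, vapply(bins, function(ix) ix[sample.int(length(ix), 1L)],
                           integer(1L)))
  }
  data.frame(
    population = sprintf("P%02d", seq_len(n)),
    x = cand[pick, 1L], y = cand[pick, 2L],
    edge_dist_km = d[pick],
    row.names = NULL
  )
}

# Gaussian smoothing matrix for one raster axis; column-normalized so a
# constant field stays constant.
.smooth_kernel <- function(n, len) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * len^2))
  K / rowSums(K)
}

# Smoothed standard-normal random field on an n x n grid.
.random_field <- function(n, len) {
  Z <- matrix(stats::rnorm(n * n), n, n)
  if (len > 0) {
    K <- .smooth_kernel(n, len)
    Z <- K %*% Z %*% t(K)
  }
  (Z - mean(Z)) / stats::sd(Z)
}

#' Generate land-cover and elevation rasters around a site
#'
#' Thresholds a smoothed Gaussian random field into land-cover classes and
#' scales a second smoothed field into elevation. The smoothing length of
#' the land-cover field decreases geometrically with `heterogeneity_knob`
#' and the elevation amplitude grows linearly with it, so the expected
#' Shannon diversity and the expected elevation roughness of the 500-m
#' buffer are both non-decreasing in the knob. At knob 0 the landscape is a
#' single class on flat terrain.
#'
#' Rasters are returned in a local frame with the site at the origin
#' `(0, 0)` and must cover at least the site's 500-m square buffer.
#'
#' @param site unused placeholder identifying the site (kept for
#'   bookkeeping; the raster frame is always site-centered).
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param knob optional override of `config$heterogeneity_knob`.
#' @return list with `land_cover` and `elevation`, both [ascii_grid()]
#'   objects.
#' @export
generate_landscape <- function(site = NULL, config, seed = config$rng_seed,
                               knob = config$heterogeneity_knob) {
  stopifnot(inherits(config, "synthetic_config"))
  if (knob < 0 || knob > 1) .stopf("`knob` must lie in [0, 1]")
  n <- config$raster_size
  res <- config$raster_resolution_m
  half_extent <- n * res / 2
  if (half_extent < 500 + res) {
    .stopf("raster (%.0f m half-extent) smaller than the 500-m buffer",
           half_extent)
  }
  origin <- c(-half_extent, -half_extent)
  set.seed(.child_seed(seed, 303L))

  if (knob == 0) {
    lc <- matrix(1L, n, n)
    elev <- matrix(0, n, n)
  } else {
    # geometric interpolation of the smoothing length: coarse blobs at low
    # knob, near-cell-scale grain at knob = 1
    len_max <- n / 2
    len_min <- 1.2
    len <- len_max^(1 - knob) * len_min^knob
    field <- .random_field(n, len)
    ncl <- config$n_landcover_classes
    breaks <- c(-Inf, stats::qnorm(seq_len(ncl - 1L) / ncl), Inf)
    lc <- matrix(as.integer(cut(field, breaks)), n, n)
    elev <- .random_field(n, 15) * config$elev_relief_m * knob
  }
  list(
    land_cover = ascii_grid(lc, resolution_m = res, origin = origin),
    elevation = ascii_grid(elev, resolution_m = res, origin = origin)
  )
}

#' Simulate individual-level trait data with known ground truth
#'
#' Draws population-level reaction norms and individual observations for one
#' trait. Two slope models are available: `"plain"` is the classic random
#' regression `b_k = fixed_slope + e_k`; `"driven"` builds the slope from
#' range position and heterogeneity as
#' `b_k = s_k * max(0, |fixed_slope| + gamma_rp RP + gamma_eh EH +
#' gamma_int RP EH + e_k)` with a random sign `s_k`. By default the driven
#' form is used whenever any `gamma` is non-zero.
#'
#' Gaussian traits are `y = a_k + b_k T_c + replicate effect +
#' Normal(0, sigma_resid)`, with `T_c` the centered treatment temperature in
#' degrees C. Germination is dish-level: cut-test categories (empty,
#' infested, moldy) are drawn per dish, and the germinated count is
#' `Binomial(viable, inverse-logit(a_k + b_k T_c + replicate effect))`.
#'
#' @param sites data frame with columns `population`, `rp`, `eh` (z-scaled
#'   driver values per site).
#' @param config a [synthetic_config()].
#' @param family `"gaussian"` or `"binomial"`.
#' @param trait trait label written into the output.
#' @param species species label written into the output.
#' @param slope_model `"auto"`, `"plain"`, or `"driven"`.
#' @param seed RNG seed.
#' @return list with `observations` (a trait table; for binomial rows the
#'   value is the dish-level germinated proportion and `n_viable`,
#'   `n_germinated` are carried along) and `truth` (per-population true
#'   intercepts, slopes, plasticities, and the driver coefficients as
#'   attributes).
#' @export
simulate_trait_data <- function(sites, config,
                                family = c("gaussian", "binomial"),
                                trait = "trait", species = "S1",
                                slope_model = c("auto", "plain", "driven"),
                                seed = config$rng_seed) {
  stopifnot(inherits(config, "synthetic_config"))
  family <- match.arg(family)
  slope_model <- match.arg(slope_model)
  if (!all(c("population", "rp", "eh") %in% names(sites))) {
    .stopf("`sites` must have columns population, rp, eh")
  }
  if (slope_model == "auto") {
    slope_model <- if (config$gamma_rp != 0 || config$gamma_eh != 0 ||
                         config$gamma_int != 0) "driven" else "plain"
  }
  set.seed(.child_seed(seed, 404L))
  npop <- nrow(sites)
  rho <- config$slope_intercept_corr
  z1 <- stats::rnorm(npop)
  z2 <- stats::rnorm(npop)
  int_dev <- config$sigma_intercept * z1
  slope_e <- config$sigma_slope * (rho * z1 + sqrt(1 - rho^2) * z2)
  a_k <- config$fixed_intercept + int_dev
  if (slope_model == "plain") {
    b_k <- config$fixed_slope + slope_e
  } else {
    mag <- pmax(0, abs(config$fixed_slope) +
                  config$gamma_rp * sites$rp +
                  config$gamma_eh * sites$eh +
                  config$gamma_int * sites$rp * sites$eh +
                  slope_e)
    s_k <- sample(c(-1, 1), npop, replace = TRUE)
    b_k <- s_k * mag
  }

  temps <- config$treatments_C
  t_c <- temps - mean(temps)
  rep_ids <- sprintf("R%d", seq_len(config$n_replicates))
  rep_eff <- stats::rnorm(config$n_replicates, 0, config$sigma_replicate)
  names(rep_eff) <- rep_ids

  if (family == "gaussian") {
    design <- expand.grid(
      ind = seq_len(config$n_individuals), replicate = rep_ids,
      treatment_C = temps, population = sites$population,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    k <- match(design$population, sites$population)
    tc <- design$treatment_C - mean(temps)
    design$value <- a_k[k] + b_k[k] * tc + rep_eff[design$replicate] +
      stats::rnorm(nrow(design), 0, config$sigma_resid)
    obs <- data.frame(species = species, population = design$population,
                      replicate = design$replicate,
                      treatment_C = design$treatment_C,
                      trait = trait, value = design$value,
                      stringsAsFactors = FALSE)
  } else {
    design <- expand.grid(
      replicate = rep_ids, treatment_C = temps, population = sites$population,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    k <- match(design$population, sites$population)
    tc <- design$treatment_C - mean(temps)
    nsown <- config$seeds_per_dish
    cats <- t(vapply(seq_len(nrow(design)), function(i) {
      drop(stats::rmultinom(1, nsown, c(0.88, 0.05, 0.04, 0.03)))
    }, integer(4L)))
    viable <- nsown - cats[, 2L] - cats[, 4L]  # exclude empty and infested
    p <- stats::plogis(a_k[k] + b_k[k] * tc + rep_eff[design$replicate])
    germ <- stats::rbinom(nrow(design), viable, p)
    obs <- data.frame(species = species, population = design$population,
                      replicate = design$replicate,
                      treatment_C = design$treatment_C,
                      trait = trait, value = ifelse(viable > 0, germ / viable, NA),
                      n_viable = viable, n_germinated = germ,
                      n_empty = cats[, 2L], n_moldy = cats[, 3L],
                      n_infested = cats[, 4L],
                      stringsAsFactors = FALSE)
  }

  truth <- data.frame(
    species = species, population = sites$population,
    rp = sites$rp, eh = sites$eh,
    intercept_true = a_k, slope_true = b_k,
    plasticity_true = abs(b_k),
    stringsAsFactors = FALSE
  )
  attr(truth, "gamma") <- c(rp = config$gamma_rp, eh = config$gamma_eh,
                            int = config$gamma_int)
  attr(truth, "slope_model") <- slope_model
  list(observations = obs, truth = truth)
}

#' Simulate z-scaled site driver metrics
#'
#' Draws the five site metrics (DRE, DCE, SHDI, PAR, ARE) as mildly
#' equicorrelated Gaussian columns and z-scales each across sites. Used by
#' driver-analysis simulations where the full raster/geometry pipeline is
#' not needed.
#'
#' @param n_pops number of populations.
#' @param rho pairwise correlation between raw metric columns.
#' @param seed RNG seed.
#' @return data frame: `population`, `dre`, `dce`, `shdi`, `par`, `are`.
#' @export
simulate_driver_metrics <- function(n_pops, rho = 0.2, seed = 1L) {
  n_pops <- .check_count(n_pops, "n_pops", min = 3L)
  if (rho < 0 || rho >= 1) .stopf("`rho` must lie in [0, 1)")
  set.seed(.child_seed(seed, 505L))
  common <- stats::rnorm(n_pops)
  m <- vapply(1:5, function(j) {
    x <- sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n_pops)
    .zscale(x)
  }, numeric(n_pops))
  colnames(m) <- c("dre", "dce", "shdi", "par", "are")
  data.frame(population = sprintf("P%02d", seq_len(n_pops)), m,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic study
#'
#' Chains the generator end to end: range polygon and climate grid,
#' population placement, per-site landscapes with site-specific
#' heterogeneity, real range-position (DRE) and heterogeneity (SHDI)
#' metrics computed by the analysis modules, and trait data whose
#' population slopes are driven by the z-scaled metrics.
#'
#' @param config a [synthetic_config()].
#' @param family error family for the simulated trait.
#' @param trait trait label.
#' @return list: `range_map`, `climate`, `sites` (with metrics and z-scaled
#'   `rp`, `eh`), `observations`, `truth`.
#' @export
simulate_study <- function(config = synthetic_config(),
                           family = "gaussian", trait = "trait") {
  stopifnot(inherits(config, "synthetic_config"))
  geo <- generate_range_and_climate(config)
  n_sites <- config$n_populations
  sites <- place_populations(geo$range_map, n_sites,
                             seed = .child_seed(config$rng_seed, 7L))
  set.seed(.child_seed(config$rng_seed, 606L))
  knobs <- stats::runif(n_sites, 0.05, 1)
  shdi <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    land <- generate_landscape(config = config,
                               seed = .child_seed(config$rng_seed, 700L + i),
                               knob = knobs[i])
    buf <- extract_square_buffer(land$land_cover, c(0, 0))
    shdi[i] <- shannon_diversity(buf)
  }
  sites$dre_km <- vapply(seq_len(n_sites), function(i) {
    distance_to_range_edge(c(sites$x[i], sites$y[i]), geo$range_map)$dre_km
  }, numeric(1L))
  sites$shdi <- shdi
  sites$rp <- .zscale(sites$dre_km)
  sites$eh <- .zscale(sites$shdi)
  sim <- simulate_trait_data(sites, config, family = family, trait = trait,
                             seed = .child_seed(config$rng_seed, 808L))
  list(range_map = geo$range_map, climate = geo$climate, sites = sites,
       observations = sim$observations, truth = sim$truth)
}
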