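test_that("range-edge distance matches exact geometry on canonical shapes", {
  # circle of radius 100: center is 100 km from either edge
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  circle <- cbind(100 * cos(theta), 100 * sin(theta))
  d <- distance_to_range_edge(c(0, 0), circle)
  expect_equal(d$dre_km, 100, tolerance = 1e-3)
  expect_equal(d$d_north, d$d_south, tolerance = 1e-3)
  # rectangle 1000 km E-W x 200 km N-S; site 30 km from the northern side,
  # 400 km from the western side: east/west edges never win
  rect <- rbind(c(0, 0), c(1000, 0), c(1000, 200), c(0, 200))
  d2 <- distance_to_range_edge(c(400, 170), rect)
  expect_equal(d2$dre_km, 30)
  expect_equal(d2$side, "north")
  expect_equal(d2$d_south, 170)
  # site on the boundary has distance 0
  d3 <- distance_to_range_edge(c(400, 0), rect)
  expect_equal(d3$dre_km, 0)
  expect_error(distance_to_range_edge(c(-50, 100), rect), "outside")
})

test_that("range-edge distance is invariant to boundary vertex ordering", {
  rect <- rbind(c(0, 0), c(1000, 0), c(1000, 200), c(0, 200))
  site <- c(250, 60)
  a <- distance_to_range_edge(site, rect)
  b <- distance_to_range_edge(site, rect[c(3, 4, 1, 2), ])
  rev_rect <- rect[rev(seq_len(nrow(rect))), ]
  c_ <- distance_to_range_edge(site, rev_rect)
  expect_equal(a$dre_km, b$dre_km)
  expect_equal(a$dre_km, c_$dre_km)
})

test_that("range-edge distances agree with dense boundary sampling", {
  set.seed(14)
  for (r in 1:100) {
    radius <- runif(1, 50, 200)
    ring <- random_blob(n_vertices = sample(30:80, 1), radius = radius)
    # random interior site, kept off the boundary so the sampled oracle's
    # resolution does not dominate the comparison
    repeat {
      site <- c(runif(1, min(ring[, 1]), max(ring[, 1])),
                runif(1, min(ring[, 2]), max(ring[, 2])))
      if (thermoplast:::.in_polygon(rbind(site), ring) &&
            min(thermoplast:::.points_to_ring_distance(rbind(site), ring)) >
              0.02 * radius) break
    }
    got <- distance_to_range_edge(site, ring)
    oracle <- dense_boundary_distance(site, ring, n_samples = 2e4)
    expect_equal(got$dre_km, oracle$d_all, tolerance = 5e-3)
    expect_equal(got$dre_km, min(got$d_north, got$d_south))
    expect_gte(min(oracle$d_north, oracle$d_south) + 1e-9, got$dre_km)
  }
})

test_that("climatic PCA scales from range cells and projects sites consistently", {
  set.seed(8)
  cells <- data.frame(clim1 = rnorm(200, 10, 2), clim2 = rnorm(200, -3, 5),
                      clim3 = rnorm(200))
  sitec <- cells[1:5, ]  # sites identical to cells score identically
  pca <- climatic_pca(cells, sitec)
  expect_equal(pca$site_scores, pca$cell_scores[1:5, , drop = FALSE],
               ignore_attr = TRUE)
  # loadings orthonormal; scores reproduce z %*% loadings
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  z <- scale(as.matrix(cells))
  expect_equal(unname(pca$cell_scores), unname(z %*% pca$loadings),
               tolerance = 1e-8)
  # one dominant axis: variables are noisy replicates of one gradient
  # (z-scoring gives every variable unit variance, so dominance must come
  # from correlation, not raw variance)
  grad <- seq(0, 10, length.out = 100)
  one <- data.frame(clim1 = grad, clim2 = grad + rnorm(100, 0, 1e-4),
                    clim3 = -2 * grad + rnorm(100, 0, 1e-4))
  p1 <- climatic_pca(one, one[1:2, ])
  expect_gte(p1$var_share[1], 0.99)
  # two perfectly correlated variables load as (1,1)/sqrt(2) on PC1
  x <- rnorm(100)
  two <- data.frame(clim1 = x, clim2 = 2 * x + 5)
  p2 <- climatic_pca(two, two[1:2, ])
  expect_equal(abs(p2$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero-variance variables are dropped with a warning
  cells$flat <- 1
  expect_warning(climatic_pca(cells, transform(sitec, flat = 1)), "zero-variance")
})

test_that("convex hull is counterclockwise, minimal, and contains all points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  hull <- convex_hull_2d(sq)
  expect_equal(nrow(hull), 4)
  # counterclockwise: positive signed area
  xs <- hull[, 1]; ys <- hull[, 2]
  expect_gt(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys), 0)
  # duplicates collapse
  dup <- rbind(matrix(0, 5, 2), c(1, 0), c(0, 1))
  expect_equal(nrow(convex_hull_2d(dup)), 3)
  expect_error(convex_hull_2d(cbind(1:5, 2 * (1:5))), "collinear")
  # brute-force half-plane check: every point inside or on the hull
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2)
  h <- convex_hull_2d(pts)
  hc <- rbind(h, h[1, ])
  for (i in seq_len(nrow(h))) {
    a <- hc[i, ]; b <- hc[i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
             (b[2] - a[2]) * (pts[, 1] - a[1])
    expect_true(all(cross >= -1e-9))
  }
})

test_that("hull-edge distance matches analytic cases and dense sampling", {
  sq <- convex_hull_2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(distance_to_climatic_edge(c(0.5, 0.5), sq)$dce, 0.5)
  expect_equal(distance_to_climatic_edge(c(0.2, 0.6), sq)$dce, 0.2)
  on_vertex <- distance_to_climatic_edge(c(0, 0), sq)
  expect_equal(on_vertex$dce, 0)
  expect_false(on_vertex$exterior)
  outside <- distance_to_climatic_edge(c(2, 0.5), sq)
  expect_equal(outside$dce, 1)
  expect_true(outside$exterior)
  # dce never exceeds the distance to any hull vertex
  set.seed(21)
  for (r in 1:100) {
    pts <- matrix(rnorm(30, sd = 5), ncol = 2)
    hull <- convex_hull_2d(pts)
    score <- c(mean(pts[, 1]), mean(pts[, 2])) + rnorm(2, 0, 2)
    got <- distance_to_climatic_edge(score, hull)$dce
    vd <- sqrt((hull[, 1] - score[1])^2 + (hull[, 2] - score[2])^2)
    expect_lte(got, min(vd) + 1e-12)
    oracle <- dense_boundary_distance(score, hull)$d_all
    expect_equal(got, oracle, tolerance = max(5e-3 * got, 1e-6))
  }
})

test_that("shrinking a hull toward its centroid scales the centroid DCE", {
  set.seed(9)
  pts <- matrix(rnorm(40, sd = 3), ncol = 2)
  hull <- convex_hull_2d(pts)
  centroid <- colMeans(hull)
  d1 <- distance_to_climatic_edge(centroid, hull)$dce
  lam <- 0.4
  shrunk <- sweep(sweep(hull, 2, centroid), 1, rep(lam, nrow(hull)), "*")
  shrunk <- sweep(shrunk, 2, centroid, "+")
  d2 <- distance_to_climatic_edge(centroid, shrunk)$dce
  expect_equal(d2, lam * d1, tolerance = 1e-9)
})

test_that("range-position metrics assemble and z-scale per run", {
  cfg <- synthetic_config(rng_seed = 33)
  geo <- generate_range_and_climate(cfg)
  sites <- place_populations(geo$range_map, 12, seed = 2)
  site_climates <- geo$climate[sample(nrow(geo$climate), 12), ]
  rp <- range_position_metrics(sites, geo$range_map, geo$climate,
                               site_climates)
  expect_equal(nrow(rp), 12)
  expect_true(all(rp$dre_km >= 0))
  expect_true(all(rp$dce >= 0))
  expect_equal(mean(rp$dre_z), 0, tolerance = 1e-9)
  expect_equal(sd(rp$dce_z), 1, tolerance = 1e-9)
})
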