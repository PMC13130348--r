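# Independent naive reference implementations used as oracles. These share
# no code with the package: plain nested loops and brute-force enumeration.

naive_shdi <- function(m) {
  classes <- unique(as.vector(m))
  total <- length(m)
  h <- 0
  for (cl in classes) {
    cnt <- 0
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] == cl) cnt <- cnt + 1
    }
    p <- cnt / total
    if (p > 0) h <- h - p * log(p)
  }
  h
}

# Label propagation to a fixed point: every cell starts as its own patch and
# repeatedly takes the minimum label among equal-class neighbors.
naive_patches <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  if (connectivity == 8) {
    nbrs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                  c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    nbrs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      for (k in seq_len(nrow(nbrs))) {
        ni <- i + nbrs[k, 1]; nj <- j + nbrs[k, 2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              m[ni, nj] == m[i, j] && lab[ni, nj] < lab[i, j]) {
          lab[i, j] <- lab[ni, nj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# Per-patch (perimeter, area) by looping over cells and their four sides.
naive_patch_stats <- function(m, res, connectivity = 8) {
  lab <- naive_patches(m, connectivity)
  ids <- sort(unique(as.vector(lab)))
  out <- data.frame(id = ids, area = 0, perim = 0)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    row <- match(lab[i, j], ids)
    out$area[row] <- out$area[row] + res^2
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      outside <- ni < 1 || ni > nrow(m) || nj < 1 || nj > ncol(m)
      if (outside || lab[ni, nj] != lab[i, j]) {
        out$perim[row] <- out$perim[row] + res
      }
    }
  }
  out
}

naive_par <- function(m, res, connectivity = 8) {
  st <- naive_patch_stats(m, res, connectivity)
  mean(st$perim / st$area)
}

naive_are <- function(z) {
  zbar <- sum(z) / length(z)
  s <- 0
  for (v in as.vector(z)) s <- s + abs(v - zbar)
  s / length(z)
}

# LMG by explicit enumeration of all t! regressor orderings.
naive_lmg <- function(X, y) {
  t_reg <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  shares <- numeric(t_reg)
  all_p <- perms(seq_len(t_reg))
  for (p in all_p) {
    for (pos in seq_along(p)) {
      j <- p[pos]
      before <- p[seq_len(pos - 1)]
      shares[j] <- shares[j] + (r2(c(before, j)) - r2(before))
    }
  }
  shares / length(all_p)
}

# Distance oracles: densely sample boundary pieces and take the minimum
# point distance. `classify` optionally restricts to the north/south split
# at the site latitude (pieces are sampled, then filtered by y).
dense_boundary_distance <- function(site, ring, n_samples = 1e4) {
  verts <- rbind(ring, ring[1, , drop = FALSE])
  seg_len <- sqrt(diff(verts[, 1])^2 + diff(verts[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  s <- seq(0, cum[length(cum)], length.out = n_samples)
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[seg]) / pmax(seg_len[seg], 1e-300)
  px <- verts[seg, 1] + frac * (verts[seg + 1, 1] - verts[seg, 1])
  py <- verts[seg, 2] + frac * (verts[seg + 1, 2] - verts[seg, 2])
  d <- sqrt((px - site[1])^2 + (py - site[2])^2)
  safe_min <- function(v) if (length(v)) min(v) else Inf
  list(d_all = min(d),
       d_north = safe_min(d[py >= site[2]]),
       d_south = safe_min(d[py <= site[2]]))
}

# Random star-shaped test polygon (radius perturbed by smooth noise).
random_blob <- function(n_vertices = 60, radius = 100) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- radius * (1 + 0.25 * sin(3 * theta + runif(1, 0, 2 * pi)) +
                   0.15 * cos(5 * theta + runif(1, 0, 2 * pi)))
  cbind(r * cos(theta), r * sin(theta))
}

# Balanced Gaussian reaction-norm data for a given population-slope SD.
make_norm_data <- function(n_pop = 20, sd_slope = 0.3, sigma_resid = 1,
                           n_ind = 10, fixed_slope = 0.5,
                           seed = 1) {
  cfg <- synthetic_config(n_populations = n_pop, sigma_slope = sd_slope,
                          sigma_resid = sigma_resid, n_individuals = n_ind,
                          fixed_slope = fixed_slope, rng_seed = seed)
  sites <- data.frame(population = sprintf("P%02d", seq_len(n_pop)),
                      rp = 0, eh = 0)
  simulate_trait_data(sites, cfg, family = "gaussian",
                      slope_model = "plain", seed = seed)
}
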