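#' Distance to the north/south range edge (DRE)
#'
#' Distance (km) from a site inside the range polygon to the nearer of the
#' northern and southern portions of the range boundary. The boundary is
#' split at the site's latitude (the east--west line through the site):
#' boundary segments, or pieces of segments, lying north of that line form
#' the northern edge and those lying south of it the southern edge; DRE is
#' the minimum over the two sets of exact point-to-segment distances.
#'
#' @param site numeric length-2 site coordinates (km, planar/projected).
#' @param range_map a `"range_map"` (or a two-column boundary matrix).
#' @return list: `dre_km`, `side` (`"north"`/`"south"`), `d_north`,
#'   `d_south`.
#' @export
distance_to_range_edge <- function(site, range_map) {
  ring <- if (inherits(range_map, "range_map")) range_map$boundary
          else as.matrix(range_map)
  site <- as.numeric(site)
  on_boundary <- min(.points_to_ring_distance(rbind(site), ring)) < 1e-9
  if (!on_boundary && !.in_polygon(rbind(site), ring)) {
    .stopf("site (%.3f, %.3f) lies outside the range polygon",
           site[1L], site[2L])
  }
  sy <- site[2L]
  verts <- rbind(ring, ring[1L, , drop = FALSE])
  d_north <- d_south <- Inf
  for (i in seq_len(nrow(verts) - 1L)) {
    a <- verts[i, ]; b <- verts[i + 1L, ]
    if (a[2L] >= sy && b[2L] >= sy) {
      d_north <- min(d_north, .point_segment_distance(rbind(site), a, b))
    } else if (a[2L] <= sy && b[2L] <= sy) {
      d_south <- min(d_south, .point_segment_distance(rbind(site), a, b))
    } else {
      # crossing segment: split at the site latitude
      t <- (sy - a[2L]) / (b[2L] - a[2L])
      c_ <- a + t * (b - a)
      up <- if (a[2L] > sy) a else b
      dn <- if (a[2L] < sy) a else b
      d_north <- min(d_north, .point_segment_distance(rbind(site), c_, up))
      d_south <- min(d_south, .point_segment_distance(rbind(site), c_, dn))
    }
  }
  list(dre_km = min(d_north, d_south),
       side = if (d_north <= d_south) "north" else "south",
       d_north = d_north, d_south = d_south)
}

#' Climatic-niche principal components
#'
#' z-scores the climate variables using means and SDs computed from the
#' range cells, applies the same scaling to the site climates, and runs a
#' PCA on the scaled cell matrix. Loadings are oriented so each component's
#' largest-magnitude loading is positive; site scores are projections of
#' the site rows with the cell-derived scaling and loadings.
#'
#' @param cell_climates data frame or matrix of climate variables over
#'   range cells (non-climate columns `cell`, `x`, `y` are ignored).
#' @param site_climates same variables for the sampled sites.
#' @return object of class `"niche_pca"`: `means`, `sds`, `loadings`,
#'   `var_share`, `cell_scores`, `site_scores`, `dropped` (zero-variance
#'   variables).
#' @export
climatic_pca <- function(cell_climates, site_climates) {
  drop_cols <- c("cell", "x", "y", "population")
  cm <- as.matrix(cell_climates[setdiff(colnames(cell_climates), drop_cols)])
  sm <- as.matrix(site_climates[setdiff(colnames(site_climates), drop_cols)])
  sm <- sm[, colnames(cm), drop = FALSE]
  if (nrow(cm) < 3L) .stopf("need >= 3 range cells")
  if (ncol(cm) < 2L) .stopf("need >= 2 climate variables")
  sds <- apply(cm, 2L, stats::sd)
  dropped <- colnames(cm)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance variable(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    cm <- cm[, sds > 0, drop = FALSE]
    sm <- sm[, colnames(cm), drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(cm) < 2L) .stopf("fewer than 2 climate variables vary")
  means <- colMeans(cm)
  zc <- sweep(sweep(cm, 2L, means), 2L, sds, "/")
  zs <- sweep(sweep(sm, 2L, means), 2L, sds, "/")
  eig <- eigen(stats::cov(zc), symmetric = TRUE)
  load <- eig$vectors
  # sign convention: largest-|loading| entry of each PC is positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(cm)
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  structure(list(
    means = means, sds = sds, loadings = load,
    var_share = eig$values / sum(eig$values),
    cell_scores = zc %*% load, site_scores = zs %*% load,
    dropped = dropped
  ), class = "niche_pca")
}

#' @export
print.niche_pca <- function(x, ...) {
  cat(sprintf("<niche_pca> %d cells, %d sites, %d variables\n",
              nrow(x$cell_scores), nrow(x$site_scores), nrow(x$loadings)))
  cat("variance shares:", paste(sprintf("%.3f", x$var_share), collapse = " "),
      "\n")
  invisible(x)
}

#' Convex hull of 2-D points
#'
#' Counterclockwise hull vertices; duplicated points collapse and interior
#' points are discarded. All-collinear input is an error (the hull would be
#' degenerate).
#'
#' @param points two-column matrix.
#' @return matrix of hull vertices in counterclockwise order.
#' @export
convex_hull_2d <- function(points) {
  pts <- unique(matrix(as.matrix(points), ncol = 2L))
  if (nrow(pts) < 3L) .stopf("need >= 3 distinct points for a hull")
  idx <- grDevices::chull(pts)
  hull <- pts[idx, , drop = FALSE]
  if (nrow(hull) < 3L) .stopf("all points are collinear: degenerate hull")
  # signed area > 0 means counterclockwise
  xs <- hull[, 1L]; ys <- hull[, 2L]
  area2 <- sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)
  if (abs(area2) < .Machine$double.eps * max(abs(pts))^2) {
    .stopf("all points are collinear: degenerate hull")
  }
  if (area2 < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  unname(hull)
}

#' Distance to the climatic-niche hull edge (DCE)
#'
#' Minimum Euclidean distance from each site score (in PC1--PC2 space) to
#' the edges of the convex hull. Sites outside the hull get the same
#' minimum edge distance with `exterior = TRUE`.
#'
#' @param site_scores two-column matrix (or length-2 vector) of PC scores.
#' @param hull hull vertices from [convex_hull_2d()].
#' @return data frame: `dce`, `exterior`.
#' @export
distance_to_climatic_edge <- function(site_scores, hull) {
  pts <- matrix(as.matrix(site_scores), ncol = 2L)
  d <- .points_to_ring_distance(pts, hull)
  inside <- .in_polygon(pts, hull) | d < 1e-12
  data.frame(dce = d, exterior = !inside)
}

#' Range-position metrics for a set of sites
#'
#' Computes DRE for every site from the range polygon and DCE from the
#' climatic-niche hull (PC1--PC2 of the range-cell climate), plus z-scaled
#' versions of both across the sites.
#'
#' @param sites data frame with `population`, `x`, `y` (km).
#' @param range_map a `"range_map"`.
#' @param cell_climates,site_climates climate variables for range cells and
#'   sites (rows of `site_climates` aligned with `sites`).
#' @return data frame: `population`, `dre_km`, `edge_side`, `dce`,
#'   `dce_exterior`, `dre_z`, `dce_z`.
#' @export
range_position_metrics <- function(sites, range_map, cell_climates,
                                   site_climates) {
  dre <- lapply(seq_len(nrow(sites)), function(i) {
    distance_to_range_edge(c(sites$x[i], sites$y[i]), range_map)
  })
  pca <- climatic_pca(cell_climates, site_climates)
  hull <- convex_hull_2d(pca$cell_scores[, 1:2])
  dce <- distance_to_climatic_edge(pca$site_scores[, 1:2], hull)
  out <- data.frame(
    population = sites$population,
    dre_km = vapply(dre, `[[`, numeric(1L), "dre_km"),
    edge_side = vapply(dre, `[[`, character(1L), "side"),
    dce = dce$dce, dce_exterior = dce$exterior,
    stringsAsFactors = FALSE
  )
  out$dre_z <- .zscale(out$dre_km)
  out$dce_z <- .zscale(out$dce)
  out
}
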