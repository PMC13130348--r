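# Internal geometry and validation helpers shared across modules.

#' Distance from points to a line segment
#'
#' Minimum Euclidean distance from each point to the segment `a`--`b`.
#' Works in any planar coordinate system; units follow the inputs.
#'
#' @param pts two-column matrix of point coordinates.
#' @param a,b numeric length-2 endpoints of the segment.
#' @return numeric vector of distances, one per row of `pts`.
#' @keywords internal
#' @noRd
.point_segment_distance <- function(pts, a, b) {
  pts <- matrix(pts, ncol = 2L)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2))
  }
  t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1L] + t * ab[1L]
  py <- a[2L] + t * ab[2L]
  sqrt((pts[, 1L] - px)^2 + (pts[, 2L] - py)^2)
}

# Minimum distance from each point in `pts` to a polyline given as a matrix of
# vertices; `closed = TRUE` appends the closing segment of a ring.
.points_to_ring_distance <- function(pts, ring, closed = TRUE) {
  pts <- matrix(pts, ncol = 2L)
  verts <- ring
  if (closed && !all(verts[1L, ] == verts[nrow(verts), ])) {
    verts <- rbind(verts, verts[1L, ])
  }
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(verts) - 1L)) {
    d <- pmin(d, .point_segment_distance(pts, verts[i, ], verts[i + 1L, ]))
  }
  d
}

# Point-in-polygon test for an open ring (first vertex not repeated).
.in_polygon <- function(pts, ring) {
  bnd <- rbind(ring, ring[1L, , drop = FALSE])
  mgcv::in.out(bnd, matrix(pts, ncol = 2L))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    .stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

.check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0) {
    .stopf("`%s` must be a single non-negative number", name)
  }
  as.numeric(x)
}

# Derive a child RNG seed from a base seed and an offset, kept within the
# 32-bit integer range accepted by set.seed().
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# z-scale a numeric vector using the sample SD; constant vectors are an error
# because downstream model matrices would be degenerate.
.zscale <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) .stopf("cannot scale `%s`: zero variance", name)
  (x - mean(x)) / s
}
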