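#' Planar raster grid
#'
#' Minimal in-memory raster: a numeric or integer matrix plus a resolution
#' and a lower-left origin. Row `i`, column `j` of `values` is the cell whose
#' center sits at `origin + ((j - 0.5), (i - 0.5)) * resolution_m`, i.e. row
#' index increases northward.
#'
#' @param values matrix of cell values (categorical class labels or
#'   continuous elevations in meters).
#' @param resolution_m cell size in meters.
#' @param origin numeric length-2 lower-left corner `(x, y)` in meters.
#' @return object of class `"ascii_grid"`.
#' @export
ascii_grid <- function(values, resolution_m, origin = c(0, 0)) {
  if (!is.matrix(values)) .stopf("`values` must be a matrix")
  if (anyNA(values) || any(!is.finite(values))) {
    .stopf("raster values must be finite and non-missing")
  }
  resolution_m <- .check_nonneg(resolution_m, "resolution_m")
  structure(list(values = values, resolution_m = resolution_m,
                 origin = as.numeric(origin)),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("<ascii_grid> %d x %d cells at %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$resolution_m,
              x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' Read/write ESRI ASCII grid files
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south.
#'
#' @param grid an [ascii_grid()].
#' @param path file path.
#' @return `read_ascii_grid` returns an [ascii_grid()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  v <- grid$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1L]),
    sprintf("yllcorner %.10g", grid$origin[2L]),
    sprintf("cellsize %.10g", grid$resolution_m),
    "NODATA_value -9999"
  )
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L, paste,
                collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- lapply(hdr, `[`, 2L)
  names(vals) <- vapply(hdr, `[`, "", 1L)
  ncols <- as.integer(vals$ncols)
  nrows <- as.integer(vals$nrows)
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != ncols * nrows) .stopf("raster body size mismatch")
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]
  ascii_grid(m, resolution_m = as.numeric(vals$cellsize),
             origin = c(as.numeric(vals$xllcorner), as.numeric(vals$yllcorner)))
}

#' Extract the square buffer around a site
#'
#' Selects the whole cells whose centers fall within the closed square
#' `[x - h, x + h] x [y - h, y + h]` around the site, the cell-center
#' inclusion rule used for all landscape metrics.
#'
#' @param grid an [ascii_grid()].
#' @param site numeric length-2 site coordinates `(x, y)` in the raster's
#'   frame (meters).
#' @param half_width_m buffer half-width in meters (default 500, i.e. a
#'   square extending 500 m from the site in all directions).
#' @return object of class `"buffer_grid"`: the sub-matrix of values plus
#'   `resolution_m` and the site.
#' @export
extract_square_buffer <- function(grid, site, half_width_m = 500) {
  stopifnot(inherits(grid, "ascii_grid"))
  half_width_m <- .check_nonneg(half_width_m, "half_width_m")
  v <- grid$values
  res <- grid$resolution_m
  xc <- grid$origin[1L] + (seq_len(ncol(v)) - 0.5) * res
  yc <- grid$origin[2L] + (seq_len(nrow(v)) - 0.5) * res
  xmax <- grid$origin[1L] + ncol(v) * res
  ymax <- grid$origin[2L] + nrow(v) * res
  lo_x <- site[1L] - half_width_m; hi_x <- site[1L] + half_width_m
  lo_y <- site[2L] - half_width_m; hi_y <- site[2L] + half_width_m
  missing <- character()
  if (lo_x < grid$origin[1L]) missing <- c(missing, sprintf("west of x=%g", grid$origin[1L]))
  if (hi_x > xmax) missing <- c(missing, sprintf("east of x=%g", xmax))
  if (lo_y < grid$origin[2L]) missing <- c(missing, sprintf("south of y=%g", grid$origin[2L]))
  if (hi_y > ymax) missing <- c(missing, sprintf("north of y=%g", ymax))
  if (length(missing)) {
    .stopf("raster does not cover the buffer: missing extent %s",
           paste(missing, collapse = ", "))
  }
  jx <- which(xc >= lo_x & xc <= hi_x)
  iy <- which(yc >= lo_y & yc <= hi_y)
  if (!length(jx) || !length(iy)) .stopf("buffer contains no cell centers")
  structure(list(values = v[iy, jx, drop = FALSE], resolution_m = res,
                 site = as.numeric(site)),
            class = "buffer_grid")
}

.buffer_values <- function(buffer) {
  if (inherits(buffer, "buffer_grid")) buffer$values
  else if (inherits(buffer, "ascii_grid")) buffer$values
  else if (is.matrix(buffer)) buffer
  else .stopf("expected a buffer_grid, ascii_grid, or matrix")
}

.buffer_res <- function(buffer, resolution_m = NULL) {
  if (!is.null(resolution_m)) return(resolution_m)
  if (is.list(buffer) && !is.null(buffer$resolution_m)) buffer$resolution_m
  else .stopf("`resolution_m` required for bare matrices")
}

#' Shannon diversity of land-cover classes (SHDI)
#'
#' Compositional heterogeneity: `-sum(p_i * ln(p_i))` over the class
#' proportions `p_i` by cell count; absent classes contribute nothing.
#' Zero iff a single class is present; at most `ln(number of classes)`.
#'
#' @param buffer a `"buffer_grid"` (or matrix) of categorical class labels.
#' @return SHDI (dimensionless, >= 0).
#' @export
shannon_diversity <- function(buffer) {
  v <- .buffer_values(buffer)
  p <- tabulate(match(v, unique(as.vector(v))))
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Delineate land-cover patches
#'
#' Labels connected components of equal-class cells under 8- (default) or
#' 4-neighbor adjacency, with deterministic labels assigned in raster-scan
#' (column-major) order.
#'
#' @param buffer categorical `"buffer_grid"` or matrix.
#' @param connectivity 8 (queen) or 4 (rook).
#' @param resolution_m cell size in meters (taken from the buffer when
#'   available).
#' @return object of class `"patch_set"`: `labels` (matrix of patch ids),
#'   `class` (per-patch class), `n_cells` (per-patch cell count),
#'   `resolution_m`.
#' @export
delineate_patches <- function(buffer, connectivity = 8, resolution_m = NULL) {
  v <- .buffer_values(buffer)
  res <- .buffer_res(buffer, resolution_m)
  if (!connectivity %in% c(4, 8)) .stopf("`connectivity` must be 4 or 8")
  nr <- nrow(v); nc <- ncol(v)
  if (connectivity == 8) {
    di <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dj <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L)
    dj <- c(0L, 0L, -1L, 1L)
  }
  labels <- matrix(0L, nr, nc)
  patch_class <- integer(0)
  patch_cells <- integer(0)
  next_label <- 0L
  queue <- integer(nr * nc)
  for (start in seq_len(nr * nc)) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    cls <- v[start]
    labels[start] <- next_label
    queue[1L] <- start
    head <- 1L; tail <- 1L
    count <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      ci <- ((cur - 1L) %% nr) + 1L
      cj <- ((cur - 1L) %/% nr) + 1L
      for (nb in seq_along(di)) {
        ni <- ci + di[nb]; nj <- cj + dj[nb]
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        pos <- (nj - 1L) * nr + ni
        if (labels[pos] == 0L && v[pos] == cls) {
          labels[pos] <- next_label
          tail <- tail + 1L
          queue[tail] <- pos
          count <- count + 1L
        }
      }
    }
    patch_class <- c(patch_class, cls)
    patch_cells <- c(patch_cells, count)
  }
  structure(list(labels = labels, class = patch_class, n_cells = patch_cells,
                 resolution_m = res, connectivity = connectivity),
            class = "patch_set")
}

#' Per-patch perimeter and area
#'
#' Area is `cell count x resolution^2`. Perimeter counts every cell side
#' adjacent to a different patch (hence a different class) or to the buffer
#' boundary, times the resolution -- patches truncated by the buffer are
#' treated as closed at its edge.
#'
#' @param patches a `"patch_set"` from [delineate_patches()].
#' @return data frame: `patch`, `class`, `area_m2`, `perimeter_m`,
#'   `par` (perimeter/area, 1/m).
#' @export
patch_perimeter_area <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  lab <- patches$labels
  res <- patches$resolution_m
  nr <- nrow(lab); nc <- ncol(lab)
  np <- length(patches$class)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lab
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  sides <- integer(np)
  for (shift in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nbr <- pad[2:(nr + 1L) + shift[1L], 2:(nc + 1L) + shift[2L], drop = FALSE]
    diff <- core != nbr
    sides <- sides + tabulate(core[diff], nbins = np)
  }
  area <- patches$n_cells * res^2
  perim <- sides * res
  data.frame(patch = seq_len(np), class = patches$class,
             area_m2 = area, perimeter_m = perim, par = perim / area)
}

#' Mean perimeter-area ratio of land-cover patches (PAR)
#'
#' Configurational heterogeneity: the arithmetic mean over all patches of
#' perimeter/area, in 1/m.
#'
#' @inheritParams delineate_patches
#' @return PAR in 1/m.
#' @export
mean_perimeter_area_ratio <- function(buffer, connectivity = 8,
                                      resolution_m = NULL) {
  patches <- delineate_patches(buffer, connectivity, resolution_m)
  mean(patch_perimeter_area(patches)$par)
}

#' Average roughness of elevation (ARE)
#'
#' Topographic heterogeneity as the surface average roughness Sa: the mean
#' absolute deviation of cell elevations from the buffer-mean elevation, in
#' meters. Optionally removes a best-fit plane first.
#'
#' @param buffer continuous (elevation) `"buffer_grid"` or matrix, meters.
#' @param detrend if `TRUE`, deviations are taken from the least-squares
#'   plane over the buffer instead of the mean.
#' @return ARE in meters.
#' @export
average_roughness <- function(buffer, detrend = FALSE) {
  z <- .buffer_values(buffer)
  if (detrend) {
    ij <- expand.grid(i = seq_len(nrow(z)), j = seq_len(ncol(z)))
    fit <- stats::lm.fit(cbind(1, ij$i, ij$j), as.vector(z))
    return(mean(abs(fit$residuals)))
  }
  mean(abs(z - mean(z)))
}

#' All three heterogeneity metrics for one site
#'
#' Convenience wrapper: extracts the 500-m square buffer from the land-cover
#' and elevation rasters and computes SHDI, PAR, and ARE.
#'
#' @param land_cover,elevation [ascii_grid()] rasters in a common frame.
#' @param site numeric length-2 site coordinates (meters).
#' @param half_width_m buffer half-width, meters.
#' @param connectivity patch adjacency rule for PAR.
#' @return one-row data frame: `shdi`, `par`, `are`.
#' @export
landscape_metrics <- function(land_cover, elevation, site = c(0, 0),
                              half_width_m = 500, connectivity = 8) {
  lc_buf <- extract_square_buffer(land_cover, site, half_width_m)
  el_buf <- extract_square_buffer(elevation, site, half_width_m)
  data.frame(
    shdi = shannon_diversity(lc_buf),
    par = mean_perimeter_area_ratio(lc_buf, connectivity),
    are = average_roughness(el_buf)
  )
}
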