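# Residence-based (RB) and mobility-based (MB) environmental-factor
# exposures over a family of circular/ring buffers, plus facility and
# street-block population densities.

#' Buffer specification and the standard ring family
#'
#' A buffer is the annulus `inner_m <= d < outer_m` around a center
#' (`inner_m = 0` gives the innermost circular buffer). The standard family
#' is ten contiguous rings from 50 m to 500 m at 50 m intervals:
#' (0,50), (50,100), ..., (450,500). Together they partition the 500 m disc,
#' so cell-center membership with the half-open radial interval assigns each
#' raster cell to exactly one ring.
#'
#' @param inner_m,outer_m ring radii in meters, `0 <= inner_m < outer_m`.
#' @return `buffer_spec`: a named list; `ring_family`: a data.frame with
#'   columns `inner_m`, `outer_m` (10 rows).
#' @export
buffer_spec <- function(inner_m, outer_m) {
  if (!(inner_m >= 0 && inner_m < outer_m))
    stopf("need 0 <= inner_m < outer_m (got %g, %g)", inner_m, outer_m)
  list(inner_m = inner_m, outer_m = outer_m)
}

#' @rdname buffer_spec
#' @export
ring_family <- function() {
  data.frame(inner_m = seq(0, 450, by = 50), outer_m = seq(50, 500, by = 50))
}

#' Land-use density in a ring buffer
#'
#' The fraction of the buffer occupied by a set of land-use classes: the
#' count of member cells whose code is in `codes` over the count of all
#' member cells. A cell is a member iff its center's distance `d` to the
#' buffer center satisfies `inner_m <= d < outer_m` (half-open, so the ring
#' family partitions the plane with no double counting; no partial-cell
#' weighting).
#'
#' @param center numeric length-2 `(x, y)` in meters.
#' @param spec a [buffer_spec()].
#' @param raster a [landuse_raster()].
#' @param codes integer class-code set defining the land-use type.
#' @return density in `[0, 1]`.
#' @export
landuse_density <- function(center, spec, raster, codes) {
  d <- ring_density_profile(center, data.frame(inner_m = spec$inner_m,
                                               outer_m = spec$outer_m),
                            raster, list(role = codes))
  if (d$n_cells[1] == 0L)
    stopf("ring (%g, %g) around (%g, %g) contains no cell centers",
          spec$inner_m, spec$outer_m, center[1], center[2])
  d$role[1]
}

# Densities of several roles over a whole ring family at one center, in one
# pass over the local raster window. Returns a data.frame with inner_m,
# outer_m, n_cells, and one column per role (NA where a ring has no cells).
ring_density_profile <- function(center, family, raster, roles) {
  cell <- raster$cell_size_m
  rmax <- max(family$outer_m)
  nr <- nrow(raster$codes); ncx <- ncol(raster$codes)
  c0 <- floor((center[1] - raster$origin[1]) / cell) + 1
  r0 <- floor((center[2] - raster$origin[2]) / cell) + 1
  rad_c <- ceiling(rmax / cell) + 1
  rows <- max(1, r0 - rad_c):min(nr, r0 + rad_c)
  cols <- max(1, c0 - rad_c):min(ncx, c0 + rad_c)
  if (!length(rows) || !length(cols) || min(rows) > max(rows))
    stopf("buffer does not intersect the raster extent")
  xs <- raster$origin[1] + (cols - 0.5) * cell
  ys <- raster$origin[2] + (rows - 0.5) * cell
  d <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, "+"))
  codes_w <- raster$codes[rows, cols, drop = FALSE]
  # half-open [inner, outer): breaks at every boundary; ring index by interval
  bounds <- sort(unique(c(family$inner_m, family$outer_m)))
  iv <- findInterval(d, bounds, left.open = FALSE, rightmost.closed = FALSE)
  ring_of <- match(paste(family$inner_m, family$outer_m),
                   paste(bounds[-length(bounds)], bounds[-1]))
  nb <- length(bounds) - 1L
  sel <- iv >= 1L & iv <= nb
  n_by_iv <- tabulate(iv[sel], nb)
  out <- data.frame(inner_m = family$inner_m, outer_m = family$outer_m,
                    n_cells = n_by_iv[ring_of])
  for (role in names(roles)) {
    m <- codes_w %in% roles[[role]] & sel
    cnt <- tabulate(iv[m], nb)
    out[[role]] <- ifelse(out$n_cells > 0, cnt[ring_of] / pmax(out$n_cells, 1L), NA_real_)
  }
  out
}

#' Residence-based (RB) exposures over a ring family
#'
#' Evaluates the land-use density of each role in each ring buffer around
#' the home location: the static measurement of residential context.
#'
#' @param home numeric `(x, y)` home location in meters.
#' @param family ring family data.frame (see [ring_family()]).
#' @param raster a [landuse_raster()].
#' @param roles named list of class-code sets (e.g.
#'   `config$class_roles[c("transport", "green", "open_space")]`).
#' @return long data.frame `method`, `inner_m`, `outer_m`, `factor`, `value`.
#' @export
rb_exposures <- function(home, family, raster, roles) {
  prof <- ring_density_profile(home, family, raster, roles)
  if (any(prof$n_cells == 0L))
    stopf("a ring around (%g, %g) contains no cell centers", home[1], home[2])
  long_exposures(prof, "RB", names(roles))
}

#' Mobility-based (MB) exposures over a ring family
#'
#' For each ring and role, the arithmetic mean over minute-level locations
#' of the land-use density of a buffer centered at that location: the
#' activity-space measurement that replaces the single home anchor with the
#' places a person actually visited. Per-point buffers averaged (rather than
#' a dissolved buffer union) is the default reading of GPS-point buffers;
#' see `details`.
#'
#' @details With `snap = TRUE` (default) minute locations are snapped to the
#' center of their 10 m raster cell and densities are computed once per
#' distinct cell, then averaged with multiplicity weights. The snap distance
#' (at most half a cell diagonal, ~7 m) is far below the smallest 50 m
#' buffer radius and makes the computation linear in *distinct* visited
#' cells instead of minutes, which matters for overnight periods spent at
#' one anchor. `snap = FALSE` evaluates every location exactly.
#'
#' @param minute_locations data.frame or matrix with `x`, `y` columns (one
#'   row per minute), NA rows dropped.
#' @param family,raster,roles as in [rb_exposures()].
#' @param snap snap minute locations to cell centers (default `TRUE`).
#' @return long data.frame `method`, `inner_m`, `outer_m`, `factor`, `value`.
#' @export
mb_exposures <- function(minute_locations, family, raster, roles, snap = TRUE) {
  ml <- as.data.frame(minute_locations)
  ml <- ml[is.finite(ml$x) & is.finite(ml$y), , drop = FALSE]
  if (!nrow(ml)) stopf("no usable minute locations")
  if (snap) {
    cells <- point_cell(raster, ml$x, ml$y)
    key <- (cells$row - 1L) * ncol(raster$codes) + cells$col
    tab <- table(key)
    ukey <- as.integer(names(tab))
    wts <- as.numeric(tab)
    urow <- (ukey - 1L) %/% ncol(raster$codes) + 1L
    ucol <- (ukey - 1L) %% ncol(raster$codes) + 1L
    ctr <- cell_center(raster, urow, ucol)
    pts <- cbind(ctr$x, ctr$y)
  } else {
    pts <- cbind(ml$x, ml$y)
    wts <- rep(1, nrow(pts))
  }
  acc <- NULL; wacc <- NULL
  for (i in seq_len(nrow(pts))) {
    prof <- ring_density_profile(pts[i, ], family, raster, roles)
    vals <- as.matrix(prof[, names(roles), drop = FALSE])
    ok <- !is.na(vals)
    vals[!ok] <- 0
    if (is.null(acc)) {
      acc <- vals * wts[i]; wacc <- ok * wts[i]
    } else {
      acc <- acc + vals * wts[i]; wacc <- wacc + ok * wts[i]
    }
  }
  if (any(wacc == 0))
    stopf("all minute locations yield undefined density for some ring")
  prof <- as.data.frame(acc / wacc)
  prof$inner_m <- family$inner_m; prof$outer_m <- family$outer_m
  long_exposures(prof, "MB", names(roles))
}

long_exposures <- function(prof, method, role_names) {
  do.call(rbind, lapply(role_names, function(role) {
    data.frame(method = method, inner_m = prof$inner_m, outer_m = prof$outer_m,
               factor = role, value = prof[[role]])
  }))
}

#' Facility index on a coarse grid and 1-km facility density
#'
#' Facilities (points) are indexed on a square grid of 1415 m cells — wide
#' enough that every facility within 1 km of any query point lies inside the
#' 3x3 neighborhood of the point's cell, so the neighborhood scan is exactly
#' equivalent to a full scan. Density is the count of facilities within
#' `radius_m`, divided by the disc area (facilities per m2).
#'
#' @param facilities data.frame with `x`, `y` columns.
#' @param cell_m grid cell edge (default 1415 m).
#' @return `facility_grid` object.
#' @export
facility_grid <- function(facilities, cell_m = 1415) {
  stopifnot(all(c("x", "y") %in% names(facilities)))
  gx <- floor(facilities$x / cell_m); gy <- floor(facilities$y / cell_m)
  structure(list(facilities = facilities, cell_m = cell_m,
                 key = paste(gx, gy)), class = "facility_grid")
}

#' @rdname facility_grid
#' @param center numeric `(x, y)` query point.
#' @param grid a `facility_grid`.
#' @param radius_m search radius (default 1000 m; must not exceed `cell_m`).
#' @export
facility_density <- function(center, grid, radius_m = 1000) {
  stopifnot(inherits(grid, "facility_grid"))
  if (radius_m > grid$cell_m)
    stopf("radius_m (%g) must not exceed the grid cell size (%g)", radius_m, grid$cell_m)
  gx <- floor(center[1] / grid$cell_m); gy <- floor(center[2] / grid$cell_m)
  nb <- as.vector(outer((gx - 1):(gx + 1), (gy - 1):(gy + 1), paste))
  cand <- grid$key %in% nb
  if (!any(cand)) return(0)
  f <- grid$facilities[cand, , drop = FALSE]
  cnt <- sum((f$x - center[1])^2 + (f$y - center[2])^2 <= radius_m^2)
  cnt / (pi * radius_m^2)
}

#' Generate synthetic facility points
#'
#' Uniform points over the extent plus extra intensity near transport cells
#' (facilities cluster along corridors in real cities).
#'
#' @param raster the world's [landuse_raster()].
#' @param config a [world_config()].
#' @param n_uniform,n_transport counts of background and corridor-attracted
#'   facilities.
#' @return data.frame `facility_id`, `x`, `y`.
#' @export
generate_facilities <- function(raster, config, n_uniform = 150, n_transport = 100) {
  ext <- raster_extent(raster)
  with_seed(sub_seed(config$seed, 303L), {
    xs <- stats::runif(n_uniform, ext["xmin"], ext["xmax"])
    ys <- stats::runif(n_uniform, ext["ymin"], ext["ymax"])
    if (n_transport > 0) {
      pts <- t(vapply(seq_len(n_transport), function(i)
        sample_role_point(raster, config$class_roles$transport), c(0, 0)))
      jit <- matrix(stats::rnorm(2 * n_transport, 0, 30), ncol = 2)
      xs <- c(xs, pmin(pmax(pts[, 1] + jit[, 1], ext["xmin"]), ext["xmax"] - 1e-6))
      ys <- c(ys, pmin(pmax(pts[, 2] + jit[, 2], ext["ymin"]), ext["ymax"] - 1e-6))
    }
    data.frame(facility_id = seq_along(xs), x = unname(xs), y = unname(ys))
  })
}

#' Street-block map and population density
#'
#' The synthetic street blocks are a rectangular partition of the extent
#' (axis-aligned blocks of `block_m` meters), each carrying a population
#' drawn from a log-normal density distribution clamped to a realistic
#' urban range (6e3 to 3.5e5 persons per km2). Blocks tile the extent with
#' no gaps or overlaps.
#'
#' @param config a [world_config()].
#' @param block_m block edge length in meters (default 250).
#' @return data.frame `block_id`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `population`, `area_km2`, with class `street_blocks`.
#' @export
generate_street_blocks <- function(config, block_m = 250) {
  W <- config$extent_m[1]; H <- config$extent_m[2]
  nx <- ceiling(W / block_m); ny <- ceiling(H / block_m)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  xmin <- (g$ix - 1) * block_m; xmax <- pmin(g$ix * block_m, W)
  ymin <- (g$iy - 1) * block_m; ymax <- pmin(g$iy * block_m, H)
  area_km2 <- (xmax - xmin) * (ymax - ymin) / 1e6
  with_seed(sub_seed(config$seed, 404L), {
    dens <- pmin(3.5e5, pmax(6e3, stats::rlnorm(nrow(g), log(9e4), 0.8)))
    out <- data.frame(block_id = seq_len(nrow(g)), xmin = xmin, xmax = xmax,
                      ymin = ymin, ymax = ymax,
                      population = round(dens * area_km2), area_km2 = area_km2)
    class(out) <- c("street_blocks", "data.frame")
    out
  })
}

#' Population density of the home street block
#'
#' Population over area (persons per km2) of the block containing the home
#' location. This is a residence-based quantity only: minute-level mobility
#' cannot be matched to a meaningful real-time population, so no MB variant
#' exists. A point on a shared block boundary is deterministically assigned
#' to the block with the lower id.
#'
#' @param home numeric `(x, y)`.
#' @param blocks a `street_blocks` data.frame.
#' @return persons per km2.
#' @export
population_density <- function(home, blocks) {
  inside <- home[1] >= blocks$xmin & home[1] <= blocks$xmax &
    home[2] >= blocks$ymin & home[2] <= blocks$ymax
  if (!any(inside)) stopf("home (%g, %g) lies outside all street blocks", home[1], home[2])
  b <- blocks[inside, , drop = FALSE]
  b <- b[which.min(b$block_id), ]   # boundary tie-break: lower id
  b$population / b$area_km2
}
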