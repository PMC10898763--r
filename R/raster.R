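#' Categorical land-use raster
#'
#' A light container for a single-band categorical raster on a regular grid
#' in projected meters. `codes` is an integer matrix with `codes[r, c]` the
#' class of the cell whose x-range is `[x0 + (c-1)*cell, x0 + c*cell)` and
#' y-range `[y0 + (r-1)*cell, y0 + r*cell)`; cell centers sit at the
#' half-cell offsets.
#'
#' @param codes integer matrix of class codes (rows index y, columns x).
#' @param origin numeric length-2 `(x0, y0)`, lower-left corner in meters.
#' @param cell_size_m cell edge length in meters.
#' @return an object of class `landuse_raster`.
#' @export
landuse_raster <- function(codes, origin = c(0, 0), cell_size_m = 10) {
  if (!is.matrix(codes)) stopf("codes must be a matrix")
  storage.mode(codes) <- "integer"
  if (anyNA(codes)) stopf("codes must not contain NA")
  structure(list(codes = codes, origin = as.numeric(origin),
                 cell_size_m = as.numeric(cell_size_m)),
            class = "landuse_raster")
}

#' @export
print.landuse_raster <- function(x, ...) {
  cat(sprintf("<landuse_raster> %d x %d cells at %g m (extent %g x %g m), %d distinct codes\n",
              nrow(x$codes), ncol(x$codes), x$cell_size_m,
              ncol(x$codes) * x$cell_size_m, nrow(x$codes) * x$cell_size_m,
              length(unique(as.vector(x$codes)))))
  invisible(x)
}

raster_extent <- function(raster) {
  c(xmin = raster$origin[1], ymin = raster$origin[2],
    xmax = raster$origin[1] + ncol(raster$codes) * raster$cell_size_m,
    ymax = raster$origin[2] + nrow(raster$codes) * raster$cell_size_m)
}

# column/row of the cell containing point(s); half-open cells [lo, hi)
point_cell <- function(raster, x, y) {
  cc <- floor((x - raster$origin[1]) / raster$cell_size_m) + 1L
  rr <- floor((y - raster$origin[2]) / raster$cell_size_m) + 1L
  list(row = pmin(pmax(as.integer(rr), 1L), nrow(raster$codes)),
       col = pmin(pmax(as.integer(cc), 1L), ncol(raster$codes)))
}

cell_center <- function(raster, row, col) {
  list(x = raster$origin[1] + (col - 0.5) * raster$cell_size_m,
       y = raster$origin[2] + (row - 0.5) * raster$cell_size_m)
}

# stamp a filled disc of cells (by cell-center distance) with a code
stamp_disc <- function(codes, cell, origin, cx, cy, radius_m, code) {
  nr <- nrow(codes); nc <- ncol(codes)
  c0 <- floor((cx - origin[1]) / cell) + 1; r0 <- floor((cy - origin[2]) / cell) + 1
  rad_c <- ceiling(radius_m / cell) + 1
  rows <- max(1, r0 - rad_c):min(nr, r0 + rad_c)
  cols <- max(1, c0 - rad_c):min(nc, c0 + rad_c)
  if (!length(rows) || !length(cols)) return(codes)
  xs <- origin[1] + (cols - 0.5) * cell
  ys <- origin[2] + (rows - 0.5) * cell
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sel <- d2 <= radius_m^2
  block <- codes[rows, cols, drop = FALSE]
  block[sel] <- code
  codes[rows, cols] <- block
  codes
}

#' Generate a synthetic land-use raster
#'
#' Builds the categorical raster of the synthetic city: a coarse-block urban
#' background drawn from the non-role ("other") classes, axis-aligned
#' transportation corridors, and contiguous green and open-space patches
#' placed by a seeded blob process (random centers and radii, stamped in
#' order so later patches overwrite earlier ones). Deterministic for a fixed
#' `config$seed`.
#'
#' With `n_green_patches = 0`, `n_open_patches = 0`, `n_corridors = 0` and a
#' single background code the result is a uniform single-class raster.
#'
#' @param config a [world_config()].
#' @return a [landuse_raster()].
#' @examples
#' r <- generate_landuse_raster(world_config(extent_m = c(500, 500), seed = 3))
#' table(r$codes)[1:3]
#' @export
generate_landuse_raster <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cell <- config$cell_size_m
  nc <- as.integer(round(config$extent_m[1] / cell))
  nr <- as.integer(round(config$extent_m[2] / cell))
  bg <- other_codes(config)
  if (!length(bg)) stopf("at least one non-role class code is required for background")
  with_seed(sub_seed(config$seed, 101L), {
    # coarse 10x10-cell blocks of background classes
    block <- 10L
    nbr <- ceiling(nr / block); nbc <- ceiling(nc / block)
    blocks <- matrix(sample(bg, nbr * nbc, replace = TRUE), nbr, nbc)
    codes <- blocks[(seq_len(nr) - 1L) %/% block + 1L,
                    (seq_len(nc) - 1L) %/% block + 1L, drop = FALSE]
    # transportation corridors: alternating horizontal/vertical bands, 2 cells
    # (20 m) wide, random positions, codes cycling through the transport set
    tcodes <- config$class_roles$transport
    n_cor <- config$n_corridors
    if (n_cor >= 1) {
      for (i in seq_len(n_cor)) {
        code <- tcodes[(i - 1L) %% length(tcodes) + 1L]
        if (i %% 2 == 1) {
          r0 <- sample(seq_len(max(1, nr - 2)), 1)
          codes[r0:min(nr, r0 + 1L), ] <- code
        } else {
          c0 <- sample(seq_len(max(1, nc - 2)), 1)
          codes[, c0:min(nc, c0 + 1L)] <- code
        }
      }
    }
    # green patches (three green classes), then open-space patches
    gcodes <- config$class_roles$green
    if (config$n_green_patches >= 1) {
      for (i in seq_len(config$n_green_patches)) {
        cx <- runif(1, 0, config$extent_m[1]); cy <- runif(1, 0, config$extent_m[2])
        rad <- runif(1, 8, 25) * cell
        codes <- stamp_disc(codes, cell, config$extent_m * 0, cx, cy, rad,
                            sample(gcodes, 1))
      }
    }
    ocode <- config$class_roles$open_space[1]
    if (config$n_open_patches >= 1) {
      for (i in seq_len(config$n_open_patches)) {
        cx <- runif(1, 0, config$extent_m[1]); cy <- runif(1, 0, config$extent_m[2])
        rad <- runif(1, 5, 12) * cell
        codes <- stamp_disc(codes, cell, config$extent_m * 0, cx, cy, rad, ocode)
      }
    }
    landuse_raster(codes, origin = c(0, 0), cell_size_m = cell)
  })
}

#' Write / read a land-use raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange: a 6-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' rows of integer codes from the top row (largest y) down.
#'
#' @param raster a [landuse_raster()].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [landuse_raster()].
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "landuse_raster"))
  hdr <- c(sprintf("ncols %d", ncol(raster$codes)),
           sprintf("nrows %d", nrow(raster$codes)),
           sprintf("xllcorner %.6f", raster$origin[1]),
           sprintf("yllcorner %.6f", raster$origin[2]),
           sprintf("cellsize %.6f", raster$cell_size_m),
           "NODATA_value -9999")
  rows <- apply(raster$codes[rev(seq_len(nrow(raster$codes))), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                        tolower(vapply(hdr, `[`, "", 1)))
  ncols <- as.integer(kv[["ncols"]]); nrows <- as.integer(kv[["nrows"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = " "), quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = nrows, ncol = ncols, byrow = TRUE)
  landuse_raster(m[rev(seq_len(nrows)), , drop = FALSE],
                 origin = c(kv[["xllcorner"]], kv[["yllcorner"]]),
                 cell_size_m = kv[["cellsize"]])
}

# Disc-kernel smoothed role indicator: fraction of cells within radius_m
# (cell-center distance) carrying a code in `codes`. Used by the synthetic
# pollution field; an all-role neighbourhood gives exactly 1.
role_proximity_field <- function(raster, codes, radius_m = 50) {
  ind <- matrix(0, nrow(raster$codes), ncol(raster$codes))
  ind[raster$codes %in% codes] <- 1
  cell <- raster$cell_size_m
  rad_c <- floor(radius_m / cell)
  offs <- expand.grid(dr = -rad_c:rad_c, dc = -rad_c:rad_c)
  offs <- offs[(offs$dr^2 + offs$dc^2) * cell^2 <= radius_m^2, , drop = FALSE]
  nr <- nrow(ind); ncx <- ncol(ind)
  acc <- matrix(0, nr, ncx); cnt <- matrix(0, nr, ncx)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(ncx, ncx + dc)
    rs0 <- rs - dr; cs0 <- cs - dc
    acc[rs0, cs0] <- acc[rs0, cs0] + ind[rs, cs]
    cnt[rs0, cs0] <- cnt[rs0, cs0] + 1
  }
  acc / cnt
}
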