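#' World configuration for the synthetic study area
#'
#' Defines the synthetic city: a rectangular extent in projected meters, a
#' categorical land-use raster resolution, the mapping from land-use roles to
#' class codes, and cohort size. The coordinate system is a local projected
#' plane in meters with the origin at the lower-left extent corner; buffers
#' are metric so no geodesy is involved at city scale.
#'
#' Land-use classes follow the convention of a 27-class cadastre in which
#' green space is represented by three classes (grassland, shrubland,
#' woodland), open space by a single recreation class, and transportation
#' land use by four classes (roads and transport facilities, railways,
#' airport, port facilities). The remaining classes play no role in the
#' exposure metrics and act as urban background.
#'
#' @param extent_m numeric length-2, width and height of the extent in meters;
#'   must be positive multiples of `cell_size_m`.
#' @param cell_size_m raster resolution in meters (default 10).
#' @param n_classes number of land-use classes (default 27).
#' @param class_roles named list with elements `green`, `open_space`,
#'   `transport`: disjoint integer code sets within `1:n_classes`.
#' @param n_participants cohort size (default 210, split over two communities).
#' @param n_days survey days (default 2: one weekday, one weekend day).
#' @param seed master integer seed; every generator derives its own sub-seed
#'   from it.
#' @param n_green_patches,n_open_patches number of contiguous patches of green
#'   and open-space classes placed by the blob process (set to 0 for a
#'   degenerate single-class world).
#' @param n_corridors number of transportation corridors (axis-aligned bands).
#' @param jitter_sd GPS positional jitter standard deviation in meters. The
#'   positional error model of consumer GPS is not standardised; this is a
#'   configuration knob, not a claim.
#' @param walk_speed_ms walking speed between activity anchors, m/s.
#' @return an object of class `world_config`.
#' @examples
#' cfg <- world_config(extent_m = c(1000, 1000), n_participants = 10, seed = 1)
#' cfg$class_roles$green
#' @export
world_config <- function(extent_m = c(3000, 3000),
                         cell_size_m = 10,
                         n_classes = 27,
                         class_roles = list(green = c(21L, 22L, 23L),
                                            open_space = 24L,
                                            transport = 1:4),
                         n_participants = 210,
                         n_days = 2,
                         seed = 1L,
                         n_green_patches = 8,
                         n_open_patches = 6,
                         n_corridors = 4,
                         jitter_sd = 3,
                         walk_speed_ms = 1.4) {
  if (length(extent_m) != 2 || any(!is.finite(extent_m)) || any(extent_m <= 0))
    stopf("extent_m must be two positive numbers")
  if (!is.numeric(cell_size_m) || cell_size_m <= 0)
    stopf("cell_size_m must be > 0")
  if (any(abs(extent_m / cell_size_m - round(extent_m / cell_size_m)) > 1e-9))
    stopf("extent dimensions must be positive multiples of cell_size_m")
  if (!is_count(n_classes)) stopf("n_classes must be a positive integer")
  roles <- lapply(class_roles, function(v) as.integer(v))
  need <- c("green", "open_space", "transport")
  if (!all(need %in% names(roles)))
    stopf("class_roles must contain roles: %s", paste(need, collapse = ", "))
  all_codes <- unlist(roles, use.names = FALSE)
  if (any(all_codes < 1L | all_codes > n_classes))
    stopf("all role codes must lie in [1, n_classes]")
  if (anyDuplicated(all_codes))
    stopf("role code sets must be pairwise disjoint")
  if (!is_count(n_participants)) stopf("n_participants must be a positive integer")
  if (!is_count(n_days)) stopf("n_days must be a positive integer")
  structure(list(
    extent_m = as.numeric(extent_m),
    cell_size_m = as.numeric(cell_size_m),
    n_classes = as.integer(n_classes),
    class_roles = roles,
    n_participants = as.integer(n_participants),
    n_days = as.integer(n_days),
    seed = as.integer(seed),
    n_green_patches = n_green_patches,
    n_open_patches = n_open_patches,
    n_corridors = n_corridors,
    jitter_sd = jitter_sd,
    walk_speed_ms = walk_speed_ms
  ), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat(sprintf("<world_config> %g x %g m at %g m; %d classes; %d participants, %d days; seed %d\n",
              x$extent_m[1], x$extent_m[2], x$cell_size_m, x$n_classes,
              x$n_participants, x$n_days, x$seed))
  invisible(x)
}

# "other" (background) codes: all codes not claimed by a role
other_codes <- function(config) {
  setdiff(seq_len(config$n_classes), unlist(config$class_roles, use.names = FALSE))
}
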