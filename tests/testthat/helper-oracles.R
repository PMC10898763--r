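# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's optimised code paths.

# exhaustive per-cell ring density: loop over every raster cell
oracle_ring_density <- function(center, inner, outer, raster, codes) {
  cell <- raster$cell_size_m
  n_in <- 0L; n_all <- 0L
  for (r in seq_len(nrow(raster$codes))) {
    for (c in seq_len(ncol(raster$codes))) {
      cx <- raster$origin[1] + (c - 0.5) * cell
      cy <- raster$origin[2] + (r - 0.5) * cell
      d <- sqrt((cx - center[1])^2 + (cy - center[2])^2)
      if (d >= inner && d < outer) {
        n_all <- n_all + 1L
        if (raster$codes[r, c] %in% codes) n_in <- n_in + 1L
      }
    }
  }
  if (n_all == 0L) NA_real_ else n_in / n_all
}

# global minimum of the 2-cluster within-SS over ALL 2-partitions (not just
# contiguous ones): feasible for n <= 12
oracle_best_2partition <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    a <- x[sel]; b <- x[!sel]
    w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (w < best) best <- w
  }
  best
}

oracle_facility_count <- function(center, facilities, radius) {
  sum((facilities$x - center[1])^2 + (facilities$y - center[2])^2 <= radius^2)
}

# small raster with a known rectangular patch of one code on a background
toy_patch_raster <- function(n = 30, cell = 10, bg = 5L, patch = 21L,
                             rows = 10:18, cols = 12:20) {
  m <- matrix(bg, n, n)
  m[rows, cols] <- patch
  landuse_raster(m, origin = c(0, 0), cell_size_m = cell)
}

# uniform single-code raster
uniform_raster <- function(code, n = 40, cell = 10) {
  landuse_raster(matrix(as.integer(code), n, n), origin = c(0, 0),
                 cell_size_m = cell)
}

tiny_world <- function(seed = 1, n = 6, extent = 1000, ...) {
  world_config(extent_m = c(extent, extent), n_participants = n, seed = seed, ...)
}

# single-community quota table over one stratum column
simple_quota <- function(props, column = "female") {
  q <- data.frame(community = "A", proportion = as.numeric(props))
  q[[column]] <- names(props)
  q
}
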