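# Ring-buffer land-use densities, RB/MB exposures, facility and population
# densities, checked against brute-force oracles.

test_that("ring family is the ten contiguous 50 m rings to 500 m", {
  fam <- ring_family()
  expect_equal(nrow(fam), 10)
  expect_equal(fam$inner_m, seq(0, 450, 50))
  expect_equal(fam$outer_m, seq(50, 500, 50))
  expect_equal(fam$inner_m[-1], fam$outer_m[-10])  # contiguous
  expect_error(buffer_spec(100, 100))
  expect_error(buffer_spec(-1, 50))
})

test_that("uniform and disjoint-code rasters give densities 1 and 0", {
  r <- uniform_raster(21L)
  spec <- buffer_spec(0, 50)
  expect_equal(landuse_density(c(200, 200), spec, r, 21L), 1.0)
  expect_equal(landuse_density(c(200, 200), spec, r, c(1L, 2L)), 0.0)
  expect_equal(landuse_density(c(200, 200), buffer_spec(100, 150), r, 21L), 1.0)
})

test_that("ring densities match exhaustive per-cell enumeration on a toy patch", {
  r <- toy_patch_raster()
  set.seed(31)
  for (k in 1:25) {
    center <- runif(2, 30, 270)
    fam <- ring_family()[sample(10, 1), ]
    got <- tryCatch(landuse_density(center, buffer_spec(fam$inner_m, fam$outer_m),
                                    r, 21L), error = function(e) NA_real_)
    want <- oracle_ring_density(center, fam$inner_m, fam$outer_m, r, 21L)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("densities over a full class partition sum to 1 for every ring", {
  cfg <- tiny_world(seed = 77, extent = 1200)
  r <- generate_landuse_raster(cfg)
  roles <- split(1:27, paste0("c", 1:27))
  prof <- mobexpo:::ring_density_profile(c(600, 600), ring_family(), r, roles)
  sums <- rowSums(prof[, names(roles)])
  expect_equal(sums, rep(1, 10), tolerance = 1e-12)
})

test_that("RB exposures produce one record per ring x role and match the oracle", {
  r <- toy_patch_raster()
  fam <- ring_family()[1:3, ]  # keep rings inside the 300 m toy extent
  roles <- list(green = 21L, other = 5L)
  home <- c(150, 140)
  rb <- rb_exposures(home, fam, r, roles)
  expect_equal(nrow(rb), 3 * 2)
  for (i in seq_len(nrow(rb))) {
    want <- oracle_ring_density(home, rb$inner_m[i], rb$outer_m[i], r,
                                roles[[rb$factor[i]]])
    expect_equal(rb$value[i], want)
  }
})

test_that("MB exposure at a constant location equals the RB exposure there", {
  r <- toy_patch_raster()
  fam <- ring_family()[1:3, ]
  roles <- list(green = 21L)
  pt <- c(152, 147)
  rb <- rb_exposures(pt, fam, r, roles)
  mb <- mb_exposures(data.frame(x = rep(pt[1], 5), y = rep(pt[2], 5)),
                     fam, r, roles, snap = FALSE)
  expect_equal(mb$value, rb$value)
  # snapped variant agrees with the density at the cell center
  ctr <- c(155, 145)  # center of the cell containing pt
  rb_ctr <- rb_exposures(ctr, fam, r, roles)
  mb_snap <- mb_exposures(data.frame(x = pt[1], y = pt[2]), fam, r, roles,
                          snap = TRUE)
  expect_equal(mb_snap$value, rb_ctr$value)
})

test_that("MB exposure is the mean of per-location densities", {
  r <- toy_patch_raster()
  fam <- data.frame(inner_m = 0, outer_m = 50)
  roles <- list(green = 21L)
  p1 <- c(150, 140); p2 <- c(60, 60)
  d1 <- landuse_density(p1, buffer_spec(0, 50), r, 21L)
  d2 <- landuse_density(p2, buffer_spec(0, 50), r, 21L)
  mb <- mb_exposures(data.frame(x = c(p1[1], p2[1]), y = c(p1[2], p2[2])),
                     fam, r, roles, snap = FALSE)
  expect_equal(mb$value, (d1 + d2) / 2)
})

test_that("a commuting trajectory raises MB transport density above RB", {
  cfg <- world_config(extent_m = c(2000, 2000), n_participants = 20, seed = 21)
  cohort <- simulate_commuter_cohort(cfg)
  expect_gt(mean(cohort$mb_transport), mean(cohort$rb_transport))
})

test_that("facility density: closed form, zero case, and grid-scan oracle equivalence", {
  empty <- facility_grid(data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(facility_density(c(500, 500), empty), 0)
  one <- facility_grid(data.frame(x = 500 + 999, y = 500))
  expect_equal(facility_density(c(500, 500), one), 1 / (pi * 1e6))
  set.seed(61)
  facs <- data.frame(x = runif(200, 0, 5000), y = runif(200, 0, 5000))
  grid <- facility_grid(facs)
  for (k in 1:100) {
    center <- runif(2, 0, 5000)
    want <- oracle_facility_count(center, facs, 1000) / (pi * 1e6)
    expect_equal(facility_density(center, grid), want)
  }
  expect_error(facility_density(c(0, 0), grid, radius_m = 2000), "cell size")
})

test_that("population density divides block population by block area", {
  blocks <- data.frame(block_id = 1:2, xmin = c(0, 1000), xmax = c(1000, 2000),
                       ymin = 0, ymax = 1000,
                       population = c(6000, 0), area_km2 = 1)
  expect_equal(population_density(c(500, 500), blocks), 6000)
  expect_equal(population_density(c(1500, 500), blocks), 0)
  # shared boundary goes to the lower block id
  expect_equal(population_density(c(1000, 500), blocks), 6000)
  expect_error(population_density(c(5000, 500), blocks), "outside")
})
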