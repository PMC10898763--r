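# Synthetic-city generators: determinism, class-code ranges, quota
# realisation, trajectory schedules, and the analytic pollution field.

test_that("land-use raster uses only configured codes and is seed-deterministic", {
  cfg <- tiny_world(seed = 42)
  r1 <- generate_landuse_raster(cfg)
  expect_true(all(unique(as.vector(r1$codes)) %in% 1:27))
  r2 <- generate_landuse_raster(cfg)
  expect_identical(r1$codes, r2$codes)
  r3 <- generate_landuse_raster(tiny_world(seed = 43))
  expect_false(identical(r1$codes, r3$codes))
})

test_that("degenerate blob weights give a uniform single-class raster", {
  # with n_classes = 4 the lone background code is 1, so a patchless,
  # corridorless world is uniform
  cfg2 <- world_config(extent_m = c(300, 300), n_participants = 2, seed = 1,
                       n_classes = 4,
                       class_roles = list(green = 2L, open_space = 3L, transport = 4L),
                       n_green_patches = 0, n_open_patches = 0, n_corridors = 0)
  r <- generate_landuse_raster(cfg2)
  expect_equal(unique(as.vector(r$codes)), 1L)
})

test_that("world_config validates extent multiples and role disjointness", {
  expect_error(world_config(extent_m = c(1005, 1000)), "multiples")
  expect_error(world_config(class_roles = list(green = c(1L, 2L), open_space = 2L,
                                               transport = 3:6)), "disjoint")
  expect_error(world_config(class_roles = list(green = c(26L, 27L, 28L),
                                               open_space = 1L, transport = 2:5)),
               "1, n_classes")
})

test_that("quota realisation matches largest-remainder targets exactly", {
  cfg <- world_config(extent_m = c(1000, 1000), n_participants = 210, seed = 9)
  p <- generate_participants(cfg)
  expect_equal(nrow(p), 210)
  expect_equal(as.vector(table(p$community)), c(105, 105))
  # realized stratum counts equal rounded targets within each community
  q <- default_quotas()
  for (comm in c("A", "B")) {
    qc <- q[q$community == comm, ]
    target <- mobexpo:::largest_remainder(qc$proportion, 105)
    got <- integer(nrow(qc))
    pc <- p[p$community == comm, ]
    key_p <- paste(pc$female, pc$age_band, pc$income4, pc$employment)
    key_q <- paste(qc$female, qc$age_band, qc$income4, qc$employment)
    tab <- table(factor(key_p, levels = key_q))
    expect_equal(as.vector(tab), target)
  }
})

test_that("largest-remainder rounding: 200 participants at female share 0.548 gives 110", {
  cfg <- world_config(extent_m = c(1000, 1000), n_participants = 200, seed = 3)
  q <- simple_quota(c(`1` = 0.548, `0` = 0.452))
  p <- generate_participants(cfg, q)
  expect_equal(nrow(p), 200)
  expect_equal(sum(p$female == 1), 110)
  expect_equal(sum(p$female == 0), 90)
})

test_that("a single stratum with proportion 1 captures every participant", {
  cfg <- world_config(extent_m = c(1000, 1000), n_participants = 30, seed = 3)
  p <- generate_participants(cfg, simple_quota(c(employed = 1.0), "employment"))
  expect_true(all(p$employment == "employed"))
})

test_that("invalid quotas are rejected", {
  cfg <- tiny_world()
  expect_error(generate_participants(cfg, simple_quota(c(`1` = 0.6, `0` = 0.3))),
               "sum")
})

test_that("participant fields are in range and homes inside the extent", {
  cfg <- world_config(extent_m = c(1000, 1000), n_participants = 80, seed = 5)
  p <- generate_participants(cfg)
  expect_true(all(p$age >= 18 & p$age <= 64))
  expect_true(all(p$income %in% 1:7))
  expect_true(all(p$education %in% 1:6))
  expect_true(all(p$home_x > 0 & p$home_x < 1000))
  expect_true(all(p$home_y > 0 & p$home_y < 1000))
})

test_that("two-day trajectory has exactly 2 x 86,400 fixes, inside the extent", {
  cfg <- tiny_world(seed = 8)
  r <- generate_landuse_raster(cfg)
  p <- generate_participants(cfg)
  tr <- generate_trajectory(p[1, ], r, cfg)
  expect_equal(nrow(tr), 2 * 86400)
  expect_true(all(tr$x >= 0 & tr$x <= 1000 & tr$y >= 0 & tr$y <= 1000))
  tr2 <- generate_trajectory(p[1, ], r, cfg)
  expect_identical(tr, tr2)
})

test_that("homebody trajectories stay within jitter range of home", {
  cfg <- tiny_world(seed = 8, jitter_sd = 2)
  r <- generate_landuse_raster(cfg)
  p <- generate_participants(cfg)
  tr <- generate_trajectory(p[1, ], r, cfg, homebody = TRUE)
  d <- sqrt((tr$x - p$home_x[1])^2 + (tr$y - p$home_y[1])^2)
  expect_true(all(d < 6 * 2))  # 6 sd covers all fixes comfortably
})

test_that("pollution field: transport-cell vs far-field difference equals the increment", {
  cfg <- world_config(extent_m = c(400, 400), n_participants = 2, seed = 1,
                      class_roles = list(green = 21:23, open_space = 24L,
                                         transport = 1:4))
  # left half all-transport, right half background: deep interiors have
  # smoothed indicators exactly 1 and 0
  m <- matrix(9L, 40, 40); m[, 1:20] <- 1L
  r <- landuse_raster(m, cell_size_m = 10)
  tm <- true_model(pollution = list(baseline = 10, gradient = 0,
                                    transport_increment = 7, green_decrement = 3,
                                    amplitude = 0, noise_sd = 0,
                                    smooth_radius_m = 50))
  f <- pollution_field(r, cfg, tm)
  on_t <- pollution_at(f, 100, 200, 0)    # deep inside transport half
  off_t <- pollution_at(f, 300, 200, 0)   # deep inside background half
  expect_equal(on_t - off_t, 7, tolerance = 1e-12)
  expect_equal(off_t, 10, tolerance = 1e-12)
})

test_that("sensor stream is deterministic per seed and non-negative", {
  cfg <- tiny_world(seed = 4)
  r <- generate_landuse_raster(cfg)
  p <- generate_participants(cfg)
  tm <- true_model()
  f <- pollution_field(r, cfg, tm)
  tr <- generate_trajectory(p[1, ], r, cfg)
  s1 <- generate_sensor_stream(tr, f, tm, seed = 99)
  s2 <- generate_sensor_stream(tr, f, tm, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1$pm25 >= 0))
  expect_equal(nrow(s1), nrow(tr))
})

test_that("questionnaire: constant latent between cutpoints 3 and 4 gives level 4", {
  tm <- true_model(perception_coefficients = c(intercept = 3.5),
                   latent_noise_sd = 0, cutpoints = c(1, 2, 3, 4, 5))
  parts <- data.frame(participant_id = 1:20)
  out <- generate_questionnaire(parts, tm, seed = 1)
  expect_true(all(out$perception == 4L))
  expect_true(all(out$mental_health >= 4 & out$mental_health <= 24))
  expect_true(all(out$respiratory >= 3 & out$respiratory <= 18))
})

test_that("questionnaire: positive mental-health coefficient induces positive correlation", {
  tm <- true_model(perception_coefficients = c(intercept = -5, mental_health = 0.4),
                   latent_noise_sd = 0.5)
  parts <- data.frame(participant_id = 1:1000)
  out <- generate_questionnaire(parts, tm, seed = 7)
  expect_gt(cor(out$mental_health, out$perception), 0.3)
})

test_that("questionnaire errors on a missing covariate", {
  tm <- true_model(perception_coefficients = c(intercept = 0, pm25 = 0.1))
  expect_error(generate_questionnaire(data.frame(participant_id = 1:5), tm, 1),
               "no matching covariate")
})

test_that("ASCII-grid round trip preserves the raster exactly", {
  r <- generate_landuse_raster(tiny_world(seed = 2, extent = 500))
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(r$codes, r2$codes)
  expect_equal(r$origin, r2$origin)
  expect_equal(r$cell_size_m, r2$cell_size_m)
})

test_that("street blocks tile the extent and population density is consistent", {
  cfg <- tiny_world(seed = 6)
  b <- generate_street_blocks(cfg, block_m = 250)
  expect_equal(sum(b$area_km2) * 1e6, 1000 * 1000)
  expect_true(all(b$population >= 0))
  # implied densities stay in the configured urban range
  dens <- b$population / b$area_km2
  expect_true(all(dens >= 6e3 - 1 & dens <= 3.5e5 + 1))
})
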