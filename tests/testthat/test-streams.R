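# Stream fusion: calibration, minute aggregation, two-day exposure,
# histograms.

make_stream <- function(t, pm, rh = 70, temp = 25, id = 1L) {
  data.frame(participant_id = id, time_s = t, pm25 = pm,
             rh = rep_len(rh, length(t)), temp = rep_len(temp, length(t)))
}

test_that("calibration is the linear map with truncation at zero", {
  s <- make_stream(0:2, c(1, 2, 3))
  expect_equal(apply_calibration(s, calibration_model(1, 0))$pm25, c(1, 2, 3))
  expect_equal(apply_calibration(s, calibration_model(2, 1))$pm25, c(3, 5, 7))
  s2 <- make_stream(0, 5)
  expect_equal(apply_calibration(s2, calibration_model(1, -10))$pm25, 0)
  expect_error(calibration_model(0, 1), "slope")
  expect_error(calibration_model(-2, 1), "slope")
})

test_that("minute aggregation averages channels and takes the fix centroid", {
  # 120 constant samples at a fixed point -> two records of that value
  t <- 0:119
  s <- make_stream(t, rep(7, 120))
  traj <- data.frame(time_s = t, x = rep(3, 120), y = rep(4, 120))
  m <- aggregate_minutes(s, traj)
  expect_equal(nrow(m), 2)
  expect_equal(m$pm25_mean, c(7, 7))
  expect_equal(m$x, c(3, 3)); expect_equal(m$y, c(4, 4))
  expect_equal(m$n_samples, c(60, 60))
  expect_equal(m$minute_start, c(0, 60))

  # samples [2, 4] in one window -> mean 3; fixes at (0,0), (10,0) -> (5,0)
  s2 <- make_stream(c(10, 20), c(2, 4))
  traj2 <- data.frame(time_s = c(10, 20), x = c(0, 10), y = c(0, 0))
  m2 <- aggregate_minutes(s2, traj2)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$pm25_mean, 3)
  expect_equal(m2$x, 5); expect_equal(m2$y, 0)
})

test_that("aggregation is mean-preserving for constant streams with gaps", {
  set.seed(1)
  t <- sort(sample(0:599, 200))
  s <- make_stream(t, rep(11.5, length(t)))
  traj <- data.frame(time_s = t, x = runif(length(t)), y = runif(length(t)))
  m <- aggregate_minutes(s, traj)
  expect_true(all(abs(m$pm25_mean - 11.5) < 1e-12))
  expect_equal(sum(m$n_samples), length(t))
  # windows with no samples are absent, not zero-filled
  expect_true(all(m$n_samples >= 1))
})

test_that("non-overlapping stream and trajectory yield a warning and no records", {
  s <- make_stream(0:10, 1:11)
  traj <- data.frame(time_s = 1000:1010, x = 0, y = 0)
  expect_warning(m <- aggregate_minutes(s, traj), "overlap")
  expect_equal(nrow(m), 0)
})

test_that("two-day exposure is the pooled mean, permutation-invariant", {
  rec <- data.frame(pm25_mean = c(10, 20, 30))
  expect_equal(two_day_exposure(rec), 20)
  expect_equal(two_day_exposure(rec[c(3, 1, 2), , drop = FALSE]), 20)
  expect_equal(two_day_exposure(data.frame(pm25_mean = rep(12.5, 9))), 12.5)
  expect_error(two_day_exposure(data.frame(pm25_mean = numeric(0))), "missing")
})

test_that("a noiseless homebody's exposure equals the field value at home", {
  cfg <- tiny_world(seed = 12, jitter_sd = 0)
  r <- generate_landuse_raster(cfg)
  p <- generate_participants(cfg)
  tm <- true_model(pollution = list(baseline = 14, gradient = 5,
                                    transport_increment = 12, green_decrement = 6,
                                    amplitude = 0, noise_sd = 0,
                                    smooth_radius_m = 50))
  f <- pollution_field(r, cfg, tm)
  tr <- generate_trajectory(p[1, ], r, cfg, homebody = TRUE)
  st <- generate_sensor_stream(tr, f, tm, seed = 1)
  m <- aggregate_minutes(st, tr)
  expect_equal(two_day_exposure(m),
               pollution_at(f, p$home_x[1], p$home_y[1], 0),
               tolerance = 1e-10)
})

test_that("exposure histogram bins per community and conserves counts", {
  h <- exposure_histogram(c(3, 7, 12), c("A", "A", "B"), bin_width = 5)
  expect_equal(unname(h["A", "[0,5)"]), 1L)
  expect_equal(unname(h["A", "[5,10)"]), 1L)
  expect_equal(unname(h["B", "[10,15)"]), 1L)
  expect_equal(sum(h), 3)
  # all exposures below 40 -> no bin at or above 40
  h2 <- exposure_histogram(runif(50, 0, 39.9), rep(c("A", "B"), 25))
  expect_true(max(as.numeric(sub("\\[(\\d+).*", "\\1", colnames(h2)))) < 40)
  expect_equal(sum(h2), 50)
  # empty community keeps an all-zero row
  h3 <- exposure_histogram(c(1, 2), factor(c("A", "A"), levels = c("A", "B")))
  expect_equal(unname(rowSums(h3)), c(2, 0))
  expect_error(exposure_histogram(1, "A", bin_width = 0), "bin_width")
})
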