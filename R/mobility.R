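# Anchor-based mobility and co-registered sensor streams.
#
# Trajectories are generated from a daily activity schedule anchored at home,
# a workplace (weekdays) and a leisure location (weekend days), with
# constant-speed straight-line walks between anchors and small iid positional
# jitter on every fix. This is deliberately simpler than route-network
# simulation: what downstream stages need is a realistic contrast between
# residence-based and mobility-based context, which commuting provides.

# sample a random cell center whose code is in `codes`; fall back to the
# extent center when no such cell exists
sample_role_point <- function(raster, codes) {
  m <- raster$codes %in% codes
  dim(m) <- dim(raster$codes)
  hit <- which(m, arr.ind = TRUE)
  if (!nrow(hit)) {
    ext <- raster_extent(raster)
    return(c(mean(ext[c(1, 3)]), mean(ext[c(2, 4)])))
  }
  i <- hit[sample.int(nrow(hit), 1L), ]
  ctr <- cell_center(raster, i[1], i[2])
  c(ctr$x, ctr$y)
}

# piecewise day path: `segments` is a data.frame(start_s, end_s, x0, y0, x1, y1);
# returns x, y vectors for seconds 0..86399
day_path <- function(segments) {
  x <- numeric(86400); y <- numeric(86400)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    idx <- (s$start_s:(s$end_s - 1)) + 1
    if (s$x0 == s$x1 && s$y0 == s$y1) {
      x[idx] <- s$x0; y[idx] <- s$y0
    } else {
      f <- seq(0, 1, length.out = length(idx))
      x[idx] <- s$x0 + f * (s$x1 - s$x0)
      y[idx] <- s$y0 + f * (s$y1 - s$y0)
    }
  }
  list(x = x, y = y)
}

build_day_segments <- function(home, away, t_leave, t_return, speed) {
  d <- sqrt(sum((away - home)^2))
  w <- max(1L, as.integer(ceiling(d / speed)))
  stopifnot(t_leave + w < t_return)
  data.frame(
    start_s = c(0L, t_leave, t_leave + w, t_return, t_return + w),
    end_s   = c(t_leave, t_leave + w, t_return, t_return + w, 86400L),
    x0 = c(home[1], home[1], away[1], away[1], home[1]),
    y0 = c(home[2], home[2], away[2], away[2], home[2]),
    x1 = c(home[1], away[1], away[1], home[1], home[1]),
    y1 = c(home[2], away[2], away[2], home[2], home[2])
  )
}

#' Generate a two-day 1-second GPS trajectory
#'
#' Produces `n_days * 86400` one-second fixes from an anchor-based schedule:
#' overnight at home, a weekday workplace anchor (drawn near the
#' transportation corridors) reached by a constant-speed straight-line walk
#' leaving at 08:00 and returning at 18:00, and a weekend leisure anchor
#' (drawn near open space or green patches) visited 09:30-16:00. Odd survey
#' days are weekdays, even days weekend days (the survey pairs one of each).
#' Every fix receives iid Gaussian jitter (`config$jitter_sd`) and is clamped
#' to the extent. Deterministic given `config$seed` and the participant id.
#'
#' @param participant one row of [generate_participants()] output (or any
#'   list with `participant_id`, `home_x`, `home_y`).
#' @param raster the world's [landuse_raster()] (used to place anchors).
#' @param config a [world_config()].
#' @param homebody if `TRUE`, all anchors equal home (a zero-mobility
#'   participant; useful as an analytic control).
#' @return data.frame `participant_id`, `time_s` (0-based seconds from
#'   survey start), `x`, `y`.
#' @export
generate_trajectory <- function(participant, raster, config, homebody = FALSE) {
  stopifnot(inherits(config, "world_config"))
  home <- c(participant$home_x, participant$home_y)
  ext <- raster_extent(raster)
  if (home[1] < ext["xmin"] || home[1] >= ext["xmax"] ||
      home[2] < ext["ymin"] || home[2] >= ext["ymax"])
    stopf("home location must lie inside the raster extent")
  id <- participant$participant_id
  with_seed(sub_seed(config$seed, 1000L + id), {
    work <- if (homebody) home else
      sample_role_point(raster, config$class_roles$transport)
    leis <- if (homebody) home else
      sample_role_point(raster, c(config$class_roles$open_space,
                                  config$class_roles$green))
    xs <- numeric(0); ys <- numeric(0)
    for (d in seq_len(config$n_days)) {
      seg <- if (d %% 2 == 1)
        build_day_segments(home, work, t_leave = 8L * 3600L,
                           t_return = 18L * 3600L, speed = config$walk_speed_ms)
      else
        build_day_segments(home, leis, t_leave = 34200L,  # 09:30
                           t_return = 16L * 3600L, speed = config$walk_speed_ms)
      p <- day_path(seg)
      xs <- c(xs, p$x); ys <- c(ys, p$y)
    }
    n <- length(xs)
    if (config$jitter_sd > 0) {
      xs <- xs + stats::rnorm(n, 0, config$jitter_sd)
      ys <- ys + stats::rnorm(n, 0, config$jitter_sd)
    }
    eps <- 1e-6
    xs <- pmin(pmax(xs, ext["xmin"] + eps), ext["xmax"] - eps)
    ys <- pmin(pmax(ys, ext["ymin"] + eps), ext["ymax"] - eps)
    data.frame(participant_id = id, time_s = seq_len(n) - 1,
               x = unname(xs), y = unname(ys))
  })
}

#' Generate a co-registered 1-second sensor stream
#'
#' One PM2.5 / relative-humidity / temperature sample per GPS fix. PM2.5 is
#' the synthetic field of [pollution_field()] evaluated at the fix (baseline
#' plus transport-proximity increment minus green-proximity decrement plus a
#' diurnal sine) with iid Gaussian measurement noise, truncated at 0.
#' Humidity and temperature follow smooth diurnal curves with noise.
#'
#' @param trajectory output of [generate_trajectory()].
#' @param field a [pollution_field()].
#' @param tm the [true_model()] (for the measurement-noise sd).
#' @param seed integer seed for the measurement noise.
#' @return data.frame `participant_id`, `time_s`, `pm25`, `rh`, `temp`.
#' @export
generate_sensor_stream <- function(trajectory, field, tm, seed = 1L) {
  n <- nrow(trajectory)
  if (n < 1L) stopf("trajectory is empty")
  with_seed(seed, {
    base <- pollution_at(field, trajectory$x, trajectory$y, trajectory$time_s)
    pm <- pmax(0, base + stats::rnorm(n, 0, tm$pollution$noise_sd))
    tod <- trajectory$time_s %% 86400
    rh <- pmin(100, pmax(0, 70 + 8 * sin(2 * pi * (tod - 4 * 3600) / 86400) +
                           stats::rnorm(n, 0, 2)))
    temp <- 26 + 3 * sin(2 * pi * (tod - 8 * 3600) / 86400) +
      stats::rnorm(n, 0, 0.5)
    data.frame(participant_id = trajectory$participant_id, time_s = trajectory$time_s,
               pm25 = pm, rh = rh, temp = temp)
  })
}
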