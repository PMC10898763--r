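# Plain-text interchange formats: GeoJSON for points/blocks, CSV for
# trajectories, sensor streams, minute records and exposure tables.

#' Write and read facilities as GeoJSON points
#'
#' @param facilities data.frame `facility_id`, `x`, `y` (coordinates in the
#'   local projected plane, meters).
#' @param path file path.
#' @return reader returns the facilities data.frame.
#' @export
write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) {
    list(type = "Feature",
         properties = list(facility_id = facilities$facility_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[i], facilities$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_facilities_geojson
#' @export
read_facilities_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  do.call(rbind, lapply(g$features, function(f) {
    data.frame(facility_id = f$properties$facility_id,
               x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]])
  }))
}

#' Write and read street blocks as GeoJSON polygons
#'
#' Each block is an axis-aligned rectangle carrying a `population` property.
#'
#' @param blocks a `street_blocks` data.frame
#'   (see [generate_street_blocks()]).
#' @param path file path.
#' @export
write_blocks_geojson <- function(blocks, path) {
  feats <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    ring <- list(c(b$xmin, b$ymin), c(b$xmax, b$ymin), c(b$xmax, b$ymax),
                 c(b$xmin, b$ymax), c(b$xmin, b$ymin))
    list(type = "Feature",
         properties = list(block_id = b$block_id, population = b$population),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blocks_geojson
#' @export
read_blocks_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  out <- do.call(rbind, lapply(g$features, function(f) {
    xs <- vapply(f$geometry$coordinates[[1]], function(p) p[[1]], 0)
    ys <- vapply(f$geometry$coordinates[[1]], function(p) p[[2]], 0)
    data.frame(block_id = f$properties$block_id,
               xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
               population = f$properties$population,
               area_km2 = (max(xs) - min(xs)) * (max(ys) - min(ys)) / 1e6)
  }))
  class(out) <- c("street_blocks", "data.frame")
  out
}

#' CSV interchange for trajectories and sensor streams
#'
#' Trajectories: `participant_id, timestamp_iso8601, x_m, y_m`. Sensor
#' streams: `participant_id, timestamp_iso8601, pm25_ugm3, rh_pct, temp_c`.
#' Timestamps render the internal seconds-from-survey-start against a fixed
#' UTC origin, so identical runs are byte-identical.
#'
#' @param traj,stream data.frames in the package's internal column layout.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(data.frame(participant_id = traj$participant_id,
                              timestamp_iso8601 = iso_time(traj$time_s),
                              x_m = traj$x, y_m = traj$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(participant_id = d$participant_id,
             time_s = parse_iso_time(d$timestamp_iso8601),
             x = d$x_m, y = d$y_m)
}

#' @rdname write_trajectory_csv
#' @export
write_sensor_csv <- function(stream, path) {
  utils::write.csv(data.frame(participant_id = stream$participant_id,
                              timestamp_iso8601 = iso_time(stream$time_s),
                              pm25_ugm3 = stream$pm25, rh_pct = stream$rh,
                              temp_c = stream$temp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_sensor_csv <- function(path) {
  d <- utils::read.csv(path)
  data.frame(participant_id = d$participant_id,
             time_s = parse_iso_time(d$timestamp_iso8601),
             pm25 = d$pm25_ugm3, rh = d$rh_pct, temp = d$temp_c)
}
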