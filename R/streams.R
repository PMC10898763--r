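# Fusion of raw 1-second sensor and GPS streams into calibrated minute-level
# records and two-day personal exposure summaries.

#' Linear sensor calibration model
#'
#' Portable optical PM2.5 sensors are calibrated against a reference
#' instrument with a linear map; the coefficients come from an external
#' co-location study and are supplied by configuration.
#'
#' @param slope dimensionless gain; must be > 0.
#' @param intercept offset in ug/m3.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(slope = 1, intercept = 0) {
  if (!is.numeric(slope) || slope <= 0) stopf("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept),
            class = "calibration_model")
}

#' Apply a linear calibration to a sensor stream
#'
#' `pm25' = max(0, slope * pm25 + intercept)`; humidity and temperature are
#' left unchanged. Truncation at 0 enforces physical non-negativity.
#'
#' @param stream data.frame with at least a `pm25` column.
#' @param model a [calibration_model()].
#' @return the stream with calibrated `pm25`.
#' @export
apply_calibration <- function(stream, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.null(stream$pm25)) stopf("stream must have a pm25 column")
  stream$pm25 <- pmax(0, model$slope * stream$pm25 + model$intercept)
  stream
}

#' Aggregate 1-second streams to minute records
#'
#' Reduces a sensor stream and its co-registered trajectory to one record
#' per half-open minute window `[t, t + 60)` containing at least one sensor
#' sample. Windows are aligned to the whole minute of the participant's
#' first sample. Channel values are arithmetic means within the window
#' (reducing minor second-to-second fluctuation); the representative
#' location is the centroid of the window's GPS fixes. Windows without
#' samples are absent, not zero-filled; windows with samples but no fixes
#' get `NA` coordinates.
#'
#' @param stream data.frame `time_s`, `pm25`, `rh`, `temp` (and optionally
#'   `participant_id`).
#' @param traj data.frame `time_s`, `x`, `y`.
#' @return data.frame `participant_id`, `minute_start` (seconds), `pm25_mean`,
#'   `rh_mean`, `temp_mean`, `x`, `y`, `n_samples`.
#' @export
aggregate_minutes <- function(stream, traj) {
  if (nrow(stream) == 0L || nrow(traj) == 0L ||
      max(stream$time_s) < min(traj$time_s) || max(traj$time_s) < min(stream$time_s)) {
    warnf("sensor stream and trajectory do not overlap in time; no minute records")
    return(data.frame(participant_id = integer(0), minute_start = numeric(0),
                      pm25_mean = numeric(0), rh_mean = numeric(0),
                      temp_mean = numeric(0), x = numeric(0), y = numeric(0),
                      n_samples = integer(0)))
  }
  t0 <- floor(min(stream$time_s) / 60) * 60
  w <- floor((stream$time_s - t0) / 60)
  key <- sort(unique(w))
  grp <- match(w, key)
  n_s <- tabulate(grp, length(key))
  agg <- function(v) rowsum(v, grp, reorder = TRUE)[, 1] / n_s
  wt <- floor((traj$time_s - t0) / 60)
  keep <- wt >= 0 & wt %in% key
  gt <- match(wt[keep], key)
  n_t <- tabulate(gt, length(key))
  cx <- rep(NA_real_, length(key)); cy <- rep(NA_real_, length(key))
  if (any(keep)) {
    sx <- rowsum(traj$x[keep], gt, reorder = TRUE)
    sy <- rowsum(traj$y[keep], gt, reorder = TRUE)
    got <- sort(unique(gt))
    cx[got] <- sx[, 1] / n_t[got]
    cy[got] <- sy[, 1] / n_t[got]
  }
  pid <- if (!is.null(stream$participant_id)) stream$participant_id[1] else NA_integer_
  data.frame(participant_id = pid,
             minute_start = t0 + key * 60,
             pm25_mean = agg(stream$pm25),
             rh_mean = agg(stream$rh),
             temp_mean = agg(stream$temp),
             x = cx, y = cy,
             n_samples = n_s)
}

#' Two-day personal PM2.5 exposure
#'
#' A participant's exposure is the arithmetic mean of the minute-level PM2.5
#' means pooled over all available minutes of the two survey days. Minutes
#' without records are simply absent; no imputation is attempted, matching
#' the use of participants with adequate and valid sensor records only.
#'
#' @param records minute records from [aggregate_minutes()].
#' @return scalar exposure in ug/m3.
#' @export
two_day_exposure <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stopf("no minute records: exposure is missing for this participant")
  mean(records$pm25_mean)
}

#' Histogram of per-participant exposures by community
#'
#' Counts participants per half-open exposure bin `[k*w, (k+1)*w)` per
#' community, the summary behind the exposure histograms of a two-community
#' monitoring campaign.
#'
#' @param exposures numeric vector of two-day exposures (ug/m3).
#' @param community character/factor of the same length (a community with no
#'   participants yields an all-zero row).
#' @param bin_width bin width in ug/m3 (default 5).
#' @return matrix of counts, rows = communities, columns = bins labelled
#'   `[lo,hi)`.
#' @export
exposure_histogram <- function(exposures, community, bin_width = 5) {
  if (!is.numeric(bin_width) || bin_width <= 0) stopf("bin_width must be > 0")
  if (!length(exposures)) stopf("exposures must be non-empty")
  comm <- if (is.factor(community)) community else factor(community)
  k <- floor(exposures / bin_width)
  kmax <- max(k)
  bins <- 0:kmax
  out <- matrix(0L, nlevels(comm), length(bins))
  for (i in seq_len(nlevels(comm)))
    out[i, ] <- tabulate(match(k[comm == levels(comm)[i]], bins), length(bins))
  colnames(out) <- sprintf("[%g,%g)", bins * bin_width, (bins + 1) * bin_width)
  rownames(out) <- levels(comm)
  out
}
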