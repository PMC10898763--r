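#' Ground-truth generating model for the synthetic cohort
#'
#' Collects every parameter of the synthetic data-generating process whose
#' recovery the downstream statistical layer is tested against: the linear
#' predictor of the latent air-quality perception, the ordered cutpoints that
#' discretise it to the six-point item, the common-factor loadings behind the
#' mental-health and respiratory instruments, and the parameters of the
#' synthetic PM2.5 field.
#'
#' The latent perception is
#' `eta = intercept + sum_j beta_j x_j + N(0, latent_noise_sd)` and the
#' reported level is `1 + #\{cutpoints < eta\}`, so five strictly increasing
#' cutpoints map the latent scale onto levels 1-6.
#'
#' The pollution field at location s and second-of-day t is
#' `pm(s, t) = baseline + gradient * (x(s)/W - 1/2)
#'  + transport_increment * T(s) - green_decrement * G(s)
#'  + amplitude * sin(2*pi*(t - 6*3600)/86400) + N(0, noise_sd)`, truncated
#' at 0, where `T` and `G` are disc-smoothed (50 m) transport and green
#' indicators in `[0, 1]` and the `gradient` term is a regional smog
#' gradient across the extent width `W` (cities sit in regional pollution
#' fields, so communities at different ends of the extent differ in ambient
#' level; this is what spreads the two-day exposure distribution over a
#' realistic 5-40 ug/m3 range).
#'
#' @param perception_coefficients named numeric vector of latent-perception
#'   weights; names must match columns of the participant table augmented
#'   with exposures (e.g. `pm25`, `age`, `female`, `mental_health`,
#'   `transport_mb`, `green_mb`). An `intercept` element is the latent
#'   intercept.
#' @param latent_noise_sd standard deviation of the latent perception noise.
#' @param cutpoints five strictly increasing thresholds.
#' @param mh_loading common-factor loading of the four mental-health items
#'   (and the three respiratory items).
#' @param item_noise_sd residual item noise on the six-point scale.
#' @param pollution list with `baseline`, `transport_increment`,
#'   `green_decrement`, `amplitude`, `noise_sd` (all in ug/m3) and
#'   `smooth_radius_m` for the proximity fields.
#' @return object of class `true_model`.
#' @export
true_model <- function(perception_coefficients = c(intercept = 2.0,
                                                   pm25 = 0.03,
                                                   age = -0.02,
                                                   female = -0.25,
                                                   mental_health = 0.06,
                                                   transport_mb = 2.5,
                                                   green_mb = 1.8),
                       latent_noise_sd = 0.8,
                       cutpoints = c(1.5, 2.5, 3.2, 4.0, 5.0),
                       mh_loading = 1.1,
                       item_noise_sd = 0.8,
                       pollution = list(baseline = 15,
                                        gradient = 20,
                                        transport_increment = 12,
                                        green_decrement = 6,
                                        amplitude = 4,
                                        noise_sd = 3,
                                        smooth_radius_m = 50)) {
  if (is.null(pollution$gradient)) pollution$gradient <- 0
  if (length(cutpoints) != 5L || any(diff(cutpoints) <= 0))
    stopf("cutpoints must be 5 strictly increasing values")
  if (latent_noise_sd < 0) stopf("latent_noise_sd must be >= 0")
  if (pollution$noise_sd < 0) stopf("pollution noise_sd must be >= 0")
  if (is.null(names(perception_coefficients)))
    stopf("perception_coefficients must be named")
  structure(list(perception_coefficients = perception_coefficients,
                 latent_noise_sd = latent_noise_sd,
                 cutpoints = cutpoints,
                 mh_loading = mh_loading,
                 item_noise_sd = item_noise_sd,
                 pollution = pollution),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat("<true_model>\n  perception: ",
      paste(sprintf("%s=%.3g", names(x$perception_coefficients),
                    x$perception_coefficients), collapse = ", "),
      sprintf("\n  latent sd %.3g; cutpoints %s\n", x$latent_noise_sd,
              paste(x$cutpoints, collapse = "/")),
      sprintf("  pollution: base %.3g +T %.3g -G %.3g amp %.3g noise %.3g\n",
              x$pollution$baseline, x$pollution$transport_increment,
              x$pollution$green_decrement, x$pollution$amplitude,
              x$pollution$noise_sd), sep = "")
  invisible(x)
}

#' Precompute the deterministic part of the synthetic pollution field
#'
#' Returns an object evaluating the noiseless field at any (x, y, t); used by
#' the sensor-stream generator and usable directly as an analytic oracle for
#' spot checks.
#'
#' @param raster a [landuse_raster()].
#' @param config a [world_config()] (supplies the role code sets).
#' @param tm a [true_model()].
#' @return object of class `pollution_field`; call
#'   [pollution_at()] to evaluate it.
#' @export
pollution_field <- function(raster, config, tm) {
  rad <- tm$pollution$smooth_radius_m
  structure(list(
    raster = raster,
    tmat = role_proximity_field(raster, config$class_roles$transport, rad),
    gmat = role_proximity_field(raster, config$class_roles$green, rad),
    params = tm$pollution
  ), class = "pollution_field")
}

#' Evaluate the noiseless synthetic PM2.5 field
#'
#' @param field a [pollution_field()].
#' @param x,y coordinates in meters (vectorised).
#' @param time_s seconds from survey start (vectorised; only second-of-day
#'   enters the diurnal term).
#' @return PM2.5 in ug/m3, truncated at 0.
#' @export
pollution_at <- function(field, x, y, time_s) {
  p <- field$params
  cells <- point_cell(field$raster, x, y)
  idx <- cbind(cells$row, cells$col)
  diurnal <- p$amplitude * sin(2 * pi * ((time_s %% 86400) - 6 * 3600) / 86400)
  ext <- raster_extent(field$raster)
  grad <- p$gradient * ((x - ext["xmin"]) / (ext["xmax"] - ext["xmin"]) - 0.5)
  pmax(0, p$baseline + unname(grad) + p$transport_increment * field$tmat[idx] -
         p$green_decrement * field$gmat[idx] + diurnal)
}
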