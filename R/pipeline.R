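# End-to-end orchestration: generate -> fuse -> expose -> score -> classify
# -> model, with a JSON run manifest and CSV artifacts.

#' Run configuration
#'
#' Bundles the world, ground-truth model, sensor calibration, ring family
#' and selector options behind a single master seed from which every stage
#' derives its own sub-seed deterministically.
#'
#' @param world a [world_config()] (its seed is overridden by `seed`).
#' @param tm a [true_model()].
#' @param calibration a [calibration_model()].
#' @param family ring family data.frame (default [ring_family()]).
#' @param selector scan selector, `"adj_r2"` (default) or `"r2"`.
#' @param mb_report_ring length-2 `(inner, outer)` of the ring whose MB
#'   transport/green densities feed the latent perception model (default
#'   the 350-400 m ring).
#' @param write_minutes write the (large) minute-record CSV (default FALSE).
#' @param seed master integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(world = world_config(), tm = true_model(),
                       calibration = calibration_model(slope = 1.05, intercept = -0.5),
                       family = ring_family(), selector = "adj_r2",
                       mb_report_ring = c(350, 400),
                       write_minutes = FALSE, seed = 1L) {
  world$seed <- as.integer(seed)
  structure(list(world = world, tm = tm, calibration = calibration,
                 family = family, selector = selector,
                 mb_report_ring = mb_report_ring,
                 write_minutes = isTRUE(write_minutes), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; YAML values override
#' the defaults, and anything omitted keeps its default. Nested keys:
#' `world` (extent_m, cell_size_m, n_participants, n_days, ...),
#' `calibration` (slope, intercept), `true_model` (latent_noise_sd,
#' cutpoints, perception_coefficients, pollution), `seed`, `selector`.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the YAML value.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  wargs <- y$world %||% list()
  world <- do.call(world_config, wargs)
  tm_args <- y$true_model %||% list()
  if (!is.null(tm_args$perception_coefficients))
    tm_args$perception_coefficients <- unlist(tm_args$perception_coefficients)
  if (!is.null(tm_args$cutpoints)) tm_args$cutpoints <- unlist(tm_args$cutpoints)
  tm <- do.call(true_model, tm_args)
  cal <- do.call(calibration_model, y$calibration %||% list())
  run_config(world = world, tm = tm, calibration = cal,
             selector = y$selector %||% "adj_r2",
             write_minutes = y$write_minutes %||% FALSE,
             seed = seed %||% y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariates of the full perception model, in reporting order
perception_covariates <- function() {
  c("pm25", "female", "community_b", "age", "education", "divorced",
    "married", "widowed", "income", "student", "unemployed", "family_size",
    "own_no_mortgage", "own_mortgage", "living_space", "exercise_days",
    "rh_mean", "temp_mean", "population_density", "transport_density",
    "green_density", "open_density", "facility_density", "respiratory",
    "mental_health")
}

# reduced covariate set of the mismatch models
mismatch_covariates <- function() {
  c("age", "female", "community_b", "student", "unemployed", "living_space",
    "rh_mean", "respiratory", "mental_health", "transport_density",
    "green_density", "open_density", "facility_density")
}

#' Assemble a model-ready design for one method and ring buffer
#'
#' Joins the participant analysis table with the wide per-factor densities
#' of one method (RB or MB) at one ring. Population density is always the
#' residence-based value (no mobility-based population density exists).
#' Covariates without variation in the cohort are dropped with a message,
#' since they cannot enter a regression.
#'
#' @param analysis participant analysis table (from [run_pipeline()] or
#'   equivalent), containing the encoded covariates, `pm25`, `rh_mean`,
#'   `temp_mean`, `population_density`, `perception`, `quadrant`.
#' @param records long exposure records (`participant_id`, `method`,
#'   `inner_m`, `outer_m`, `factor`, `value`).
#' @param method `"RB"` or `"MB"`.
#' @param inner_m,outer_m the ring.
#' @return data.frame ready for [fit_linear_perception()] /
#'   [fit_multinomial_mismatch()].
#' @export
build_design <- function(analysis, records, method, inner_m, outer_m) {
  sel <- records$method == method & records$inner_m %in% inner_m &
    records$outer_m %in% outer_m
  if (!any(sel)) stopf("no exposure records for %s ring (%g, %g)", method, inner_m, outer_m)
  r <- records[sel, , drop = FALSE]
  wide <- stats::reshape(r[, c("participant_id", "factor", "value")],
                         idvar = "participant_id", timevar = "factor",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  ren <- c(transport = "transport_density", green = "green_density",
           open_space = "open_density")
  for (nm in names(ren)) if (nm %in% names(wide))
    names(wide)[names(wide) == nm] <- ren[[nm]]
  # facility density is ring-independent (1-km disc) but method-specific
  fsel <- records$method == method & records$factor == "facility"
  if (any(fsel))
    wide <- merge(wide, data.frame(
      participant_id = records$participant_id[fsel],
      facility_density = records$value[fsel]), by = "participant_id")
  out <- merge(analysis, wide, by = "participant_id")
  dropped <- character(0)
  for (nm in setdiff(names(out), c("participant_id", "perception", "quadrant"))) {
    v <- out[[nm]]
    if (is.numeric(v) && length(unique(v[!is.na(v)])) < 2L) {
      out[[nm]] <- NULL
      dropped <- c(dropped, nm)
    }
  }
  if (length(dropped))
    message("build_design: dropped constant covariate(s): ",
            paste(dropped, collapse = ", "))
  out
}

design_formula <- function(design, response, covariates) {
  use <- intersect(covariates, names(design))
  stats::as.formula(paste(response, "~", paste(use, collapse = " + ")))
}

#' Run the full synthetic-study pipeline
#'
#' Generates the synthetic city and cohort, fuses the 1-second streams to
#' minute records, computes RB and MB ring-buffer exposures plus facility
#' and population densities, scores the questionnaire, dichotomises
#' exposure and assigns mismatch quadrants, runs the buffer-distance
#' sensitivity scan, fits the linear perception models (RB and MB at their
#' selected rings) and the multinomial mismatch models, and performs the
#' RB-vs-MB and group-comparison tests. All artifacts are written to
#' `out_dir` as plain text (CSV / GeoJSON / ASCII grid / JSON manifest);
#' identical seeds give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param through last stage to run: `"exposure"` (stop after the exposure
#'   and questionnaire tables) or `"models"` (default, everything).
#' @return invisibly, a list with the stage outputs (`participants`,
#'   `analysis`, `records`, `split`, `scan`, `fits`, `tests`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL, through = c("models", "exposure")) {
  stopifnot(inherits(config, "run_config"))
  through <- match.arg(through)
  w <- config$world
  t_start <- proc.time()[["elapsed"]]
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ras <- generate_landuse_raster(w)
  facs <- generate_facilities(ras, w)
  fgrid <- facility_grid(facs)
  blocks <- generate_street_blocks(w)
  field <- pollution_field(ras, w, config$tm)
  parts <- generate_participants(w)
  n0 <- nrow(parts)

  roles <- w$class_roles[c("transport", "green", "open_space")]
  names(roles) <- c("transport", "green", "open_space")
  fam <- config$family

  rec_list <- vector("list", n0)
  env_rows <- vector("list", n0)
  valid_stream <- logical(n0)
  for (i in seq_len(n0)) {
    p <- parts[i, ]
    traj <- generate_trajectory(p, ras, w)
    stream <- generate_sensor_stream(traj, field, config$tm,
                                     seed = sub_seed(w$seed, 2000L + p$participant_id))
    stream <- apply_calibration(stream, config$calibration)
    minutes <- aggregate_minutes(stream, traj)
    valid_stream[i] <- nrow(minutes) > 0
    if (!valid_stream[i]) next
    pm <- two_day_exposure(minutes)
    home <- c(p$home_x, p$home_y)
    rb <- rb_exposures(home, fam, ras, roles)
    mb <- mb_exposures(minutes[, c("x", "y")], fam, ras, roles)
    # facility density: RB at home; MB as the mean over minute locations
    fd_rb <- facility_density(home, fgrid)
    ml <- minutes[is.finite(minutes$x), c("x", "y")]
    fd_mb <- mean(vapply(seq_len(nrow(ml)), function(j)
      facility_density(c(ml$x[j], ml$y[j]), fgrid), 0))
    rb <- rbind(rb, data.frame(method = "RB", inner_m = NA, outer_m = NA,
                               factor = "facility", value = fd_rb))
    mb <- rbind(mb, data.frame(method = "MB", inner_m = NA, outer_m = NA,
                               factor = "facility", value = fd_mb))
    rec <- rbind(rb, mb)
    rec$participant_id <- p$participant_id
    rec_list[[i]] <- rec
    mbr <- config$mb_report_ring
    env_rows[[i]] <- data.frame(
      participant_id = p$participant_id,
      pm25 = pm,
      rh_mean = mean(minutes$rh_mean), temp_mean = mean(minutes$temp_mean),
      population_density = population_density(home, blocks),
      transport_mb = mb$value[mb$factor == "transport" &
                                mb$inner_m %in% mbr[1] & mb$outer_m %in% mbr[2]],
      green_mb = mb$value[mb$factor == "green" &
                            mb$inner_m %in% mbr[1] & mb$outer_m %in% mbr[2]])
  }
  records <- do.call(rbind, rec_list)
  env <- do.call(rbind, env_rows)

  enc <- encode_covariates(parts)
  analysis <- merge(merge(parts[, c("participant_id", "community")], enc,
                          by = "participant_id"),
                    env, by = "participant_id")
  analysis <- generate_questionnaire(analysis, config$tm,
                                     seed = sub_seed(w$seed, 3000L))
  n_quest <- sum(stats::complete.cases(
    analysis[, c("perception", "mental_health", "respiratory")]))

  split <- kmeans_split(analysis$pm25)
  analysis$exposure_label <- split$labels
  analysis$perception_label <- binarize_perception(analysis$perception)
  analysis$quadrant <- assign_quadrant(analysis$exposure_label,
                                       analysis$perception_label)
  n_lab <- sum(!is.na(analysis$quadrant))

  out <- list(config = config, raster = ras, facilities = facs,
              blocks = blocks, participants = parts, analysis = analysis,
              records = records, split = split)

  if (through == "models" &&
      nrow(analysis) <= length(perception_covariates()) + 2L) {
    message("cohort too small for the full perception model (n = ",
            nrow(analysis), "); model stage skipped")
    through <- "exposure"
  }
  if (through == "models") {
    designs <- list()
    for (m in c("RB", "MB")) for (k in seq_len(nrow(fam))) {
      designs[[length(designs) + 1L]] <- list(
        method = m, inner_m = fam$inner_m[k], outer_m = fam$outer_m[k],
        data = build_design(analysis, records, m, fam$inner_m[k], fam$outer_m[k]))
    }
    common <- Reduce(intersect, lapply(designs, function(d) names(d$data)))
    scan_fml <- stats::as.formula(paste(
      "perception ~", paste(intersect(perception_covariates(), common),
                            collapse = " + ")))
    scan <- sensitivity_scan(designs, formula = scan_fml,
                             selector = config$selector)
    sel_rb <- scan$selected[scan$selected$method == "RB", ]
    sel_mb <- scan$selected[scan$selected$method == "MB", ]

    fit_at <- function(method, sel) {
      d <- build_design(analysis, records, method, sel$inner_m, sel$outer_m)
      fit_linear_perception(design_formula(d, "perception", perception_covariates()), d)
    }
    fits <- list(linear_rb = fit_at("RB", sel_rb), linear_mb = fit_at("MB", sel_mb))

    fit_mm <- function(method, sel) {
      d <- build_design(analysis, records, method, sel$inner_m, sel$outer_m)
      d <- d[!is.na(d$quadrant), , drop = FALSE]
      tryCatch(fit_multinomial_mismatch(
        design_formula(d, "quadrant", mismatch_covariates()), d),
        error = function(e) { message("multinomial fit (", method, ") skipped: ",
                                      conditionMessage(e)); NULL })
    }
    fits$multinomial_rb <- fit_mm("RB", sel_rb)
    fits$multinomial_mb <- fit_mm("MB", sel_mb)

    # RB vs MB Mann-Whitney per land-use factor at the selected rings
    tests <- list()
    for (fac in c("transport", "green", "open_space")) {
      rbv <- records$value[records$method == "RB" & records$factor == fac &
                             records$inner_m %in% sel_rb$inner_m]
      mbv <- records$value[records$method == "MB" & records$factor == fac &
                             records$inner_m %in% sel_mb$inner_m]
      tests[[paste0("mw_", fac)]] <- compare_rb_mb(rbv, mbv)
    }
    tests$mw_facility <- compare_rb_mb(
      records$value[records$method == "RB" & records$factor == "facility"],
      records$value[records$method == "MB" & records$factor == "facility"])
    tests$anova_employment <- tryCatch(
      group_anova(analysis$pm25, parts$employment[match(analysis$participant_id,
                                                        parts$participant_id)]),
      error = function(e) NULL)
    d1 <- build_design(analysis, records, "RB", sel_rb$inner_m, sel_rb$outer_m)
    vif_cols <- intersect(perception_covariates(), names(d1))
    tests$vif <- vif_diagnostics(d1[, vif_cols])

    out$scan <- scan
    out$fits <- fits
    out$tests <- tests
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mobexpo")),
    seed = config$seed,
    n_participants_generated = n0,
    n_valid_streams = sum(valid_stream),
    n_complete_questionnaires = n_quest,
    n_quadrant_labelled = n_lab,
    kmeans_low_max = split$low_max,
    kmeans_high_min = split$high_min,
    selected_rings = if (through == "models")
      list(RB = c(out$scan$selected$inner_m[out$scan$selected$method == "RB"],
                  out$scan$selected$outer_m[out$scan$selected$method == "RB"]),
           MB = c(out$scan$selected$inner_m[out$scan$selected$method == "MB"],
                  out$scan$selected$outer_m[out$scan$selected$method == "MB"]))
    else NULL,
    elapsed_s = round(proc.time()[["elapsed"]] - t_start, 2))
  out$manifest <- manifest

  if (!is.null(out_dir)) {
    write_ascii_grid(ras, file.path(out_dir, "landuse.asc"))
    write_facilities_geojson(facs, file.path(out_dir, "facilities.geojson"))
    write_blocks_geojson(blocks, file.path(out_dir, "street_blocks.geojson"))
    utils::write.csv(format_num(analysis), file.path(out_dir, "participants.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(format_num(records), file.path(out_dir, "exposures.csv"),
                     row.names = FALSE, quote = FALSE)
    if (through == "models") {
      utils::write.csv(format_num(out$scan$table), file.path(out_dir, "scan.csv"),
                       row.names = FALSE, quote = FALSE)
      write_model_tables(out$fits, out_dir)
    }
    manifest_file <- manifest
    manifest_file$elapsed_s <- NULL   # keep artifacts byte-identical per seed
    jsonlite::write_json(manifest_file, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

# round-trip-stable numeric formatting so equal runs give equal bytes
format_num <- function(df) {
  for (nm in names(df)) if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
    df[[nm]] <- sprintf("%.10g", df[[nm]])
  df
}

write_model_tables <- function(fits, out_dir) {
  lin <- function(f, label) {
    sm <- summary(f$fit)$coefficients
    data.frame(model = label, term = rownames(sm), estimate = sm[, 1],
               se = sm[, 2], t = sm[, 3], p = sm[, 4], row.names = NULL)
  }
  tab <- rbind(lin(fits$linear_rb, "RB"), lin(fits$linear_mb, "MB"))
  utils::write.csv(format_num(tab), file.path(out_dir, "linear_models.csv"),
                   row.names = FALSE, quote = FALSE)
  mm <- list(RB = fits$multinomial_rb, MB = fits$multinomial_mb)
  rows <- list()
  for (m in names(mm)) if (!is.null(mm[[m]])) {
    s <- summary(mm[[m]])$table
    s$model <- m
    rows[[m]] <- s
  }
  if (length(rows))
    utils::write.csv(format_num(do.call(rbind, rows)),
                     file.path(out_dir, "multinomial_models.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Render a human-readable run report
#'
#' Builds a Markdown report (plus PNG figures) from a completed run
#' directory: perception distribution by community, exposure histograms,
#' RB-vs-MB comparison, regression tables, and mismatch-quadrant counts.
#' A missing artifact skips its section with a notice instead of failing.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
make_report <- function(run_dir) {
  rp <- file.path(run_dir, "report.md")
  lines <- c("# Synthetic mobility-exposure run report", "")
  pfile <- file.path(run_dir, "participants.csv")
  if (file.exists(pfile)) {
    a <- utils::read.csv(pfile)
    lines <- c(lines, "## Perception distribution", "",
               "Six-point perception item by community (counts):", "")
    tb <- table(a$community, factor(a$perception, levels = 1:6))
    lines <- c(lines, paste("|", paste(c("community", 1:6), collapse = " | "), "|"),
               paste(rep("|---", 7), collapse = ""), "|")
    for (rn in rownames(tb))
      lines <- c(lines, paste("|", paste(c(rn, tb[rn, ]), collapse = " | "), "|"))
    lines <- c(lines, "")
    png_path <- file.path(run_dir, "exposure_hist.png")
    grDevices::png(png_path, width = 700, height = 450)
    graphics::hist(a$pm25, breaks = seq(0, max(a$pm25) + 5, by = 5),
                   main = "Two-day mean PM2.5 exposure", xlab = "ug/m3")
    grDevices::dev.off()
    lines <- c(lines, "## Exposure histogram", "",
               "![exposure histogram](exposure_hist.png)", "")
    lines <- c(lines, "## Mismatch quadrants", "")
    qt <- table(a$quadrant)
    for (nm in names(qt)) lines <- c(lines, sprintf("- %s: %d", nm, qt[[nm]]))
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "_participants.csv missing: participant sections skipped_", "")
  }
  efile <- file.path(run_dir, "exposures.csv")
  if (file.exists(efile)) {
    e <- utils::read.csv(efile)
    lines <- c(lines, "## RB vs MB environmental factors", "",
               "Mean density by method and factor (all rings pooled):", "")
    ag <- stats::aggregate(value ~ method + factor, data = e, FUN = mean)
    for (i in seq_len(nrow(ag)))
      lines <- c(lines, sprintf("- %s %s: %.4g", ag$method[i], ag$factor[i], ag$value[i]))
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "_exposures.csv missing: RB/MB section skipped_", "")
  }
  lfile <- file.path(run_dir, "linear_models.csv")
  if (file.exists(lfile)) {
    lines <- c(lines, "## Linear perception models", "",
               "See `linear_models.csv` for the full coefficient table.", "")
  } else {
    lines <- c(lines, "_linear_models.csv missing: model section skipped_", "")
  }
  mfile <- file.path(run_dir, "multinomial_models.csv")
  if (file.exists(mfile)) {
    lines <- c(lines, "## Multinomial mismatch models", "",
               "See `multinomial_models.csv` (reference group: high-high).", "")
  } else {
    lines <- c(lines, "_multinomial_models.csv missing: mismatch-model section skipped_", "")
  }
  writeLines(lines, rp)
  invisible(rp)
}
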