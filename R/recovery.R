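# Ground-truth recovery experiments: simulated cohorts with known
# coefficients, confidence-interval coverage of the linear and multinomial
# fits, ring-selection recovery for the sensitivity scan, and the
# neighborhood-effect-averaging diagnostic.

#' Simulate a regression cohort with known linear coefficients
#'
#' Draws sociodemographic-like covariates (standard normal by default) and a
#' response `y = X beta + N(0, sigma)`; the returned truth enables coverage
#' checks of the OLS confidence intervals.
#'
#' @param n cohort size.
#' @param beta named coefficient vector; an `intercept` element is the
#'   intercept, other names become covariate columns.
#' @param sigma residual standard deviation.
#' @param seed integer seed.
#' @return list `data` (data.frame with `y` and covariates), `beta`.
#' @export
simulate_linear_cohort <- function(n, beta, sigma = 1, seed = 1L) {
  with_seed(seed, {
    covs <- setdiff(names(beta), "intercept")
    X <- matrix(stats::rnorm(n * length(covs)), n,
                dimnames = list(NULL, covs))
    b0 <- if ("intercept" %in% names(beta)) beta[["intercept"]] else 0
    y <- b0 + drop(X %*% beta[covs]) + stats::rnorm(n, 0, sigma)
    list(data = data.frame(y = y, X), beta = beta)
  })
}

#' Coverage of 95% OLS confidence intervals under the true model
#'
#' Repeatedly simulates cohorts with [simulate_linear_cohort()], fits the
#' perception model, and reports the fraction of (replicate, coefficient)
#' pairs whose 95% confidence interval covers the truth. Nominal coverage
#' is 0.95.
#'
#' @param n cohort size per replicate.
#' @param beta,sigma as in [simulate_linear_cohort()].
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return list `coverage` (overall fraction), `per_coefficient`.
#' @export
recovery_experiment_linear <- function(n = 500, beta = c(intercept = 3, x1 = 0.5,
                                                         x2 = -0.3, x3 = 0.2),
                                       sigma = 1, n_rep = 100, seed = 1L) {
  covs <- setdiff(names(beta), "intercept")
  fml <- stats::as.formula(paste("y ~", paste(covs, collapse = " + ")))
  truth <- c(beta[["intercept"]], beta[covs])
  hits <- matrix(NA, n_rep, length(truth))
  for (r in seq_len(n_rep)) {
    sim <- simulate_linear_cohort(n, beta, sigma, seed = sub_seed(seed, r))
    f <- fit_linear_perception(fml, sim$data)
    ci <- stats::confint(f$fit, level = 0.95)
    hits[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  list(coverage = mean(hits),
       per_coefficient = stats::setNames(colMeans(hits), c("intercept", covs)))
}

#' Simulate a mismatch cohort with known multinomial coefficients
#'
#' Covariates are drawn as `age ~ U(18, 64)`, `female ~ Bernoulli(0.55)`,
#' and any additional standard-normal columns named in the coefficient
#' matrix; quadrant labels are drawn from the true multinomial logit with
#' the given class-contrast coefficients (reference class `high-high`).
#'
#' @param n cohort size.
#' @param B coefficient matrix: one row per non-reference class (rownames
#'   from the quadrant labels), columns `intercept` plus covariate names.
#' @param seed integer seed.
#' @return list `data` (data.frame `quadrant` + covariates), `B`.
#' @export
simulate_mismatch_cohort <- function(n,
                                     B = rbind(
                                       `low-low`  = c(intercept = 0.4, age = -0.02, female = 0.2),
                                       `low-high` = c(intercept = -0.3, age = -0.01, female = -0.3),
                                       `high-low` = c(intercept = -1.5, age = 0.05, female = 0.1)),
                                     seed = 1L) {
  with_seed(seed, {
    covs <- setdiff(colnames(B), "intercept")
    dat <- data.frame(row.names = seq_len(n))
    for (nm in covs) {
      dat[[nm]] <- switch(nm,
                          age = stats::runif(n, 18, 64),
                          female = stats::rbinom(n, 1, 0.55),
                          stats::rnorm(n))
    }
    X <- cbind(intercept = 1, as.matrix(dat[, covs, drop = FALSE]))
    Eta <- X %*% t(B[, colnames(X), drop = FALSE])
    P <- cbind(`high-high` = 1, exp(Eta))
    P <- P / rowSums(P)
    lv <- colnames(P)
    ix <- apply(P, 1, function(p) sample.int(length(p), 1, prob = p))
    dat$quadrant <- factor(lv[ix], levels = c("low-low", "high-high",
                                              "low-high", "high-low"))
    list(data = dat, B = B)
  })
}

#' Coverage of 95% Wald intervals of the multinomial mismatch model
#'
#' @param n cohort size per replicate.
#' @param B true coefficient matrix (see [simulate_mismatch_cohort()]).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return list `coverage` (overall fraction over replicates, classes and
#'   coefficients), `per_coefficient` (matrix).
#' @export
recovery_experiment_multinomial <- function(n = 800,
                                            B = rbind(
                                              `low-low`  = c(intercept = 0.4, age = -0.02, female = 0.2),
                                              `low-high` = c(intercept = -0.3, age = -0.01, female = -0.3),
                                              `high-low` = c(intercept = -1.5, age = 0.05, female = 0.1)),
                                            n_rep = 100, seed = 1L) {
  covs <- setdiff(colnames(B), "intercept")
  fml <- stats::as.formula(paste("quadrant ~", paste(covs, collapse = " + ")))
  hit_sum <- 0; hit_n <- 0
  per <- matrix(0, nrow(B), ncol(B), dimnames = dimnames(B))
  used <- 0
  for (r in seq_len(n_rep)) {
    sim <- simulate_mismatch_cohort(n, B, seed = sub_seed(seed, 5000 + r))
    fit <- tryCatch(fit_multinomial_mismatch(fml, sim$data),
                    error = function(e) NULL)
    if (is.null(fit)) next
    used <- used + 1
    est <- fit$coefficients; se <- fit$se
    colnames(est)[colnames(est) == "(Intercept)"] <- "intercept"
    colnames(se)[colnames(se) == "(Intercept)"] <- "intercept"
    tr <- B[rownames(est), colnames(est)]
    hit <- tr >= est - 1.96 * se & tr <= est + 1.96 * se
    per <- per + hit[rownames(B), colnames(B)]
    hit_sum <- hit_sum + sum(hit); hit_n <- hit_n + length(hit)
  }
  list(coverage = hit_sum / hit_n, per_coefficient = per / used,
       replicates_used = used)
}

#' Ring-selection recovery for the sensitivity scan
#'
#' Builds cohorts in which only one ring's mobility-based green density
#' enters the true perception model, runs the per-ring [sensitivity_scan()],
#' and reports how often the scan selects the true ring. Per replicate a
#' fresh synthetic world is generated; each participant contributes a short
#' random-walk activity trace from which per-ring MB green densities are
#' computed, the response is `b * density_true_ring + noise` with the noise
#' sd set to half the signal sd (a strong but not degenerate design), and
#' the scan picks the ring with the highest adjusted R-squared.
#'
#' @param true_ring index of the ring carrying the signal (default 4, the
#'   150-200 m ring).
#' @param n participants per replicate.
#' @param n_rep replicates.
#' @param seed integer seed.
#' @return list `hit_rate`, `selected` (integer vector of selected ring
#'   indices per replicate).
#' @export
scan_recovery_experiment <- function(true_ring = 4L, n = 80, n_rep = 25, seed = 1L) {
  fam <- ring_family()
  selected <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- world_config(extent_m = c(1500, 1500), n_participants = n,
                        seed = sub_seed(seed, 7000 + r),
                        n_green_patches = 10, n_open_patches = 3, n_corridors = 2)
    ras <- generate_landuse_raster(cfg)
    roles <- cfg$class_roles["green"]
    dens <- with_seed(sub_seed(seed, 7500 + r), {
      t(vapply(seq_len(n), function(i) {
        # short random-walk activity trace, kept 500 m inside the extent
        start <- stats::runif(2, 520, cfg$extent_m - 520)
        steps <- matrix(stats::rnorm(2 * 20, 0, 60), ncol = 2)
        pts <- sweep(apply(steps, 2, cumsum), 2, start, "+")
        pts <- pmin(pmax(pts, 505), cfg$extent_m[1] - 505)
        mb <- mb_exposures(data.frame(x = pts[, 1], y = pts[, 2]),
                           fam, ras, roles)
        mb$value[mb$factor == "green"]
      }, numeric(nrow(fam))))
    })
    sig <- 5 * dens[, true_ring]
    noise_sd <- max(stats::sd(sig), 1e-6) / 2
    y <- with_seed(sub_seed(seed, 7900 + r),
                   sig + stats::rnorm(n, 0, noise_sd))
    designs <- lapply(seq_len(nrow(fam)), function(k) {
      list(method = "MB", inner_m = fam$inner_m[k], outer_m = fam$outer_m[k],
           data = data.frame(y = y, green = dens[, k]))
    })
    sc <- sensitivity_scan(designs, y ~ green)
    selected[r] <- which(fam$outer_m == sc$selected$outer_m[1])
  }
  list(hit_rate = mean(selected == true_ring), selected = selected)
}

#' Designed commuter cohort: RB vs MB contrast and averaging
#'
#' Generates a cohort whose members live in residential zones but commute
#' to workplaces inside a central transport district (a disc of
#' transportation land use stamped at the city center, emulating a
#' road-and-transit-dominated employment core), so mobility-based transport
#' exposure systematically exceeds the residence-based one. Used to
#' exercise the RB-vs-MB Mann-Whitney comparison and the
#' neighborhood-effect-averaging diagnostic. Minute-level activity is
#' summarised as a home/workplace/path mixture (60/25/15% of minutes)
#' rather than a full 1-second trajectory, which preserves the contrast at
#' a fraction of the cost.
#'
#' @param config a [world_config()].
#' @param spec a [buffer_spec()] at which the per-factor densities are
#'   reported (default the 100-150 m ring).
#' @param hub_radius_m radius of the central transport district (default
#'   250 m).
#' @return data.frame, one row per participant: `participant_id`,
#'   `rb_transport`, `mb_transport`, `rb_green`, `mb_green`.
#' @export
simulate_commuter_cohort <- function(config, spec = buffer_spec(100, 150),
                                     hub_radius_m = 250) {
  ras <- generate_landuse_raster(config)
  ctr <- config$extent_m / 2
  ras$codes <- stamp_disc(ras$codes, ras$cell_size_m, ras$origin,
                          ctr[1], ctr[2], hub_radius_m,
                          config$class_roles$transport[1])
  parts <- generate_participants(config)
  fam <- data.frame(inner_m = spec$inner_m, outer_m = spec$outer_m)
  roles <- config$class_roles[c("transport", "green")]
  with_seed(sub_seed(config$seed, 606L), {
    rows <- lapply(seq_len(nrow(parts)), function(i) {
      home <- c(parts$home_x[i], parts$home_y[i])
      th <- stats::runif(1, 0, 2 * pi)
      rr <- hub_radius_m * 0.5 * sqrt(stats::runif(1))
      work <- ctr + rr * c(cos(th), sin(th))
      mid <- (home + work) / 2
      n_home <- 60; n_work <- 25; n_path <- 15
      locs <- data.frame(
        x = c(rep(home[1], n_home), rep(work[1], n_work), rep(mid[1], n_path)),
        y = c(rep(home[2], n_home), rep(work[2], n_work), rep(mid[2], n_path)))
      rb <- rb_exposures(home, fam, ras, roles)
      mb <- mb_exposures(locs, fam, ras, roles)
      data.frame(participant_id = parts$participant_id[i],
                 rb_transport = rb$value[rb$factor == "transport"],
                 mb_transport = mb$value[mb$factor == "transport"],
                 rb_green = rb$value[rb$factor == "green"],
                 mb_green = mb$value[mb$factor == "green"])
    })
    do.call(rbind, rows)
  })
}

#' Neighborhood-effect-averaging slope
#'
#' Regresses the MB-minus-RB exposure difference on the RB exposure. A
#' negative slope is the averaging signature: mobility pulls individually
#' extreme residential exposures toward the population mean.
#'
#' @param rb,mb numeric per-participant exposures.
#' @return the OLS slope.
#' @export
neap_slope <- function(rb, mb) {
  unname(stats::coef(stats::lm((mb - rb) ~ rb))[2])
}
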