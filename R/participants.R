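#' Default stratified quota table for the synthetic cohort
#'
#' Joint quota proportions per community over gender x age band x income
#' group x employment status, built as the product of community-level
#' marginals that mirror a two-community stratified quota survey (a dense
#' old-urban community "A" and a newer residential-town community "B").
#' Proportions sum to 1 within each community.
#'
#' @return data.frame with columns `community`, `female`, `age_band`,
#'   `income4`, `employment`, `proportion`.
#' @export
default_quotas <- function() {
  marg <- list(
    A = list(female = c(`0` = 0.438, `1` = 0.562),
             age_band = c(`18-24` = 0.152, `25-44` = 0.476, `45-64` = 0.372),
             income4 = c(`1` = 0.114, `2` = 0.352, `3` = 0.314, `4` = 0.220),
             employment = c(employed = 0.781, student = 0.086, unemployed = 0.133)),
    B = list(female = c(`0` = 0.467, `1` = 0.533),
             age_band = c(`18-24` = 0.219, `25-44` = 0.486, `45-64` = 0.295),
             income4 = c(`1` = 0.067, `2` = 0.229, `3` = 0.429, `4` = 0.275),
             employment = c(employed = 0.733, student = 0.133, unemployed = 0.134))
  )
  out <- do.call(rbind, lapply(names(marg), function(comm) {
    m <- marg[[comm]]
    g <- expand.grid(female = names(m$female), age_band = names(m$age_band),
                     income4 = names(m$income4), employment = names(m$employment),
                     stringsAsFactors = FALSE)
    p <- m$female[g$female] * m$age_band[g$age_band] *
      m$income4[g$income4] * m$employment[g$employment]
    data.frame(community = comm, g, proportion = as.numeric(p / sum(p)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Largest-remainder rounding of n * props to integer counts summing to n.
# Ties go to the earlier stratum, making the rule deterministic.
largest_remainder <- function(props, n) {
  t <- props * n
  k <- floor(t)
  short <- n - sum(k)
  if (short > 0) {
    ord <- order(-(t - k), seq_along(t))
    k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1
  }
  as.integer(k)
}

community_zones <- function(config) {
  W <- config$extent_m[1]; H <- config$extent_m[2]
  r <- 0.12 * min(W, H)
  list(A = list(cx = 0.30 * W, cy = 0.50 * H, r = r),
       B = list(cx = 0.70 * W, cy = 0.50 * H, r = r))
}

#' Generate the synthetic participant table
#'
#' Realises the stratified quota design: per community, stratum counts are
#' the quota proportions times the community sample size rounded by the
#' largest-remainder method (deterministic, sums preserved). Each participant
#' receives sociodemographics consistent with their stratum (age uniform
#' within band, detailed 7-level income drawn within the 4-level quota
#' group), plus education (1-6), marital status, home ownership, family
#' size, living-space category, weekly exercise days, and a home location
#' inside their community's residential zone.
#'
#' @param config a [world_config()]; `n_participants` is split equally over
#'   the communities appearing in `quotas` (largest remainder on equal
#'   shares when not divisible).
#' @param quotas data.frame with columns `community`, `proportion` and any
#'   subset of the stratum columns `female`, `age_band`, `income4`,
#'   `employment`; proportions must sum to 1 within each community.
#' @return data.frame (one row per participant) with columns
#'   `participant_id`, `community`, `female` (0/1), `age`, `income` (1-7),
#'   `education` (1-6), `employment`, `marital`, `ownership`, `family_size`,
#'   `living_space`, `exercise_days`, `home_x`, `home_y`.
#' @export
generate_participants <- function(config, quotas = default_quotas()) {
  stopifnot(inherits(config, "world_config"))
  if (!all(c("community", "proportion") %in% names(quotas)))
    stopf("quotas must have columns 'community' and 'proportion'")
  comms <- unique(quotas$community)
  for (comm in comms) {
    s <- sum(quotas$proportion[quotas$community == comm])
    if (abs(s - 1) > 1e-6)
      stopf("quota proportions for community %s sum to %.6f, not 1", comm, s)
  }
  n_comm <- largest_remainder(rep(1 / length(comms), length(comms)),
                              config$n_participants)
  zones <- community_zones(config)
  strat_cols <- intersect(c("female", "age_band", "income4", "employment"),
                          names(quotas))

  with_seed(sub_seed(config$seed, 202L), {
    rows <- list()
    for (ci in seq_along(comms)) {
      comm <- comms[ci]
      q <- quotas[quotas$community == comm, , drop = FALSE]
      counts <- largest_remainder(q$proportion, n_comm[ci])
      idx <- rep(seq_len(nrow(q)), counts)
      df <- q[idx, strat_cols, drop = FALSE]
      df$community <- comm
      rows[[ci]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    n <- nrow(out)
    out$participant_id <- seq_len(n)

    # fill stratum fields absent from the quota table
    if (is.null(out$female))
      out$female <- sample(c(0L, 1L), n, TRUE, c(0.45, 0.55))
    out$female <- as.integer(as.character(out$female))
    if (is.null(out$age_band))
      out$age_band <- sample(c("18-24", "25-44", "45-64"), n, TRUE,
                             c(0.19, 0.48, 0.33))
    if (is.null(out$income4))
      out$income4 <- sample(as.character(1:4), n, TRUE, c(0.09, 0.29, 0.37, 0.25))
    out$income4 <- as.integer(as.character(out$income4))
    if (is.null(out$employment))
      out$employment <- sample(c("employed", "student", "unemployed"), n, TRUE,
                               c(0.757, 0.110, 0.133))

    # age uniform within band
    lo <- c(`18-24` = 18, `25-44` = 25, `45-64` = 45)[out$age_band]
    hi <- c(`18-24` = 24, `25-44` = 44, `45-64` = 64)[out$age_band]
    out$age <- as.integer(lo + floor(runif(n) * (hi - lo + 1)))

    # detailed 7-level income within the 4-level quota group
    out$income <- out$income4
    g3 <- out$income4 == 3L
    out$income[g3] <- sample(c(3L, 4L), sum(g3), TRUE, c(0.5, 0.5))
    g4 <- out$income4 == 4L
    out$income[g4] <- sample(c(5L, 6L, 7L), sum(g4), TRUE, c(0.6, 0.25, 0.15))

    out$education <- sample(1:6, n, TRUE,
                            c(0.024, 0.338, 0.086, 0.038, 0.400, 0.114))
    out$marital <- sample(c("never", "married", "divorced", "widowed"), n, TRUE,
                          c(0.529, 0.367, 0.081, 0.023))
    out$ownership <- sample(c("rent", "own_no_mortgage", "own_mortgage"), n, TRUE,
                            c(0.55, 0.20, 0.25))
    out$family_size <- pmin(6L, 1L + stats::rpois(n, 1.6))
    out$living_space <- sample(1:5, n, TRUE, c(0.35, 0.30, 0.20, 0.10, 0.05))
    out$exercise_days <- pmin(7L, stats::rpois(n, 1.8))

    # home locations: uniform in the community's residential disc
    z <- zones[match(out$community, names(zones))]
    th <- runif(n, 0, 2 * pi); rr <- sqrt(runif(n))
    out$home_x <- vapply(seq_len(n), function(i) z[[i]]$cx + z[[i]]$r * rr[i] * cos(th[i]), 0)
    out$home_y <- vapply(seq_len(n), function(i) z[[i]]$cy + z[[i]]$r * rr[i] * sin(th[i]), 0)

    cols <- c("participant_id", "community", "female", "age", "age_band",
              "income", "income4", "education", "employment", "marital",
              "ownership", "family_size", "living_space", "exercise_days",
              "home_x", "home_y")
    out[, cols]
  })
}
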