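# Latent-variable questionnaire generator: perception item, mental-health
# and respiratory instruments with known ground-truth structure.

clamp_item <- function(x) pmin(6L, pmax(1L, as.integer(round(x))))

#' Generate questionnaire responses from the ground-truth model
#'
#' Mental-health (4 items) and respiratory (3 items) responses come from
#' one common factor each: `item = round(3.5 + loading * z + noise)` clamped
#' to 1..6, with `z ~ N(0, 1)` per participant, so the composites have high
#' internal consistency by construction (with zero item noise the items are
#' perfectly correlated and Cronbach's alpha is 1).
#'
#' The perception item is an ordered-latent-variable response:
#' `eta = intercept + sum_j beta_j x_j + N(0, latent_noise_sd)` with the
#' coefficients of [true_model()], discretised by the five cutpoints to a
#' level in 1..6. Coefficient names must match columns of the augmented
#' participant table (`mental_health` refers to the composite score, which
#' is generated first and then enters the linear predictor).
#'
#' @param participants participant table (must contain every covariate named
#'   in the perception coefficients except `intercept` and `mental_health`).
#' @param tm a [true_model()].
#' @param seed integer seed.
#' @return `participants` with added columns `mh1..mh4`, `resp1..resp3`,
#'   `mental_health`, `respiratory`, `perception` (1-6).
#' @export
generate_questionnaire <- function(participants, tm, seed = 1L) {
  n <- nrow(participants)
  with_seed(seed, {
    zm <- stats::rnorm(n)
    for (j in 1:4)
      participants[[paste0("mh", j)]] <-
        clamp_item(3.5 + tm$mh_loading * zm + stats::rnorm(n, 0, tm$item_noise_sd))
    zr <- stats::rnorm(n)
    for (j in 1:3)
      participants[[paste0("resp", j)]] <-
        clamp_item(3.5 + tm$mh_loading * zr + stats::rnorm(n, 0, tm$item_noise_sd))
    participants$mental_health <-
      composite_score(participants[, paste0("mh", 1:4)], 4)
    participants$respiratory <-
      composite_score(participants[, paste0("resp", 1:3)], 3)

    b <- tm$perception_coefficients
    eta <- rep(if ("intercept" %in% names(b)) b[["intercept"]] else 0, n)
    for (nm in setdiff(names(b), "intercept")) {
      if (is.null(participants[[nm]]))
        stopf("perception coefficient '%s' has no matching covariate column", nm)
      eta <- eta + b[[nm]] * as.numeric(participants[[nm]])
    }
    eta <- eta + stats::rnorm(n, 0, tm$latent_noise_sd)
    participants$perception <-
      as.integer(1L + findInterval(eta, tm$cutpoints))
    participants
  })
}
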