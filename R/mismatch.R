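# Exposure dichotomisation by exact 1-D 2-means and the four-quadrant
# perception-mismatch classification.

#' Exact one-dimensional 2-means split of exposures
#'
#' Dichotomises exposures into `low` and `high` by 2-means clustering,
#' computed exactly: for k = 2 in one dimension the optimal partition is a
#' contiguous split of the sorted values, so the global minimum of the total
#' within-cluster sum of squares is found by enumerating the n - 1 split
#' points. No random initialisation, hence fully deterministic; ties are
#' broken toward the split with the smaller low cluster. The boundary is
#' reported as a two-interval pair: the largest exposure labelled
#' low (`low_max`) and the smallest labelled high (`high_min`).
#'
#' @param exposures numeric vector (n >= 2, at least two distinct values).
#' @return object of class `exposure_split` with elements `labels` (factor
#'   `low`/`high` in input order), `low_max`, `high_min`, `centroids`,
#'   `withinss`, `n`.
#' @examples
#' s <- kmeans_split(c(1, 2, 10, 11))
#' s$low_max; s$high_min
#' @export
kmeans_split <- function(exposures) {
  x <- as.numeric(exposures)
  if (length(x) < 2L) stopf("need at least 2 exposures")
  if (anyNA(x)) stopf("exposures must not contain NA")
  if (length(unique(x)) < 2L)
    stopf("all exposure values identical: 2-means split is degenerate")
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  m <- seq_len(n - 1L)
  wss_low <- cs2[m] - cs[m]^2 / m
  wss_high <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
  tot <- wss_low + wss_high
  # ties (to numerical tolerance) break toward the smaller low cluster
  tol <- 1e-9 * max(1, max(abs(tot)))
  best <- which(tot <= min(tot) + tol)[1]
  labels_sorted <- rep(c("low", "high"), c(best, n - best))
  labels <- character(n)
  labels[ord] <- labels_sorted
  structure(list(
    labels = factor(labels, levels = c("low", "high")),
    low_max = xs[best],
    high_min = xs[best + 1L],
    centroids = c(low = cs[best] / best, high = (cs[n] - cs[best]) / (n - best)),
    withinss = tot[best],
    n = n
  ), class = "exposure_split")
}

#' @export
print.exposure_split <- function(x, ...) {
  cat(sprintf("<exposure_split> n=%d  low: n=%d (max %.3f)  high: n=%d (min %.3f)\n",
              x$n, sum(x$labels == "low"), x$low_max,
              sum(x$labels == "high"), x$high_min))
  cat(sprintf("  centroids %.3f / %.3f, within-SS %.4g\n",
              x$centroids["low"], x$centroids["high"], x$withinss))
  invisible(x)
}

#' Four-quadrant perception-mismatch classification
#'
#' Crosses dichotomised measured exposure (`low`/`high`) with binarised
#' perceived air quality (`good`/`poor`):
#' low x good -> `low-low` (accurate), high x poor -> `high-high` (accurate),
#' low x poor -> `low-high` (overestimation), high x good -> `high-low`
#' (underestimation). Rows with a missing label are excluded with a message
#' reporting the count.
#'
#' @param exposure_label factor/character `low`/`high`.
#' @param perception_label factor/character `good`/`poor`.
#' @return factor with levels `low-low`, `high-high`, `low-high`,
#'   `high-low` (NA where a label was missing).
#' @export
assign_quadrant <- function(exposure_label, perception_label) {
  e <- as.character(exposure_label)
  p <- as.character(perception_label)
  if (length(e) != length(p)) stopf("label vectors must have equal length")
  bad_e <- !is.na(e) & !e %in% c("low", "high")
  bad_p <- !is.na(p) & !p %in% c("good", "poor")
  if (any(bad_e) || any(bad_p)) stopf("labels must be low/high and good/poor")
  miss <- is.na(e) | is.na(p)
  if (any(miss))
    message(sprintf("assign_quadrant: %d participant(s) excluded for missing labels",
                    sum(miss)))
  out <- rep(NA_character_, length(e))
  ok <- !miss
  out[ok] <- ifelse(e[ok] == "low",
                    ifelse(p[ok] == "good", "low-low", "low-high"),
                    ifelse(p[ok] == "poor", "high-high", "high-low"))
  factor(out, levels = c("low-low", "high-high", "low-high", "high-low"))
}
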