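# Questionnaire scoring and covariate encoding.

#' Composite instrument score
#'
#' Sum of item scores. The mental-health instrument has 4 items (score range
#' 4-24), the respiratory instrument 3 items (range 3-18); items are on a
#' six-point frequency scale (1 never ... 6 always). Missing items
#' invalidate the composite: no imputation.
#'
#' @param items numeric vector (one respondent) or matrix/data.frame (one
#'   row per respondent, one column per item).
#' @param n_items expected item count (4 for mental health, 3 for
#'   respiratory); checked when given.
#' @return integer sum (vector for matrix input).
#' @export
composite_score <- function(items, n_items = NULL) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (!is.null(n_items) && ncol(m) != n_items)
    stopf("expected %d items, got %d", n_items, ncol(m))
  if (anyNA(m)) stopf("missing item response: composite is undefined (no imputation)")
  if (any(m < 1 | m > 6)) stopf("item responses must lie in 1..6")
  s <- as.integer(rowSums(m))
  if (nrow(m) == 1L) s[1] else s
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(var(item_j)) / var(rowsum))`
#' with sample variances (denominator n-1). Undefined when the total score
#' has zero variance.
#'
#' @param item_matrix n x k numeric matrix (n respondents, k >= 2 items).
#' @return alpha (dimensionless, <= 1).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) stopf("need at least 2 respondents and 2 items")
  tot <- rowSums(m)
  vt <- stats::var(tot)
  if (vt <= .Machine$double.eps) stopf("zero total-score variance: alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Binarize the six-point perception item
#'
#' Levels 1-3 ("not at all" / "not serious" / "not very serious") map to
#' `good`; levels 4-6 ("a little serious" / "serious" / "very serious") map
#' to `poor`.
#'
#' @param level integer vector in 1..6.
#' @return factor with levels `good`, `poor`.
#' @export
binarize_perception <- function(level) {
  if (any(!level %in% 1:6)) stopf("perception levels must lie in 1..6")
  factor(ifelse(level <= 3, "good", "poor"), levels = c("good", "poor"))
}

income_brackets <- function() {
  c("<9999" = 1L, "10000-19999" = 2L, "20000-29999" = 3L, "30000-39999" = 4L,
    "40000-59999" = 5L, "60000-79999" = 6L, ">80000" = 7L)
}

education_levels <- function() {
  c("Primary and below" = 1L, "Secondary" = 2L,
    "Post-secondary: Diploma/Certificate" = 3L,
    "Post-secondary: Sub-degree course" = 4L,
    "Post-secondary: Degree course" = 5L, "Master and above" = 6L)
}

#' Encode raw sociodemographics into model-ready covariates
#'
#' Income is coded 1-7 over the monthly household-income brackets (treated
#' as continuous downstream), education 1-6, gender as a `female` indicator
#' (reference: male), employment as `student`/`unemployed` indicators
#' (reference: employed), marital status as `divorced`/`married`/`widowed`
#' indicators (reference: never married), home ownership as
#' `own_no_mortgage`/`own_mortgage` indicators (reference: renter), and
#' community as an indicator for the second community (reference: community
#' A, the dense-urban one). Numeric codes already in range pass through.
#'
#' @param raw participant data.frame (as from [generate_participants()], or
#'   the same columns with raw labels: `income` may be a bracket string,
#'   `education` a level label).
#' @return data.frame of numeric model covariates.
#' @export
encode_covariates <- function(raw) {
  n <- nrow(raw)
  enc <- data.frame(participant_id = raw$participant_id)
  # income
  if (is.numeric(raw$income)) {
    if (any(!raw$income %in% 1:7)) stopf("numeric income codes must lie in 1..7")
    enc$income <- as.integer(raw$income)
  } else {
    code <- income_brackets()[as.character(raw$income)]
    if (anyNA(code)) stopf("unknown income bracket: %s",
                           paste(unique(raw$income[is.na(code)]), collapse = ", "))
    enc$income <- unname(code)
  }
  # education
  if (is.numeric(raw$education)) {
    if (any(!raw$education %in% 1:6)) stopf("numeric education codes must lie in 1..6")
    enc$education <- as.integer(raw$education)
  } else {
    code <- education_levels()[as.character(raw$education)]
    if (anyNA(code)) stopf("unknown education level: %s",
                           paste(unique(raw$education[is.na(code)]), collapse = ", "))
    enc$education <- unname(code)
  }
  enc$female <- as.integer(raw$female)
  if (any(!enc$female %in% 0:1)) stopf("female must be coded 0/1")
  enc$age <- as.numeric(raw$age)
  comm <- as.character(raw$community)
  ref_comm <- sort(unique(comm))[1]
  enc$community_b <- as.integer(comm != ref_comm)
  emp <- as.character(raw$employment)
  bad <- setdiff(unique(emp), c("employed", "student", "unemployed"))
  if (length(bad)) stopf("unknown employment category: %s", paste(bad, collapse = ", "))
  enc$student <- as.integer(emp == "student")
  enc$unemployed <- as.integer(emp == "unemployed")
  mar <- as.character(raw$marital)
  bad <- setdiff(unique(mar), c("never", "divorced", "married", "widowed", "separated"))
  if (length(bad)) stopf("unknown marital category: %s", paste(bad, collapse = ", "))
  enc$divorced <- as.integer(mar %in% c("divorced", "separated"))
  enc$married <- as.integer(mar == "married")
  enc$widowed <- as.integer(mar == "widowed")
  own <- as.character(raw$ownership)
  bad <- setdiff(unique(own), c("rent", "own_no_mortgage", "own_mortgage"))
  if (length(bad)) stopf("unknown ownership category: %s", paste(bad, collapse = ", "))
  enc$own_no_mortgage <- as.integer(own == "own_no_mortgage")
  enc$own_mortgage <- as.integer(own == "own_mortgage")
  for (col in c("family_size", "living_space", "exercise_days")) {
    if (!is.null(raw[[col]])) enc[[col]] <- as.numeric(raw[[col]])
  }
  enc
}
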