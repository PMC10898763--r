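# Linear perception models, buffer-distance sensitivity scan, RB-vs-MB
# group comparisons and collinearity diagnostics.

#' Linear model of perceived air pollution
#'
#' Ordinary least squares of the six-point perception item on exposure,
#' sociodemographic and environmental covariates, as used when the
#' perception response is close enough to normal for a linear treatment (a
#' Shapiro-Wilk statistic on the response is recorded alongside, not used
#' as a gate). An ordered-logit variant is available via `engine =
#' "ordered_logit"` for sensitivity, but OLS is the default and the
#' documented analysis path.
#'
#' @param formula model formula (e.g. `perception ~ pm25 + female + ...`).
#' @param data data.frame.
#' @param engine `"ols"` (default) or `"ordered_logit"` (proportional-odds
#'   fit via [MASS::polr()], reported for sensitivity only).
#' @return object of class `perception_fit`: the `lm` fit plus `r2`,
#'   `adj_r2`, `f_p` (overall F-test p), `shapiro_p`, `n`.
#' @export
fit_linear_perception <- function(formula, data, engine = c("ols", "ordered_logit")) {
  engine <- match.arg(engine)
  if (engine == "ordered_logit") {
    if (!requireNamespace("MASS", quietly = TRUE))
      stopf("the ordered-logit engine needs the MASS package")
    mf <- stats::model.frame(formula, data)
    dat <- data
    dat$.y <- stats::model.response(mf)
    fit <- MASS::polr(stats::update(formula, ordered(factor(.y)) ~ .),
                      data = dat, Hess = TRUE)
    return(structure(list(fit = fit, engine = "ordered_logit",
                          n = nrow(mf)), class = "perception_fit"))
  }
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("singular design: collinear column(s) %s", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  n <- stats::nobs(fit)
  y <- stats::model.response(stats::model.frame(fit))
  sh <- if (length(unique(y)) > 2 && n >= 3 && n <= 5000)
    tryCatch(stats::shapiro.test(y)$p.value, error = function(e) NA_real_)
  else NA_real_
  fp <- if (!is.null(sm$fstatistic))
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  else NA_real_
  structure(list(fit = fit, engine = "ols", r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, f_p = fp, shapiro_p = sh, n = n),
            class = "perception_fit")
}

#' @export
print.perception_fit <- function(x, ...) {
  if (x$engine == "ordered_logit") {
    cat("<perception_fit> ordered logit (sensitivity engine)\n")
    print(x$fit)
    return(invisible(x))
  }
  cat(sprintf("<perception_fit> OLS, n=%d, R2 %.3f (adj %.3f), model p %.4g\n",
              x$n, x$r2, x$adj_r2, x$f_p))
  invisible(x)
}

#' @export
coef.perception_fit <- function(object, ...) stats::coef(object$fit)

#' @export
summary.perception_fit <- function(object, ...) summary(object$fit)

#' @export
predict.perception_fit <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.perception_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' Buffer-distance sensitivity scan
#'
#' Fits the perception model once per (method, ring buffer) design and
#' tabulates explanatory power, selecting per method the buffer with the
#' highest adjusted R-squared (the fixed, documented selector; plain
#' R-squared is also emitted). Ties break to the smallest outer radius. A
#' design whose fit fails is recorded as missing and the scan continues.
#' The scan result does not depend on the order of the designs.
#'
#' @param designs list of entries, each a list with `method`, `inner_m`,
#'   `outer_m`, `data` (a data.frame for [fit_linear_perception()]).
#' @param formula model formula applied to every design.
#' @param selector `"adj_r2"` (default) or `"r2"`.
#' @return object of class `sensitivity_scan`: `table` (one row per design,
#'   columns `method`, `inner_m`, `outer_m`, `r2`, `adj_r2`, `model_p`) and
#'   `selected` (one row per method).
#' @export
sensitivity_scan <- function(designs, formula, selector = c("adj_r2", "r2")) {
  selector <- match.arg(selector)
  rows <- lapply(designs, function(d) {
    res <- tryCatch({
      f <- fit_linear_perception(formula, d$data)
      data.frame(method = d$method, inner_m = d$inner_m, outer_m = d$outer_m,
                 r2 = f$r2, adj_r2 = f$adj_r2, model_p = f$f_p)
    }, error = function(e)
      data.frame(method = d$method, inner_m = d$inner_m, outer_m = d$outer_m,
                 r2 = NA_real_, adj_r2 = NA_real_, model_p = NA_real_))
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$method, tab$outer_m), , drop = FALSE]
  rownames(tab) <- NULL
  sel <- do.call(rbind, lapply(split(tab, tab$method), function(g) {
    crit <- g[[selector]]
    if (all(is.na(crit))) return(g[0, ])
    g <- g[order(-crit, g$outer_m, na.last = TRUE), , drop = FALSE]
    g[1, ]
  }))
  rownames(sel) <- NULL
  structure(list(table = tab, selected = sel, selector = selector),
            class = "sensitivity_scan")
}

#' @export
print.sensitivity_scan <- function(x, ...) {
  cat(sprintf("<sensitivity_scan> %d designs, selector %s\n", nrow(x$table), x$selector))
  cat("selected per method:\n")
  print(x$selected, digits = 4)
  invisible(x)
}

#' Mann-Whitney U comparison of RB and MB measurements
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of whether
#' residence-based and mobility-based measurements of an environmental
#' factor differ in distribution. Exact enumeration when both samples have
#' fewer than 20 untied values; the tie-corrected normal approximation
#' otherwise.
#'
#' @param values_rb,values_mb numeric samples.
#' @return list with `U` (statistic of the first sample), `p_value`,
#'   `method`.
#' @export
compare_rb_mb <- function(values_rb, values_mb) {
  if (!length(values_rb) || !length(values_mb)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(values_rb, values_mb)) > 0
  exact <- length(values_rb) < 20 && length(values_mb) < 20 && !ties
  ht <- suppressWarnings(stats::wilcox.test(values_rb, values_mb,
                                            exact = exact, correct = FALSE))
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' One-way ANOVA of exposure across groups, with pre-checks
#'
#' Records per-group Shapiro-Wilk normality p-values and Levene's
#' homogeneity-of-variance test before the one-way ANOVA F test. Pre-check
#' failures are flagged in the result but do not block the ANOVA (they are
#' reported alongside). Groups with fewer than 2 observations are excluded
#' with a warning.
#'
#' @param exposures numeric vector.
#' @param grouping factor of the same length.
#' @return object of class `group_anova`: `f`, `p_value`, `shapiro`
#'   (per-group p), `levene_p`, `groups`, `precheck_ok`.
#' @export
group_anova <- function(exposures, grouping) {
  g <- factor(grouping)
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warnf("excluding group(s) with n < 2: %s", paste(small, collapse = ", "))
    keep <- !g %in% small
    exposures <- exposures[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stopf("need at least 2 groups with n >= 2")
  shapiro <- vapply(levels(g), function(lv) {
    x <- exposures[g == lv]
    if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
  }, 0)
  lev <- car::leveneTest(exposures ~ g)
  levene_p <- lev[["Pr(>F)"]][1]
  av <- summary(stats::aov(exposures ~ g))[[1]]
  structure(list(f = av[["F value"]][1], p_value = av[["Pr(>F)"]][1],
                 shapiro = shapiro, levene_p = levene_p,
                 groups = table(g),
                 precheck_ok = all(c(shapiro, levene_p) > 0.05, na.rm = TRUE)),
            class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat(sprintf("<group_anova> F = %.3f, p = %.4g (%d groups)\n",
              x$f, x$p_value, length(x$groups)))
  cat(sprintf("  pre-checks: Levene p = %.3g; Shapiro-Wilk min p = %.3g%s\n",
              x$levene_p, suppressWarnings(min(x$shapiro, na.rm = TRUE)),
              if (x$precheck_ok) "" else "  [flagged]"))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing covariate j
#' on all the others. VIF at or above 10 is flagged as problematic
#' multicollinearity; perfect collinearity yields an infinite VIF reported
#' as a flag rather than an error.
#'
#' @param design numeric data.frame or matrix of covariates (no response,
#'   no intercept column).
#' @return data.frame `covariate`, `vif`, `flag`.
#' @export
vif_diagnostics <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2L) stopf("need at least 2 covariates")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(covariate = colnames(X), vif = vif, flag = vif >= 10)
}
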