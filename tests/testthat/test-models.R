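# Statistical layer: linear perception model, Newton multinomial fit (with
# nnet as the independent oracle), sensitivity scan, Mann-Whitney, ANOVA
# pre-checks, and VIF.

test_that("OLS perception fit: exact fit, null design, and singularity error", {
  d <- data.frame(x = 1:20)
  d$y <- 2 + 3 * d$x
  f <- suppressWarnings(fit_linear_perception(y ~ x, d))
  expect_equal(f$r2, 1)
  expect_equal(unname(coef(f)), c(2, 3))

  set.seed(4)
  d2 <- data.frame(y = rnorm(5000), x1 = rnorm(5000), x2 = rnorm(5000))
  f2 <- fit_linear_perception(y ~ x1 + x2, d2)
  expect_lt(abs(f2$adj_r2), 0.02)

  d3 <- data.frame(y = rnorm(10), a = 1:10)
  d3$b <- d3$a * 2
  expect_error(fit_linear_perception(y ~ a + b, d3), "collinear.*b")
})

test_that("adjusted R2 uses the standard small-sample correction", {
  set.seed(8)
  d <- data.frame(y = rnorm(40), x1 = rnorm(40), x2 = rnorm(40), x3 = rnorm(40))
  f <- fit_linear_perception(y ~ x1 + x2 + x3, d)
  n <- 40; p <- 3
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * (n - 1) / (n - p - 1))
})

test_that("Newton multinomial fit agrees with nnet::multinom", {
  skip_if_not_installed("nnet")
  sim <- simulate_mismatch_cohort(600, seed = 14)
  fit <- fit_multinomial_mismatch(quadrant ~ age + female, sim$data)
  nn <- nnet::multinom(quadrant ~ age + female,
                       data = transform(sim$data,
                                        quadrant = relevel(sim$data$quadrant,
                                                           "high-high")),
                       trace = FALSE, reltol = 1e-12, maxit = 500)
  cf_nn <- coef(nn)
  cf <- coef(fit)[rownames(cf_nn), colnames(cf_nn)]
  expect_equal(unname(cf), unname(cf_nn), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(nn)), tolerance = 1e-6)
})

test_that("intercept-only multinomial reproduces class shares to 1e-8", {
  sim <- simulate_mismatch_cohort(400, seed = 5)
  fit <- fit_multinomial_mismatch(quadrant ~ 1, sim$data)
  shares <- as.numeric(table(sim$data$quadrant)[fit$levels]) / 400
  expect_equal(unname(fit$fitted[1, ]), shares, tolerance = 1e-8)
})

test_that("pseudo-R2 values are coherent (Cox-Snell/Nagelkerke in [0,1), McFadden <= Nagelkerke)", {
  sim <- simulate_mismatch_cohort(500, seed = 6)
  fit <- fit_multinomial_mismatch(quadrant ~ age + female, sim$data)
  pr <- fit$pseudo_r2
  expect_true(pr["cox_snell"] >= 0 && pr["cox_snell"] < 1)
  expect_true(pr["nagelkerke"] >= 0 && pr["nagelkerke"] < 1)
  expect_gte(pr["nagelkerke"], pr["cox_snell"])
  expect_lte(pr["mcfadden"], pr["nagelkerke"])
})

test_that("changing the reference class transforms contrasts consistently", {
  sim <- simulate_mismatch_cohort(700, seed = 8)
  f1 <- fit_multinomial_mismatch(quadrant ~ age + female, sim$data,
                                 reference = "high-high")
  f2 <- fit_multinomial_mismatch(quadrant ~ age + female, sim$data,
                                 reference = "low-low")
  # beta(k vs newref) = beta(k vs oldref) - beta(newref vs oldref)
  b_new_old <- coef(f1)["low-low", ]
  expect_equal(unname(coef(f2)["high-high", ]), unname(-b_new_old),
               tolerance = 1e-4)
  expect_equal(unname(coef(f2)["high-low", ]),
               unname(coef(f1)["high-low", ] - b_new_old), tolerance = 1e-4)
})

test_that("an empty quadrant class aborts with an instructive error", {
  sim <- simulate_mismatch_cohort(200, seed = 9)
  d <- sim$data[sim$data$quadrant != "high-low", ]
  expect_error(fit_multinomial_mismatch(quadrant ~ age, d,
                                        reference = "high-low"),
               "empty|absent")
})

test_that("sensitivity scan tabulates all designs and breaks ties to the smallest ring", {
  set.seed(10)
  d <- data.frame(y = rnorm(50), g = rnorm(50))
  fam <- ring_family()
  designs <- lapply(seq_len(10), function(k)
    list(method = "MB", inner_m = fam$inner_m[k], outer_m = fam$outer_m[k],
         data = d))
  sc <- sensitivity_scan(designs, y ~ g)
  expect_equal(nrow(sc$table), 10)
  expect_true(all(abs(sc$table$adj_r2 - sc$table$adj_r2[1]) < 1e-12))
  expect_equal(sc$selected$outer_m, 50)
  # scan is invariant to design order
  sc2 <- sensitivity_scan(rev(designs), y ~ g)
  expect_equal(sc2$table, sc$table)
  expect_equal(sc2$selected, sc$selected)
})

test_that("sensitivity scan records failed fits as missing and continues", {
  d_ok <- data.frame(y = rnorm(30), g = rnorm(30))
  d_bad <- data.frame(y = rnorm(30), g = rep(1, 30))  # constant covariate
  designs <- list(list(method = "RB", inner_m = 0, outer_m = 50, data = d_bad),
                  list(method = "RB", inner_m = 50, outer_m = 100, data = d_ok))
  sc <- sensitivity_scan(designs, y ~ g)
  expect_true(is.na(sc$table$adj_r2[sc$table$outer_m == 50]))
  expect_equal(sc$selected$outer_m, 100)
})

test_that("Mann-Whitney wrapper: identical samples, separated samples, hand-enumerated U", {
  r <- compare_rb_mb(c(1, 2), c(1, 2))
  expect_equal(r$p_value, 1)
  r2 <- compare_rb_mb(c(1, 2), c(3, 4))
  expect_equal(unname(r2$U), 0)
  expect_equal(r2$method, "exact")
  set.seed(15)
  rb <- runif(105, 0, 0.01); mb <- runif(105, 0.2, 0.3)
  expect_lt(compare_rb_mb(rb, mb)$p_value, 0.001)
})

test_that("group ANOVA: gross separation, pre-checks, and degenerate groups", {
  set.seed(16)
  x <- c(rnorm(200, 10, 2), rnorm(200, 20, 2))
  g <- rep(c("a", "b"), each = 200)
  res <- group_anova(x, g)
  expect_lt(res$p_value, 0.001)
  expect_length(res$shapiro, 2)
  expect_true(is.finite(res$levene_p))
  expect_error(group_anova(rnorm(10), rep("a", 10)), "2 groups")
  expect_warning(res2 <- group_anova(c(rnorm(50), 1, rnorm(50, 5)),
                                     c(rep("a", 50), "tiny", rep("b", 50))),
                 "excluding")
  expect_equal(length(res2$groups), 2)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(17)
  ps <- replicate(500, {
    x <- rnorm(80); g <- rep(c("a", "b"), each = 40)
    group_anova(x, g)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("VIF matches its closed form, flags near-collinearity, and agrees with car", {
  set.seed(18)
  X <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
  v <- vif_diagnostics(X)
  # independent oracle: direct auxiliary regressions via lm
  for (j in 1:3) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    expect_equal(v$vif[j], 1 / (1 - summary(fit)$r.squared), tolerance = 1e-10)
  }
  y <- rnorm(100)
  cv <- car::vif(stats::lm(y ~ x1 + x2 + x3, data = X))
  expect_equal(unname(v$vif), unname(cv), tolerance = 1e-8)

  X$x4 <- X$x1 + rnorm(100, 0, 1e-8)
  v2 <- vif_diagnostics(X)
  expect_true(v2$flag[v2$covariate == "x4"])
  X$x5 <- X$x1 * 2
  v3 <- vif_diagnostics(X)
  expect_true(is.infinite(v3$vif[v3$covariate == "x5"]))
})

test_that("ordered-logit sensitivity engine runs on the same design", {
  skip_if_not_installed("MASS")
  sim <- simulate_linear_cohort(300, c(intercept = 3, x1 = 0.8), sigma = 1, seed = 2)
  d <- sim$data
  d$y <- pmin(6, pmax(1, round(d$y)))
  f <- fit_linear_perception(y ~ x1, d, engine = "ordered_logit")
  expect_s3_class(f, "perception_fit")
  expect_equal(f$engine, "ordered_logit")
})
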