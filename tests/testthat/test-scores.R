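# Instrument scoring, internal consistency, perception binarisation, and
# covariate encoding.

test_that("composite scores hit the documented extremes and sum correctly", {
  expect_equal(composite_score(c(6, 6, 6, 6), 4), 24L)
  expect_equal(composite_score(c(1, 1, 1, 1), 4), 4L)
  expect_equal(composite_score(c(6, 6, 6), 3), 18L)
  expect_equal(composite_score(c(1, 1, 1), 3), 3L)
  expect_equal(composite_score(c(2, 5, 3, 4), 4), 14L)
  # permutation invariance and the constant-response identity k * c
  set.seed(2)
  v <- sample(1:6, 4, replace = TRUE)
  expect_equal(composite_score(v, 4), composite_score(rev(v), 4))
  expect_equal(composite_score(rep(3, 4), 4), 12L)
  expect_error(composite_score(c(1, 2, NA, 4), 4), "imputation")
  expect_error(composite_score(c(1, 2, 3), 4), "expected 4")
  expect_error(composite_score(c(0, 2, 3, 4), 4), "1..6")
})

test_that("Cronbach's alpha: identical columns, affine columns, independent items", {
  m <- matrix(rep(c(1, 3, 4, 6), 4), ncol = 4)
  expect_equal(cronbach_alpha(m), 1.0)
  # items differing by a constant: hand computation gives exactly 1
  toy <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(cronbach_alpha(toy), 1.0)
  # independent uniform items at n = 10,000: alpha near 0
  set.seed(11)
  ind <- matrix(sample(1:6, 4e4, replace = TRUE), ncol = 4)
  expect_lt(abs(cronbach_alpha(ind)), 0.05)
  expect_error(cronbach_alpha(matrix(2, 5, 3)), "zero total-score variance")
})

test_that("alpha never exceeds 1 on random item matrices", {
  set.seed(13)
  for (k in 1:20) {
    m <- matrix(sample(1:6, 60, replace = TRUE), ncol = 3)
    if (stats::var(rowSums(m)) < 1e-12) next
    expect_lte(cronbach_alpha(m), 1)
  }
})

test_that("perfectly loading items give alpha 1 in the questionnaire generator", {
  tm <- true_model(perception_coefficients = c(intercept = 3),
                   latent_noise_sd = 0, mh_loading = 1, item_noise_sd = 0)
  out <- generate_questionnaire(data.frame(participant_id = 1:200), tm, seed = 3)
  expect_equal(cronbach_alpha(as.matrix(out[, paste0("mh", 1:4)])), 1.0)
})

test_that("perception binarisation partitions 1..6 at the 3|4 boundary", {
  expect_equal(as.character(binarize_perception(c(1, 3, 4, 6))),
               c("good", "good", "poor", "poor"))
  b <- binarize_perception(1:6)
  expect_equal(as.character(b), c(rep("good", 3), rep("poor", 3)))
  expect_error(binarize_perception(7), "1..6")
  expect_error(binarize_perception(0), "1..6")
})

test_that("covariate encoding maps labels to the documented codes", {
  raw <- data.frame(
    participant_id = 1:3,
    community = c("A", "B", "A"),
    female = c(0, 1, 1),
    age = c(30, 50, 22),
    income = c("20000-29999", "<9999", ">80000"),
    education = c("Master and above", "Secondary", "Primary and below"),
    employment = c("student", "employed", "unemployed"),
    marital = c("never", "married", "widowed"),
    ownership = c("rent", "own_mortgage", "rent"),
    family_size = c(2, 4, 1), living_space = c(1, 3, 2), exercise_days = c(0, 3, 7))
  enc <- encode_covariates(raw)
  expect_equal(enc$income, c(3L, 1L, 7L))
  expect_equal(enc$education, c(6L, 2L, 1L))
  expect_equal(enc$student, c(1L, 0L, 0L))
  expect_equal(enc$unemployed, c(0L, 0L, 1L))
  expect_equal(enc$community_b, c(0L, 1L, 0L))
  expect_equal(enc$married, c(0L, 1L, 0L))
  expect_equal(enc$widowed, c(0L, 0L, 1L))
  expect_equal(enc$own_mortgage, c(0L, 1L, 0L))
  raw$income <- c("weird", "<9999", ">80000")
  expect_error(encode_covariates(raw), "unknown income")
})
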