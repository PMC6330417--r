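test_that("weighted prevalence and its Kish CI match closed forms", {
  all_one <- make_cohort(age = c(30, 40), disability = 1L)
  res <- weighted_prevalence(all_one)
  expect_equal(res$estimate, 1)
  expect_equal(c(res$lower, res$upper), c(1, 1))

  half <- make_cohort(age = c(30, 40), disability = c(1L, 0L))
  expect_equal(weighted_prevalence(half)$estimate, 0.5)

  cohort <- make_cohort(age = c(30, 40, 50), disability = c(1L, 0L, 0L),
                        weight = c(2, 1, 1))
  res <- weighted_prevalence(cohort)
  expect_equal(res$estimate, 0.5)
  n_eff <- 16 / 6
  se <- sqrt(0.25 / n_eff)
  expect_equal(res$n_eff, n_eff)
  expect_equal(res$lower, max(0, 0.5 - qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(res$upper, min(1, 0.5 + qnorm(0.975) * se), tolerance = 1e-12)
  expect_error(weighted_prevalence(cohort, education = "high"), "no records")
})

test_that("direct standardization is a normalized weighted mean and linear", {
  expect_equal(age_standardize(rep(0.37, 6), rep(1, 6)), 0.37)
  expect_equal(age_standardize(c(0.2, 0.4), c(0.5, 0.5)), 0.3)

  withr::with_seed(81, {
    v <- runif(6); w <- runif(6)
    manual <- sum(v * w) / sum(w)
    expect_equal(age_standardize(v, w), manual, tolerance = 1e-12)
    # linearity
    x <- runif(6); y <- runif(6)
    expect_equal(age_standardize(2 * x + 3 * y, w),
                 2 * age_standardize(x, w) + 3 * age_standardize(y, w),
                 tolerance = 1e-12)
  })
  expect_error(age_standardize(c(NA, rep(0.1, 5)), rep(1, 6)), "missing band")
})

test_that("crude weighted odds ratio matches the 2x2 cross-product", {
  balanced <- make_cohort(age = rep(30, 40),
                          education = rep(c("low", "high"), each = 20),
                          disability = rep(c(1L, 0L, 1L, 0L), each = 10))
  expect_equal(odds_ratio(balanced)$or, 1)

  skewed <- make_cohort(age = rep(30, 60),
                        education = rep(c("low", "high"), each = 30),
                        disability = c(rep(1L, 20), rep(0L, 10),
                                       rep(1L, 10), rep(0L, 20)))
  res <- odds_ratio(skewed)
  expect_equal(res$or, 4)
  expect_lt(res$lower, 4)
  expect_gt(res$upper, 4)
  # scale invariance in the weights
  skewed$weight <- skewed$weight * 7
  expect_equal(odds_ratio(skewed)$or, 4)

  empty_cell <- make_cohort(age = rep(30, 4),
                            education = c("low", "low", "high", "high"),
                            disability = c(1L, 1L, 1L, 1L))
  expect_error(odds_ratio(empty_cell), "empty")
})

test_that("standardizing band-specific attributions preserves additivity", {
  m <- 4
  params <- random_params(m, 91)
  cohort <- random_cohort(3000, m, 92)
  sp <- std_pop_from_weights(c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1))
  res <- standardized_attribution(params, cohort, sex = "male",
                                  education = "low", std_pop = sp)
  expect_equal(res$background + sum(res$contributions), res$prevalence,
               tolerance = 1e-10)
  # agrees with standardizing each cause by hand
  per_band <- lapply(1:6, function(a) {
    population_attribution(params, cohort, sex = "male", education = "low",
                           band = a)
  })
  w <- disattrib:::std_weights(sp, "male")
  manual <- sum(sapply(per_band, `[[`, "prevalence") * w) / sum(w)
  expect_equal(res$prevalence, manual, tolerance = 1e-12)
})

test_that("band-specific disease prevalences are weighted means", {
  cohort <- make_cohort(age = c(30, 32, 45), weight = c(1, 3, 2),
                        X = rbind(c(1L, 0L), c(0L, 0L), c(1L, 1L)))
  p <- disease_prevalence_by_band(cohort, sex = "male", education = "low")
  expect_equal(p["arthritis", "25-39"], 0.25)
  expect_equal(p["arthritis", "40-49"], 1)
  expect_true(is.na(p["arthritis", "80+"]))
})
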