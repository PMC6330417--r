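test_that("individual shares follow the proportional-hazard rule", {
  # no hazard: all shares zero
  params0 <- toy_params(alpha = 0, delta = 0)
  sh0 <- individual_shares(params0, make_cohort(age = 30))
  expect_equal(sh0$pi, 0)
  expect_equal(sh0$background, 0)
  expect_equal(unname(sh0$shares[1, ]), c(0, 0))

  # single cause carrying the whole hazard
  params1 <- toy_params(alpha = 0, delta = log(2))
  sh1 <- individual_shares(params1, make_cohort(age = 30, X = matrix(c(1L, 0L), 1)))
  expect_equal(sh1$pi, 0.5)
  expect_equal(unname(sh1$shares[1, "arthritis"]), 0.5)
  expect_equal(sh1$background, 0)

  # background 0.1 plus one disease 0.3: shares split pro rata and sum to pi
  params2 <- toy_params(alpha = 0.1, delta = 0.3)
  sh2 <- individual_shares(params2, make_cohort(age = 30, X = matrix(c(1L, 0L), 1)))
  pi <- 1 - exp(-0.4)
  expect_equal(sh2$pi, pi, tolerance = 1e-12)
  expect_equal(sh2$background, pi * 0.1 / 0.4, tolerance = 1e-12)
  expect_equal(unname(sh2$shares[1, "arthritis"]), pi * 0.3 / 0.4, tolerance = 1e-12)
  expect_equal(sh2$background + sum(sh2$shares[1, ]), sh2$pi, tolerance = 1e-14)
})

test_that("population attribution is the weighted mean of shares", {
  params <- toy_params(alpha = 0.2, delta = 0.3)
  healthy <- make_cohort(age = c(30, 35), weight = c(1, 3))
  res <- population_attribution(params, healthy)
  expect_equal(res$background, res$prevalence, tolerance = 1e-14)
  expect_equal(unname(res$contributions), c(0, 0))

  # two records, weights 1 and 3, second has arthritis
  cohort <- make_cohort(age = c(30, 35), weight = c(1, 3),
                        X = rbind(c(0L, 0L), c(1L, 0L)))
  res <- population_attribution(params, cohort)
  pi1 <- 1 - exp(-0.2); pi2 <- 1 - exp(-0.5)
  expect_equal(res$prevalence, (pi1 + 3 * pi2) / 4, tolerance = 1e-12)
  expect_equal(unname(res$contributions["arthritis"]),
               3 * pi2 * (0.3 / 0.5) / 4, tolerance = 1e-12)
  expect_equal(res$background,
               (pi1 + 3 * pi2 * (0.2 / 0.5)) / 4, tolerance = 1e-12)
  expect_equal(res$n_effective, 4)
  expect_error(population_attribution(params, cohort, education = "high"),
               "no records")
})

test_that("additivity holds exactly in random scopes", {
  m <- 5
  params <- random_params(m, 51)
  cohort <- random_cohort(400, m, 52)
  for (e in c(NA, education_levels())) {
    scope_e <- if (is.na(e)) NULL else e
    res <- population_attribution(params, cohort, education = scope_e)
    expect_equal(res$background + sum(res$contributions), res$prevalence,
                 tolerance = 1e-10)
    expect_true(all(res$contributions >= 0))
  }
})

test_that("raising a disease effect does not lower its contribution", {
  m <- 3
  for (seed in 1:4) {
    params <- random_params(m, seed + 60)
    cohort <- random_cohort(200, m, seed + 70)
    base <- population_attribution(params, cohort)
    up <- params
    up$delta[1, ] <- up$delta[1, ] + 0.2
    bumped <- population_attribution(up, cohort)
    expect_gte(bumped$contributions[["dz1"]], base$contributions[["dz1"]])
  }
})

test_that("attribution results validate their invariants", {
  expect_error(attribution_result(0.5, c(a = 0.2), 0.2), "additivity")
  expect_error(attribution_result(0.1, c(a = -0.1), 0.2), "non-negative")
  ok <- attribution_result(0.4, c(a = 0.25), 0.15)
  expect_s3_class(ok, "attribution_result")
  df <- as.data.frame(ok)
  expect_equal(df$value[df$cause == "total"], 0.4)
  # external (rounded) figures can skip the check
  ext <- attribution_result(0.39, c(a = 0.25), 0.15, check = FALSE)
  expect_s3_class(ext, "attribution_result")
})
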