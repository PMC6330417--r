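test_that("linear predictor matches explicit summation", {
  params <- toy_params(alpha = 0.1, delta = 0.3)
  no_disease <- make_cohort(age = 30)
  expect_equal(linear_predictor(params, no_disease), 0.1)
  one_disease <- make_cohort(age = 30, X = matrix(c(1L, 0L), 1))
  expect_equal(linear_predictor(params, one_disease), 0.4)

  # brute-force re-summation oracle on random parameters and records
  for (seed in 1:3) {
    m <- 4
    params <- random_params(m, seed)
    cohort <- random_cohort(25, m, seed + 100)
    eta <- linear_predictor(params, cohort)
    X <- as.matrix(as.data.frame(cohort)[paste0("dz", 1:m)])
    for (i in seq_len(nrow(cohort))) {
      a <- assign_band(cohort$age[i], background_bands())
      c_ <- assign_band(cohort$age[i], rank_bands())
      e <- match(cohort$education[i], education_levels())
      eta_i <- params$alpha[a, e]
      for (d in seq_len(m)) {
        eta_i <- eta_i + params$gamma[[c_]] * params$delta[d, e] * X[i, d]
      }
      expect_equal(eta[i], unname(eta_i), tolerance = 1e-12)
    }
    expect_true(all(eta >= 0))
  }
})

test_that("disability probability is the complement of the survival term", {
  expect_equal(disability_prob(0), 0)
  expect_equal(disability_prob(log(2)), 0.5)
  expect_equal(disability_prob(0.28), 1 - exp(-0.28), tolerance = 1e-12)
  expect_equal(disability_prob(0.28), 0.2442163, tolerance = 1e-6)
  expect_error(disability_prob(-0.1), "non-negative")
})

test_that("negative log-likelihood matches the per-record definition", {
  params <- toy_params(alpha = log(2), delta = 0)
  y1 <- make_cohort(age = 30, disability = 1L)
  expect_equal(neg_log_likelihood(params, y1), log(2), tolerance = 1e-12)
  y0 <- make_cohort(age = 30, disability = 0L)
  expect_equal(neg_log_likelihood(params, y0), log(2), tolerance = 1e-12)

  m <- 3
  params <- random_params(m, 21)
  cohort <- random_cohort(10, m, 22)
  nll <- neg_log_likelihood(params, cohort)
  eta <- linear_predictor(params, cohort)
  pi <- pmax(1 - exp(-eta), 1e-12)
  w <- cohort$weight / mean(cohort$weight)
  manual <- 0
  for (i in 1:10) {
    manual <- manual - w[i] * (cohort$disability[i] * log(pi[i]) +
                               (1 - cohort$disability[i]) * (-eta[i]))
  }
  expect_equal(nll, manual, tolerance = 1e-10)
  expect_gt(neg_log_likelihood(params, cohort, use_weights = FALSE), 0)
})

test_that("likelihood is invariant to the gamma/delta scale trade-off", {
  m <- 3
  params <- random_params(m, 31)
  cohort <- random_cohort(40, m, 32)
  for (c_ in c(0.5, 2)) {
    scaled <- params
    scaled$gamma <- params$gamma * c_
    scaled$delta <- params$delta / c_
    # bypass the gamma[1] = 1 normalization to probe the raw surface
    expect_equal(neg_log_likelihood(scaled, cohort),
                 neg_log_likelihood(params, cohort),
                 tolerance = 1e-9)
  }
})

test_that("block iterations never decrease the likelihood and converge", {
  cfg <- simple_config(n = 4000, weight_dispersion = 0.3)
  cohort <- generate_cohort(cfg, seed = 8)
  fit <- suppressWarnings(fit_additive_hazard(cohort, "male", n_starts = 1))
  expect_true(fit$converged)
  expect_true(all(diff(fit$nll_trace) <= 1e-6))
  expect_true(all(fit$params$alpha >= 0))
  expect_true(all(fit$params$delta >= 0))
  expect_equal(unname(fit$params$gamma[1]), 1)
  pi_hat <- disability_prob(linear_predictor(fit$params, cohort))
  expect_true(all(pi_hat >= 0 & pi_hat < 1))
})

test_that("the gamma normalization makes jittered starts agree", {
  cfg <- default_truth()
  cohort <- generate_cohort(cfg, n = 30000, seed = 12)
  f1 <- fit_additive_hazard(cohort, "female", n_starts = 2, seed = 1)
  f2 <- fit_additive_hazard(cohort, "female", n_starts = 2, seed = 99)
  expect_lt(max(abs(f1$params$delta - f2$params$delta)), 0.02)
  expect_lt(max(abs(f1$params$gamma - f2$params$gamma)), 0.02)
  expect_lt(max(abs(f1$params$alpha - f2$params$alpha)), 0.02)
})

test_that("parameters of unobserved diseases and empty cells are pinned at 0", {
  cfg <- simple_config(n = 3000, p = c(0.3, 0))  # second disease never occurs
  cohort <- generate_cohort(cfg, seed = 13)
  expect_warning(fit <- fit_additive_hazard(cohort, "male", n_starts = 1),
                 "pinned")
  expect_equal(unname(fit$params$delta["spine_disorders", ]), c(0, 0, 0))
  expect_true(any(grepl("delta\\[spine_disorders", fit$boundary_flags)))
  # middle/high education and bands 2-6 carry no records
  expect_true(any(grepl("alpha\\[40-49", fit$boundary_flags)))
})

test_that("standardized disabling impact averages beta over the age pattern", {
  params <- toy_params(gamma = c(1, 1, 1, 1), delta = 0.2)
  expect_equal(disabling_impact(params, rep(0.25, 4)), params$delta)
  params2 <- toy_params(gamma = c(1, 2, 3, 4), delta = 0.2)
  expect_equal(disabling_impact(params2, rep(0.25, 4)), 2.5 * params2$delta)

  params3 <- random_params(3, 41)
  w <- c(0.4, 0.3, 0.2, 0.1)
  imp <- disabling_impact(params3, w)
  gbar <- sum(params3$gamma * w) / sum(w)
  for (d in 1:3) for (e in 1:3) {
    expect_equal(imp[d, e], gbar * params3$delta[d, e], tolerance = 1e-12)
  }
  # background-band standard populations are projected onto rank bands
  sp <- std_pop_from_weights(rep(1 / 6, 6))
  gbar_bg <- sum(params3$gamma * c(1 / 6, 1 / 4, 1 / 4, 1 / 3))
  expect_equal(disabling_impact(params3, sp, sex = "male")[1, 1],
               gbar_bg * params3$delta[1, 1], tolerance = 1e-12)
})
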