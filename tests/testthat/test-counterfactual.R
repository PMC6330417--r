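test_that("stratum enumeration matches closed forms", {
  # one disease, no background: prevalence = p * (1 - exp(-beta))
  sh <- expected_stratum_shares(0, 1, 0.4, 0.5)
  expect_equal(sh$prevalence, 0.5 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_equal(sh$contributions, 0.5 * (1 - exp(-0.4)), tolerance = 1e-12)
  expect_equal(sh$background, 0)

  # no diseases present: background takes everything
  sh0 <- expected_stratum_shares(0.3, 1, c(0.2, 0.5), c(0, 0))
  expect_equal(sh0$prevalence, 1 - exp(-0.3), tolerance = 1e-12)
  expect_equal(sh0$contributions, c(0, 0))
  expect_equal(sh0$background, sh0$prevalence, tolerance = 1e-12)

  # shares always sum to the prevalence
  withr::with_seed(101, {
    for (rep in 1:5) {
      m <- sample(2:6, 1)
      sh <- expected_stratum_shares(runif(1, 0, 0.5), runif(1, 0.5, 2),
                                    runif(m, 0, 0.6), runif(m))
      expect_equal(sh$background + sum(sh$contributions), sh$prevalence,
                   tolerance = 1e-12)
    }
  })
})

test_that("enumeration agrees with a Monte-Carlo oracle", {
  withr::with_seed(102, {
    m <- 3
    alpha <- runif(1, 0.05, 0.3)
    gamma_c <- runif(1, 0.8, 2)
    delta <- runif(m, 0.1, 0.5)
    p <- runif(m, 0.1, 0.6)
    exact <- expected_stratum_shares(alpha, gamma_c, delta, p)
    draws <- 2e5
    X <- matrix(runif(draws * m) < rep(p, each = draws), draws, m)
    storage.mode(X) <- "double"
    eta <- alpha + gamma_c * as.vector(X %*% delta)
    pi <- 1 - exp(-eta)
    mc_prev <- mean(pi)
    se <- sd(pi) / sqrt(draws)
    expect_lt(abs(exact$prevalence - mc_prev), 3 * se)
  })
})

test_that("monte-carlo fallback engages above the enumeration cap", {
  sh <- expected_stratum_shares(0.1, 1, rep(0.2, 3), rep(0.3, 3),
                                max_exact_m = 2L, mc_draws = 5e4, mc_seed = 4)
  expect_equal(sh$method, "monte-carlo")
  exact <- expected_stratum_shares(0.1, 1, rep(0.2, 3), rep(0.3, 3))
  expect_equal(exact$method, "enumeration")
  expect_lt(abs(sh$prevalence - exact$prevalence), 0.01)
})

test_that("identity swaps reproduce the baseline attribution", {
  cfg <- default_truth()
  cohort <- generate_cohort(cfg, n = 30000, seed = 14)
  sp <- std_pop_from_weights(cfg$age_distribution)
  params <- cfg$true_params$male
  baseline <- standardized_attribution(params, cohort, sex = "male",
                                       education = "low", std_pop = sp)
  id_impact <- run_scenario(params, cohort,
                            counterfactual_scenario("swap_impact", "low", "low",
                                                    "male"), sp)
  expect_equal(id_impact$prevalence, baseline$prevalence, tolerance = 1e-12)
  expect_equal(id_impact$contributions, baseline$contributions,
               tolerance = 1e-12)

  id_prev <- run_scenario(params, cohort,
                          counterfactual_scenario("swap_prevalence", "low",
                                                  "low", "male"), sp)
  # equal up to sampling error of the multivariate disease distribution
  # (~3 standard errors of the low-educated male subgroup prevalence)
  expect_lt(abs(id_prev$prevalence - baseline$prevalence), 0.02)
  expect_lt(max(abs(id_prev$contributions - baseline$contributions)), 0.02)
})

test_that("gap decomposition differences are consistent and validated", {
  base <- attribution_result(0.4, c(a = 0.2, b = 0.1), 0.1)
  d0 <- decompose_gap(base, base, base, base)
  expect_equal(d0$baseline_gap, 0)
  expect_equal(d0$remaining_gap_equal_prevalence, 0)
  expect_equal(d0$remaining_gap_equal_impact, 0)
  expect_true(all(abs(d0$table$gap_baseline) < 1e-14))

  other <- attribution_result(0.3, c(a = 0.15, c = 0.05), 0.1)
  expect_error(decompose_gap(base, other, base, base), "mismatched")
})

test_that("the decomposition isolates prevalence-driven gaps", {
  # education groups share alpha and delta; only prevalences differ
  diseases <- disease_groups()
  m <- length(diseases)
  base_p <- seq(0.06, 0.3, length.out = m)
  prev <- array(0, dim = c(m, 6, 3, 2))
  for (a in 1:6) for (s in 1:2) {
    prev[, a, 1, s] <- pmin(base_p * 2 * c(0.6, 0.8, 1, 1.2, 1.4, 1.6)[a], 0.9)
    prev[, a, 2, s] <- pmin(base_p * 1.5 * c(0.6, 0.8, 1, 1.2, 1.4, 1.6)[a], 0.9)
    prev[, a, 3, s] <- pmin(base_p * c(0.6, 0.8, 1, 1.2, 1.4, 1.6)[a], 0.9)
  }
  alpha <- matrix(rep(c(0.08, 0.1, 0.14, 0.18, 0.24, 0.3), 3), 6, 3)
  delta <- matrix(rep(seq(0.1, 0.4, length.out = m), 3), m, 3)
  tp <- model_params(alpha, c(1, 1.3, 1.7, 2.2), delta, diseases)
  cfg <- cohort_config(60000, prev, list(male = tp, female = tp),
                       education_mix = c(0.4, 0.3, 0.3),
                       age_distribution = c(0.28, 0.18, 0.18, 0.14, 0.12, 0.1),
                       sex_mix = c(1, 0), weight_dispersion = 0.3)
  cohort <- generate_cohort(cfg, seed = 15)
  sp <- std_pop_from_weights(cfg$age_distribution)
  fit <- fit_additive_hazard(cohort, "male", seed = 3)
  low <- standardized_attribution(fit$params, cohort, "male", "low", sp)
  high <- standardized_attribution(fit$params, cohort, "male", "high", sp)
  cf_prev <- run_scenario(fit$params, cohort,
                          counterfactual_scenario("swap_prevalence"), sp)
  cf_imp <- run_scenario(fit$params, cohort,
                         counterfactual_scenario("swap_impact"), sp)
  gap <- decompose_gap(low, high, cf_prev, cf_imp)
  expect_gt(gap$baseline_gap, 0.04)
  # equalizing prevalence removes (nearly) the whole gap
  expect_lt(abs(gap$remaining_gap_equal_prevalence), 0.02)
  # equalizing impacts changes (nearly) nothing
  expect_lt(abs(gap$remaining_gap_equal_impact - gap$baseline_gap), 0.02)
})
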