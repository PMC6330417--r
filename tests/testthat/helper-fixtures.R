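# Builders for small cohorts and parameter sets used across test files.

# A cohort from explicit vectors; disease columns supplied as a matrix X.
make_cohort <- function(age, sex = "male", education = "low", X = NULL,
                        disability = 0L, weight = 1,
                        diseases = c("arthritis", "spine_disorders")) {
  n <- length(age)
  if (is.null(X)) X <- matrix(0L, n, length(diseases))
  colnames(X) <- diseases
  df <- data.frame(id = paste0("t", seq_len(n)),
                   sex = rep_len(sex, n), age = age,
                   education = rep_len(education, n), X,
                   disability = rep_len(disability, n),
                   weight = rep_len(weight, n),
                   stringsAsFactors = FALSE)
  survey_cohort(df, diseases = diseases)
}

# model_params with constant alpha and per-education-constant delta.
toy_params <- function(diseases = c("arthritis", "spine_disorders"),
                       alpha = 0.1, gamma = c(1, 1, 1, 1), delta = 0.2) {
  m <- length(diseases)
  if (length(delta) == 1L) delta <- matrix(delta, m, 3)
  if (length(alpha) == 1L) alpha <- matrix(alpha, 6, 3)
  model_params(alpha, gamma, delta, diseases)
}

# Single-stratum generator config (one sex, one education, youngest band).
simple_config <- function(n = 5000, diseases = c("arthritis", "spine_disorders"),
                          p = c(0.3, 0.2), alpha = 0.1,
                          delta = c(0.3, 0.15), gamma = c(1, 1, 1, 1),
                          weight_dispersion = 0) {
  m <- length(diseases)
  prev <- array(rep(p, 6 * 3 * 2), dim = c(m, 6, 3, 2))
  dmat <- matrix(rep(delta, 3), m, 3)
  amat <- matrix(alpha, 6, 3)
  tp <- model_params(amat, gamma, dmat, diseases)
  cohort_config(n, prev, list(male = tp, female = tp),
                education_mix = c(1, 0, 0),
                age_distribution = c(1, 0, 0, 0, 0, 0),
                sex_mix = c(1, 0), weight_dispersion = weight_dispersion,
                diseases = diseases)
}

# Random non-negative parameter set for oracle comparisons.
random_params <- function(m, seed) {
  withr::with_seed(seed, {
    model_params(matrix(runif(18, 0, 0.5), 6, 3),
                 c(1, runif(3, 0.5, 3)),
                 matrix(runif(3 * m, 0, 0.6), m, 3),
                 paste0("dz", seq_len(m)))
  })
}

# Random small cohort matching random_params' disease list.
random_cohort <- function(n, m, seed) {
  withr::with_seed(seed, {
    make_cohort(age = sample(25:95, n, replace = TRUE),
                sex = "male",
                education = sample(education_levels(), n, replace = TRUE),
                X = matrix(rbinom(n * m, 1, 0.3), n, m),
                disability = rbinom(n, 1, 0.4),
                weight = runif(n, 0.2, 3),
                diseases = paste0("dz", seq_len(m)))
  })
}
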