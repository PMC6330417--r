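#' Configuration for the synthetic survey-cohort generator
#'
#' Describes a survey-like population with known ground truth: the
#' age/sex/education structure, the prevalence of each chronic condition in
#' every (disease, background band, education, sex) stratum, and the true
#' additive hazard parameters per sex from which disability is generated.
#' Fitting and attribution can then be validated against known parameters
#' without access to restricted survey microdata.
#'
#' @param n Default cohort size.
#' @param disease_prevalence Numeric array `[m, 6, 3, 2]` (disease x
#'   background band x education x sex) of prevalences in `[0, 1]`.
#' @param true_params Named list with `male` and `female` [model_params()].
#' @param education_mix Proportions of the three education levels (sums
#'   to 1).
#' @param age_distribution Proportions of the six background age bands
#'   (sums to 1).
#' @param sex_mix Proportions of males and females (sums to 1).
#' @param weight_dispersion Coefficient of variation of the sampling
#'   weights; 0 gives uniform weights, otherwise weights are gamma draws
#'   with mean 1.
#' @param disease_correlation Pairwise latent dependence in `[0, 1)`
#'   between disease indicators within an individual (Gaussian-copula
#'   style shared tilt); 0 (default) gives conditionally independent
#'   diseases, matching the model's independent-competing-causes
#'   assumption.
#' @param diseases Ordered disease names.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n, disease_prevalence, true_params, education_mix,
                          age_distribution, sex_mix = c(male = 0.5, female = 0.5),
                          weight_dispersion = 0, disease_correlation = 0,
                          diseases = disease_groups()) {
  m <- length(diseases)
  stopifnot(n >= 1)
  disease_prevalence <- as.array(disease_prevalence)
  if (!identical(dim(disease_prevalence), c(m, 6L, 3L, 2L))) {
    stop("`disease_prevalence` must have dimensions [m, 6 bands, 3 educations, 2 sexes]",
         call. = FALSE)
  }
  if (any(disease_prevalence < 0) || any(disease_prevalence > 1)) {
    stop("disease prevalences must lie in [0, 1]", call. = FALSE)
  }
  dimnames(disease_prevalence) <- list(diseases, band_labels(background_bands()),
                                       education_levels(), sex_levels())
  for (s in sex_levels()) {
    if (!inherits(true_params[[s]], "model_params")) {
      stop("`true_params` must contain model_params for both sexes", call. = FALSE)
    }
    if (nrow(true_params[[s]]$delta) != m) {
      stop("true_params delta rows must match the disease list", call. = FALSE)
    }
  }
  check_mix <- function(x, k, name) {
    if (length(x) != k || any(x < 0) || abs(sum(x) - 1) > 1e-8) {
      stop(sprintf("`%s` must be %d non-negative proportions summing to 1", name, k),
           call. = FALSE)
    }
  }
  check_mix(education_mix, 3L, "education_mix")
  check_mix(age_distribution, 6L, "age_distribution")
  check_mix(sex_mix, 2L, "sex_mix")
  stopifnot(weight_dispersion >= 0,
            disease_correlation >= 0, disease_correlation < 1)
  structure(list(
    n = as.integer(n),
    disease_prevalence = disease_prevalence,
    true_params = true_params,
    education_mix = stats::setNames(as.numeric(education_mix), education_levels()),
    age_distribution = stats::setNames(as.numeric(age_distribution),
                                       band_labels(background_bands())),
    sex_mix = stats::setNames(as.numeric(sex_mix), sex_levels()),
    weight_dispersion = weight_dispersion,
    disease_correlation = disease_correlation,
    diseases = diseases
  ), class = "cohort_config")
}

# Prevalence array from per-sex base prevalence matrices (disease x
# education) and a multiplicative age profile over the six bands.
prevalence_array <- function(base_male, base_female, age_profile,
                             diseases = disease_groups(), cap = 0.95) {
  m <- length(diseases)
  arr <- array(0, dim = c(m, 6L, 3L, 2L))
  for (a in 1:6) {
    arr[, a, , 1L] <- pmin(base_male * age_profile[a], cap)
    arr[, a, , 2L] <- pmin(base_female * age_profile[a], cap)
  }
  dimnames(arr) <- list(diseases, band_labels(background_bands()),
                        education_levels(), sex_levels())
  arr
}

#' Default ground-truth generator configuration
#'
#' A documented fixture emulating a national disability survey of adults
#' 25 and over: three education strata with education-graded disease
#' prevalences and disabling effects (for example, arthritis is both more
#' prevalent and more disabling in the low-educated group), disease
#' prevalence rising with age, a background disability hazard rising with
#' age and decreasing with education, and gamma-distributed sampling
#' weights.  All values are fixture choices on realistic scales, not
#' estimates from any survey.
#'
#' @param n Cohort size (default 23,348, a typical national-survey size).
#' @return A [cohort_config()].
#' @export
default_truth <- function(n = 23348) {
  diseases <- disease_groups()
  # base prevalence at the reference (50-59) band, by education low/mid/high
  base_m <- rbind(
    spine_disorders    = c(0.20, 0.17, 0.14),
    arthritis          = c(0.20, 0.16, 0.11),
    dementia           = c(0.04, 0.04, 0.04),
    stroke             = c(0.05, 0.045, 0.04),
    neurologic         = c(0.05, 0.045, 0.04),
    ischemic_heart_pad = c(0.10, 0.09, 0.06),
    other_heart        = c(0.07, 0.065, 0.06),
    copd               = c(0.10, 0.08, 0.05),
    psychiatric        = c(0.08, 0.05, 0.05),
    sensorial          = c(0.04, 0.04, 0.04),
    cancer             = c(0.05, 0.045, 0.04),
    diabetes           = c(0.10, 0.07, 0.05),
    accidents          = c(0.06, 0.05, 0.04)
  )
  base_f <- rbind(
    spine_disorders    = c(0.22, 0.22, 0.21),
    arthritis          = c(0.28, 0.23, 0.20),
    dementia           = c(0.04, 0.04, 0.04),
    stroke             = c(0.04, 0.04, 0.04),
    neurologic         = c(0.04, 0.04, 0.04),
    ischemic_heart_pad = c(0.05, 0.045, 0.04),
    other_heart        = c(0.06, 0.05, 0.06),
    copd               = c(0.08, 0.075, 0.07),
    psychiatric        = c(0.12, 0.09, 0.08),
    sensorial          = c(0.04, 0.04, 0.04),
    cancer             = c(0.04, 0.04, 0.04),
    diabetes           = c(0.08, 0.05, 0.04),
    accidents          = c(0.04, 0.04, 0.04)
  )
  age_profile <- c(0.5, 0.8, 1.0, 1.3, 1.6, 1.9)
  prev <- prevalence_array(base_m, base_f, age_profile, diseases)

  gamma <- c(1, 1.3, 1.7, 2.2)
  alpha_m <- cbind(low    = c(0.10, 0.13, 0.17, 0.22, 0.30, 0.45),
                   middle = c(0.07, 0.09, 0.12, 0.16, 0.22, 0.35),
                   high   = c(0.05, 0.06, 0.08, 0.11, 0.16, 0.28))
  alpha_f <- cbind(low    = c(0.12, 0.15, 0.20, 0.26, 0.34, 0.50),
                   middle = c(0.08, 0.10, 0.14, 0.18, 0.25, 0.40),
                   high   = c(0.05, 0.07, 0.09, 0.12, 0.18, 0.30))
  delta_m <- rbind(
    spine_disorders    = c(0.15, 0.10, 0.08),
    arthritis          = c(0.25, 0.22, 0.16),
    dementia           = c(0.45, 0.40, 0.35),
    stroke             = c(0.40, 0.35, 0.25),
    neurologic         = c(0.45, 0.40, 0.25),
    ischemic_heart_pad = c(0.40, 0.30, 0.30),
    other_heart        = c(0.30, 0.15, 0.15),
    copd               = c(0.20, 0.14, 0.08),
    psychiatric        = c(0.30, 0.25, 0.18),
    sensorial          = c(0.25, 0.15, 0.10),
    cancer             = c(0.30, 0.20, 0.22),
    diabetes           = c(0.10, 0.08, 0.08),
    accidents          = c(0.45, 0.30, 0.22)
  )
  delta_f <- rbind(
    spine_disorders    = c(0.18, 0.16, 0.07),
    arthritis          = c(0.28, 0.22, 0.17),
    dementia           = c(0.45, 0.40, 0.40),
    stroke             = c(0.40, 0.45, 0.35),
    neurologic         = c(0.45, 0.42, 0.38),
    ischemic_heart_pad = c(0.45, 0.40, 0.18),
    other_heart        = c(0.35, 0.18, 0.22),
    copd               = c(0.11, 0.16, 0.16),
    psychiatric        = c(0.22, 0.18, 0.11),
    sensorial          = c(0.40, 0.35, 0.25),
    cancer             = c(0.35, 0.40, 0.45),
    diabetes           = c(0.19, 0.15, 0.20),
    accidents          = c(0.14, 0.25, 0.30)
  )
  cohort_config(
    n = n,
    disease_prevalence = prev,
    true_params = list(
      male = model_params(alpha_m, gamma, delta_m, diseases),
      female = model_params(alpha_f, gamma, delta_f, diseases)
    ),
    education_mix = c(0.35, 0.40, 0.25),
    age_distribution = c(0.28, 0.18, 0.18, 0.14, 0.12, 0.10),
    sex_mix = c(0.48, 0.52),
    weight_dispersion = 0.5,
    disease_correlation = 0
  )
}

#' Generate a synthetic survey cohort
#'
#' Draws a cohort from a [cohort_config()]: age band and exact age
#' (uniform within band, 80-94 for the open band), sex and education from
#' their mixing proportions; disease indicators from the configured
#' stratum prevalences (independently, or tilted by a shared latent
#' Gaussian when `disease_correlation > 0`); disability from the additive
#' hazard model with the true parameters; and positive sampling weights
#' with mean 1.  Fully reproducible from `seed`.
#'
#' @param config A [cohort_config()].
#' @param n Number of records (defaults to `config$n`).
#' @param seed Integer seed.
#' @return A `survey_cohort`.
#' @export
generate_cohort <- function(config, n = NULL, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(n %||% config$n)
  m <- length(config$diseases)
  breaks <- background_bands()
  with_seed(seed, {
    band <- sample.int(6L, n, replace = TRUE, prob = config$age_distribution)
    lo <- breaks[band]
    hi <- ifelse(is.finite(breaks[band + 1L]), breaks[band + 1L], 95)
    age <- lo + floor(stats::runif(n) * (hi - lo))
    sex <- sex_levels()[sample.int(2L, n, replace = TRUE, prob = config$sex_mix)]
    edu <- education_levels()[sample.int(3L, n, replace = TRUE,
                                         prob = config$education_mix)]
    sex_i <- match(sex, sex_levels())
    edu_i <- match(edu, education_levels())
    P <- matrix(0, n, m)
    for (d in seq_len(m)) {
      P[, d] <- config$disease_prevalence[cbind(d, band, edu_i, sex_i)]
    }
    rho <- config$disease_correlation
    if (rho > 0) {
      z0 <- stats::rnorm(n)
      Z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
      X <- 1L * (stats::pnorm(Z) < P)
    } else {
      X <- 1L * (matrix(stats::runif(n * m), n, m) < P)
    }
    colnames(X) <- config$diseases
    weight <- if (config$weight_dispersion > 0) {
      shape <- 1 / config$weight_dispersion^2
      stats::rgamma(n, shape = shape, rate = shape)
    } else {
      rep(1, n)
    }
    df <- data.frame(id = sprintf("r%06d", seq_len(n)), sex = sex, age = age,
                     education = edu, X, disability = 0L, weight = weight,
                     stringsAsFactors = FALSE)
    cohort <- survey_cohort(df, diseases = config$diseases)
    u <- stats::runif(n)
    for (s in sex_levels()) {
      sel <- cohort$sex == s
      if (any(sel)) {
        eta <- linear_predictor(config$true_params[[s]],
                                filter_cohort(cohort, sex = s))
        cohort$disability[sel] <- 1L * (u[sel] < disability_prob(eta))
      }
    }
    cohort
  })
}

#' Exact disability expectation in one stratum under independence
#'
#' Enumerates all disease-state combinations to compute the expected
#' disability probability \eqn{E[1 - e^{-\eta}]} in a stratum with
#' background hazard `alpha`, age-pattern value `gamma_c`, disease effects
#' `delta` and independent disease prevalences `p`.  Used as an
#' enumeration oracle for the generator and for counterfactual
#' expectations.
#'
#' @param alpha Background cumulative rate of the stratum.
#' @param gamma_c Age-pattern multiplier of the stratum.
#' @param delta Disease effects (length m).
#' @param p Disease prevalences (length m).
#' @return Expected disability probability.
#' @export
expected_disability_prob <- function(alpha, gamma_c, delta, p) {
  sh <- expected_stratum_shares(alpha, gamma_c, delta, p)
  sh$prevalence
}
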