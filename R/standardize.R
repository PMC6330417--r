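#' Survey-weighted prevalence with a normal-approximation CI
#'
#' Estimates \eqn{\sum w_i Y_i / \sum w_i} and a 95% confidence interval
#' based on the Kish effective sample size
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}, clipped to `[0, 1]`.
#'
#' @param cohort A `survey_cohort`.
#' @param sex,education,band Optional scope filters.
#' @param outcome Column to summarise (default `"disability"`).
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper` and `n_eff`.
#' @export
weighted_prevalence <- function(cohort, sex = NULL, education = NULL,
                                band = NULL, outcome = "disability",
                                level = 0.95) {
  sub <- filter_cohort(cohort, sex = sex, education = education, band = band)
  if (nrow(sub) == 0L) stop("prevalence scope contains no records", call. = FALSE)
  y <- sub[[outcome]]
  w <- sub$weight
  est <- sum(w * y) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  se <- sqrt(est * (1 - est) / n_eff)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est,
       lower = max(0, est - z * se),
       upper = min(1, est + z * se),
       n_eff = n_eff)
}

#' Direct age standardization
#'
#' Weighted average of band-specific values using a standard population's
#' age structure: \eqn{\sum_a v_a w_a / \sum_a w_a}.
#'
#' @param values Numeric vector of band-specific values, in background-band
#'   order (may contain `NA` only for bands with zero weight).
#' @param std_pop A [std_population()] or a numeric vector of 6 band
#'   weights.
#' @param sex Sex whose standard weights to use when `std_pop` is a
#'   `std_population`.
#' @return The standardized value.
#' @export
age_standardize <- function(values, std_pop, sex = "male") {
  w <- if (inherits(std_pop, "std_population")) std_weights(std_pop, sex) else std_pop
  stopifnot(length(values) == length(w), all(w >= 0), sum(w) > 0)
  if (any(is.na(values) & w > 0)) {
    stop("missing band value where the standard population has positive weight",
         call. = FALSE)
  }
  values[w == 0] <- 0
  sum(values * w) / sum(w)
}

#' Crude weighted odds ratio of disability between education levels
#'
#' Builds the weighted 2x2 table of disability by education for the two
#' requested levels and returns the crude odds ratio (no covariate
#' adjustment) with a Woolf-type confidence interval on the log scale,
#' using Kish effective counts per cell to account for unequal weights.
#'
#' @param cohort A `survey_cohort`.
#' @param exposure Education pair `c(exposed, reference)`, default low vs
#'   high.
#' @param sex Optional sex filter.
#' @param level Confidence level.
#' @return List with `or`, `lower`, `upper` and the weighted `cells`.
#' @export
odds_ratio <- function(cohort, exposure = c("low", "high"), sex = NULL,
                       level = 0.95) {
  stopifnot(length(exposure) == 2L, all(exposure %in% education_levels()))
  sub <- filter_cohort(cohort, sex = sex, education = exposure)
  cell <- function(edu, y) {
    s <- sub$education == edu & sub$disability == y
    w <- sub$weight[s]
    list(w = sum(w), n_eff = if (length(w)) sum(w)^2 / sum(w^2) else 0)
  }
  a <- cell(exposure[1L], 1L)  # disabled, exposed
  b <- cell(exposure[1L], 0L)
  c_ <- cell(exposure[2L], 1L)
  d <- cell(exposure[2L], 0L)
  if (any(c(a$w, b$w, c_$w, d$w) == 0)) {
    stop("odds ratio undefined: a weighted 2x2 cell is empty", call. = FALSE)
  }
  or <- (a$w * d$w) / (b$w * c_$w)
  se <- sqrt(1 / a$n_eff + 1 / b$n_eff + 1 / c_$n_eff + 1 / d$n_eff)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or,
       lower = or * exp(-z * se),
       upper = or * exp(z * se),
       cells = c(disabled_exposed = a$w, healthy_exposed = b$w,
                 disabled_reference = c_$w, healthy_reference = d$w))
}

#' Age-standardized weighted disease prevalence by band
#'
#' Weighted prevalence of each disease in each background band of a scope,
#' as needed for counterfactual prevalence swaps; optionally collapsed to
#' a single standardized figure per disease.
#'
#' @param cohort A `survey_cohort`.
#' @param sex,education Scope filters.
#' @return m x 6 matrix of weighted prevalences (disease x band); bands
#'   with no records are `NA`.
#' @export
disease_prevalence_by_band <- function(cohort, sex, education) {
  sub <- filter_cohort(cohort, sex = sex, education = education)
  if (nrow(sub) == 0L) stop("scope contains no records", call. = FALSE)
  X <- disease_matrix(sub)
  bg <- assign_band(sub$age, background_bands())
  out <- matrix(NA_real_, ncol(X), 6L,
                dimnames = list(cohort_diseases(sub),
                                band_labels(background_bands())))
  for (a in 1:6) {
    sel <- bg == a
    if (any(sel)) {
      w <- sub$weight[sel]
      out[, a] <- as.vector(crossprod(X[sel, , drop = FALSE], w)) / sum(w)
    }
  }
  out
}
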