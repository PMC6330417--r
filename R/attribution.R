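#' Attribution result container
#'
#' Holds a disability prevalence split additively into per-disease
#' contributions and a background part for one scope (a sex, education
#' level and optionally an age band, or an age-standardized summary).
#' Results produced by the package satisfy
#' `background + sum(contributions) == prevalence` to 1e-10 by
#' construction; set `check = FALSE` only when assembling a result from
#' externally rounded figures (e.g. published tables).
#'
#' @param prevalence Disability prevalence attributed (model-predicted
#'   weighted mean probability).
#' @param contributions Named non-negative vector, one entry per disease.
#' @param background Non-negative background contribution.
#' @param scope Named list describing the stratum.
#' @param n_effective Sum of sampling weights in the scope.
#' @param check Verify the additivity invariant (default `TRUE`).
#' @return An `attribution_result`.
#' @export
attribution_result <- function(prevalence, contributions, background,
                               scope = list(), n_effective = NA_real_,
                               check = TRUE) {
  prevalence <- unname(prevalence)
  background <- unname(background)
  if (check) {
    if (any(contributions < -1e-12) || background < -1e-12) {
      stop("contributions must be non-negative", call. = FALSE)
    }
    gap <- abs(background + sum(contributions) - prevalence)
    if (gap > 1e-10) {
      stop(sprintf("additivity violated: |background + sum - prevalence| = %.3g", gap),
           call. = FALSE)
    }
  }
  structure(list(prevalence = prevalence,
                 contributions = contributions,
                 background = background,
                 scope = scope,
                 n_effective = n_effective),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  sc <- paste(names(x$scope), unlist(lapply(x$scope, as.character)),
              sep = "=", collapse = ", ")
  cat(sprintf("Disability attribution (%s): prevalence %.4f\n", sc, x$prevalence))
  tab <- c(sort(x$contributions, decreasing = TRUE), background = x$background)
  print(round(tab, 4))
  invisible(x)
}

#' Tidy table view of an attribution result
#'
#' @param x An `attribution_result`.
#' @param ... Unused.
#' @return Data frame with one row per cause (diseases, background, total).
#' @export
as.data.frame.attribution_result <- function(x, ...) {
  data.frame(
    cause = c(names(x$contributions), "background", "total"),
    value = c(unname(x$contributions), x$background, x$prevalence),
    stringsAsFactors = FALSE
  )
}

#' Individual-level attribution of the disability probability
#'
#' Splits each record's modelled disability probability \eqn{\pi_i}
#' proportionally to the hazard components: disease d receives
#' \eqn{\pi_i \beta_{cde} X_{di} / \eta_i} and the background
#' \eqn{\pi_i \alpha_{ae} / \eta_i}, so the shares sum to \eqn{\pi_i}
#' exactly; records with zero hazard get all-zero shares.
#'
#' @param params A [model_params()] object.
#' @param cohort A `survey_cohort`.
#' @return List with `pi` (modelled probabilities), `background` (vector)
#'   and `shares` (n x m matrix of per-disease shares).
#' @export
individual_shares <- function(params, cohort) {
  X <- disease_matrix(cohort)
  bg <- assign_band(cohort$age, background_bands())
  rk <- assign_band(cohort$age, rank_bands())
  edu <- match(cohort$education, education_levels())
  beta_x <- (X * t(params$delta)[edu, , drop = FALSE]) * params$gamma[rk]
  alpha_i <- params$alpha[cbind(bg, edu)]
  eta <- alpha_i + rowSums(beta_x)
  pi <- disability_prob(eta)
  ratio <- ifelse(eta > 0, pi / eta, 0)
  shares <- beta_x * ratio
  colnames(shares) <- cohort_diseases(cohort)
  list(pi = pi, background = alpha_i * ratio, shares = shares)
}

#' Population attribution of disability prevalence
#'
#' Weighted mean of the individual shares over a scope: the quantity
#' partitioned is the model-predicted prevalence (weighted mean of
#' \eqn{\hat\pi_i}), which makes the additive split exact; its discrepancy
#' from the observed weighted prevalence is returned as a fit diagnostic
#' (`observed_prevalence` in the scope).
#'
#' @param params A [model_params()] object.
#' @param cohort A `survey_cohort`.
#' @param sex,education,band Optional scope filters (band is a background
#'   band index).
#' @param use_weights Use sampling weights (default `TRUE`).
#' @return An [attribution_result()].
#' @export
population_attribution <- function(params, cohort, sex = NULL, education = NULL,
                                   band = NULL, use_weights = TRUE) {
  sub <- filter_cohort(cohort, sex = sex, education = education, band = band)
  if (nrow(sub) == 0L) stop("attribution scope contains no records", call. = FALSE)
  w <- if (use_weights) sub$weight else rep(1, nrow(sub))
  sh <- individual_shares(params, sub)
  sw <- sum(w)
  contributions <- as.vector(crossprod(sh$shares, w)) / sw
  names(contributions) <- cohort_diseases(sub)
  attribution_result(
    prevalence = sum(sh$pi * w) / sw,
    contributions = contributions,
    background = sum(sh$background * w) / sw,
    scope = list(sex = sex %||% "all", education = education %||% "all",
                 band = band %||% "all",
                 observed_prevalence = sum(sub$disability * w) / sw),
    n_effective = sw
  )
}

#' Age-standardized population attribution
#'
#' Computes the attribution separately in each background age band of the
#' scope and averages each cause's contribution (and the prevalence) with
#' standard-population weights.  Standardization is linear, so additivity
#' of the split is preserved exactly.
#'
#' @inheritParams population_attribution
#' @param std_pop A [std_population()].
#' @return An [attribution_result()] (scope marked as standardized).
#' @export
standardized_attribution <- function(params, cohort, sex, education, std_pop,
                                     use_weights = TRUE) {
  w_std <- std_weights(std_pop, sex)
  active <- which(w_std > 0)
  per_band <- vector("list", length(active))
  for (i in seq_along(active)) {
    a <- active[i]
    sub <- filter_cohort(cohort, sex = sex, education = education, band = a)
    if (nrow(sub) == 0L) {
      stop(sprintf("no records in age band %s for %s/%s but the standard population gives it positive weight",
                   band_labels(background_bands())[a], sex, education),
           call. = FALSE)
    }
    per_band[[i]] <- population_attribution(params, cohort, sex = sex,
                                            education = education, band = a,
                                            use_weights = use_weights)
  }
  wa <- w_std[active] / sum(w_std[active])
  contributions <- Reduce(`+`, Map(function(r, w) r$contributions * w, per_band, wa))
  attribution_result(
    prevalence = sum(vapply(per_band, `[[`, numeric(1), "prevalence") * wa),
    contributions = contributions,
    background = sum(vapply(per_band, `[[`, numeric(1), "background") * wa),
    scope = list(sex = sex, education = education, standardized = TRUE),
    n_effective = sum(vapply(per_band, `[[`, numeric(1), "n_effective"))
  )
}
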