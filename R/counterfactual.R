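# Counterfactual scenarios: recompute the low-educated group's disability
# attribution after giving it the high-educated group's disease prevalences
# (swap_prevalence) or disease disabling impacts (swap_impact), then
# measure how much of the educational gap remains.

#' Expected per-cause shares in one stratum under disease independence
#'
#' Enumerates all \eqn{2^m} disease-state vectors x with probability
#' \eqn{\prod_d p_d^{x_d}(1-p_d)^{1-x_d}}, evaluates the disability
#' probability and the proportional-hazard shares at each state, and
#' returns their exact expectations.  For more than `max_exact_m` diseases
#' the expectation falls back to Monte-Carlo draws (flagged in the
#' result).
#'
#' @param alpha Background cumulative rate of the stratum.
#' @param gamma_c Age-pattern multiplier of the stratum.
#' @param delta Disease effects (length m).
#' @param p Independent disease prevalences (length m).
#' @param max_exact_m Largest m for exact enumeration (default 15).
#' @param mc_draws,mc_seed Monte-Carlo fallback settings.
#' @return List with `prevalence`, `background`, `contributions` (length
#'   m) and `method` (`"enumeration"` or `"monte-carlo"`).
#' @export
expected_stratum_shares <- function(alpha, gamma_c, delta, p,
                                    max_exact_m = 15L, mc_draws = 1e6,
                                    mc_seed = 1L) {
  m <- length(delta)
  stopifnot(length(p) == m, all(p >= 0), all(p <= 1), alpha >= 0, gamma_c >= 0)
  if (m <= max_exact_m) {
    S <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    logpr <- S %*% log(pc) + (1 - S) %*% log(1 - pc)
    pr <- exp(as.vector(logpr))
    # states involving a disease with true p = 0 (or absent with p = 1)
    # must carry zero probability despite the clamp
    if (any(p == 0)) pr[S[, p == 0, drop = FALSE] %*% rep(1, sum(p == 0)) > 0] <- 0
    if (any(p == 1)) pr[(1 - S[, p == 1, drop = FALSE]) %*% rep(1, sum(p == 1)) > 0] <- 0
    pr <- pr / sum(pr)
    method <- "enumeration"
  } else {
    S <- with_seed(mc_seed, {
      matrix(stats::runif(mc_draws * m), mc_draws, m) < matrix(p, mc_draws, m, byrow = TRUE)
    })
    storage.mode(S) <- "double"
    pr <- rep(1 / nrow(S), nrow(S))
    method <- "monte-carlo"
  }
  beta_x <- S * matrix(gamma_c * delta, nrow(S), m, byrow = TRUE)
  eta <- alpha + rowSums(beta_x)
  pi <- -expm1(-eta)
  ratio <- ifelse(eta > 0, pi / eta, 0)
  list(prevalence = sum(pr * pi),
       background = sum(pr * alpha * ratio),
       contributions = as.vector(crossprod(beta_x * ratio, pr)),
       method = method)
}

#' Expected age-standardized attribution from disease prevalences
#'
#' For an education level and sex, computes the exact expected attribution
#' of disability in each background age band from band-specific disease
#' prevalences (assuming independent diseases, consistent with the model's
#' independent-competing-causes assumption), then age-standardizes.  This
#' is the engine of the prevalence-swap counterfactual: feeding it another
#' group's prevalences with this group's hazard parameters answers "what
#' if only the disease prevalences changed".
#'
#' @param params A [model_params()] object.
#' @param prevalences m x 6 matrix of disease prevalences by background
#'   band.
#' @param education Education level whose hazard parameters to use.
#' @param sex Sex for the standard-population weights.
#' @param std_pop A [std_population()].
#' @param gamma_mix Optional 6 x 4 matrix giving the rank-band composition
#'   of each background band (defaults to a uniform-age split); used to
#'   average the age pattern within the straddling band.
#' @param max_exact_m,mc_draws,mc_seed Passed to
#'   [expected_stratum_shares()].
#' @return An [attribution_result()] with `scope$method` recording whether
#'   enumeration or Monte-Carlo was used.
#' @export
expected_attribution <- function(params, prevalences, education, sex, std_pop,
                                 gamma_mix = NULL, max_exact_m = 15L,
                                 mc_draws = 1e6, mc_seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  m <- nrow(params$delta)
  prevalences <- as.matrix(prevalences)
  if (!identical(dim(prevalences), c(m, 6L))) {
    stop("`prevalences` must be an m x 6 matrix (disease x background band)",
         call. = FALSE)
  }
  e <- match(match.arg(education, education_levels()), education_levels())
  gamma_mix <- gamma_mix %||% band_projection_matrix()
  gamma_band <- as.vector(gamma_mix %*% params$gamma)
  w_std <- std_weights(std_pop, sex)
  active <- which(w_std > 0)
  wa <- w_std[active] / sum(w_std[active])
  prevalence <- 0
  background <- 0
  contributions <- numeric(m)
  method <- "enumeration"
  for (i in seq_along(active)) {
    a <- active[i]
    if (anyNA(prevalences[, a])) {
      stop("missing disease prevalence in a band with positive standard weight",
           call. = FALSE)
    }
    sh <- expected_stratum_shares(params$alpha[a, e], gamma_band[a],
                                  params$delta[, e], prevalences[, a],
                                  max_exact_m = max_exact_m,
                                  mc_draws = mc_draws,
                                  mc_seed = derive_seed(mc_seed, paste0("band", a)))
    if (sh$method == "monte-carlo") method <- "monte-carlo"
    prevalence <- prevalence + wa[i] * sh$prevalence
    background <- background + wa[i] * sh$background
    contributions <- contributions + wa[i] * sh$contributions
  }
  names(contributions) <- rownames(params$delta)
  attribution_result(prevalence, contributions, background,
                     scope = list(sex = sex, education = education_levels()[e],
                                  standardized = TRUE, expected = TRUE,
                                  method = method))
}

#' Define a counterfactual scenario
#'
#' @param kind `"swap_prevalence"` (give the recipient the donor's
#'   age-specific disease prevalences) or `"swap_impact"` (give the
#'   recipient the donor's disease effects \eqn{\delta}); the background
#'   hazard is never swapped.
#' @param donor,recipient Education levels (must differ); conventionally
#'   donor `"high"`, recipient `"low"`.
#' @param sex Sex analysed.
#' @return A `counterfactual_scenario`.
#' @export
counterfactual_scenario <- function(kind = c("swap_prevalence", "swap_impact"),
                                    donor = "high", recipient = "low",
                                    sex = "male") {
  kind <- match.arg(kind)
  donor <- match.arg(donor, education_levels())
  recipient <- match.arg(recipient, education_levels())
  sex <- match.arg(sex, sex_levels())
  structure(list(kind = kind, donor = donor, recipient = recipient, sex = sex),
            class = "counterfactual_scenario")
}

#' Run a counterfactual scenario
#'
#' `swap_impact` re-attributes the recipient group's observed records
#' after replacing its disease effects \eqn{\delta} with the donor's
#' (background and age pattern unchanged) and age-standardizes.
#' `swap_prevalence` computes the exact expected attribution using the
#' donor's age-specific weighted disease prevalences with the recipient's
#' own hazard parameters; the age-pattern mixture within bands is taken
#' from the recipient's records.
#'
#' An identity swap (donor equal to recipient) reproduces the baseline
#' attribution: exactly for `swap_impact`, and up to sampling/independence
#' error for `swap_prevalence`.
#'
#' @param params A [model_params()] fitted for `scenario$sex` (contains
#'   all education levels).
#' @param cohort A `survey_cohort`.
#' @param scenario A [counterfactual_scenario()].
#' @param std_pop A [std_population()].
#' @param use_weights Use sampling weights.
#' @return An [attribution_result()] for the recipient group under the
#'   scenario.
#' @export
run_scenario <- function(params, cohort, scenario, std_pop, use_weights = TRUE) {
  stopifnot(inherits(scenario, "counterfactual_scenario"))
  sex <- scenario$sex
  if (scenario$kind == "swap_impact") {
    cf <- params
    cf$delta[, scenario$recipient] <- params$delta[, scenario$donor]
    res <- standardized_attribution(cf, cohort, sex = sex,
                                    education = scenario$recipient,
                                    std_pop = std_pop, use_weights = use_weights)
  } else {
    prev_donor <- disease_prevalence_by_band(cohort, sex = sex,
                                             education = scenario$donor)
    sub <- filter_cohort(cohort, sex = sex, education = scenario$recipient)
    if (nrow(sub) == 0L) stop("no recipient records", call. = FALSE)
    mix <- rank_mix_from_records(sub)
    res <- expected_attribution(params, prev_donor,
                                education = scenario$recipient, sex = sex,
                                std_pop = std_pop, gamma_mix = mix)
  }
  res$scope$scenario <- scenario$kind
  res$scope$donor <- scenario$donor
  res
}

# Weighted rank-band composition of each background band, estimated from
# records; bands without records fall back to the uniform-age split.
rank_mix_from_records <- function(cohort) {
  mix <- band_projection_matrix()
  bg <- assign_band(cohort$age, background_bands())
  rk <- assign_band(cohort$age, rank_bands())
  for (a in 1:6) {
    sel <- bg == a
    if (any(sel)) {
      w <- rowsum(cohort$weight[sel], rk[sel])
      row <- numeric(4)
      row[as.integer(rownames(w))] <- w[, 1L]
      mix[a, ] <- row / sum(row)
    }
  }
  mix
}

#' Decompose the educational gap in disability
#'
#' Given baseline attributions for the low- (recipient) and high-educated
#' (donor) groups and the two counterfactual attributions for the
#' recipient, computes the baseline gap (low minus high), the gap
#' remaining when disease prevalences are equalized (counterfactual
#' prevalence minus high: the part due to differential disabling impact)
#' and the gap remaining when disabling impacts are equalized
#' (counterfactual impact minus high: the part due to differential
#' prevalence), overall and per cause.
#'
#' Inputs may be [attribution_result()] objects or named numeric vectors
#' (per-cause values plus `background` and `total`), e.g. figures
#' transcribed from a published table; all four must share one cause list
#' and standardization.
#'
#' @param baseline_low,baseline_high,cf_prevalence,cf_impact The four
#'   attribution columns.
#' @return A `gap_decomposition` with elements `baseline_gap`,
#'   `remaining_gap_equal_prevalence`, `remaining_gap_equal_impact` and a
#'   per-cause `table`.
#' @export
decompose_gap <- function(baseline_low, baseline_high, cf_prevalence, cf_impact) {
  cols <- lapply(list(low = baseline_low, high = baseline_high,
                      cf_prevalence = cf_prevalence, cf_impact = cf_impact),
                 as_cause_vector)
  causes <- names(cols$low)
  for (nm in names(cols)) {
    if (!identical(names(cols[[nm]]), causes)) {
      stop("attribution inputs have mismatched cause lists", call. = FALSE)
    }
  }
  tab <- data.frame(cause = causes,
                    low = unname(cols$low),
                    high = unname(cols$high),
                    cf_prevalence = unname(cols$cf_prevalence),
                    cf_impact = unname(cols$cf_impact),
                    stringsAsFactors = FALSE)
  tab$gap_baseline <- tab$low - tab$high
  tab$gap_equal_prevalence <- tab$cf_prevalence - tab$high
  tab$gap_equal_impact <- tab$cf_impact - tab$high
  tot <- tab[tab$cause == "total", ]
  structure(list(
    baseline_gap = tot$gap_baseline,
    remaining_gap_equal_prevalence = tot$gap_equal_prevalence,
    remaining_gap_equal_impact = tot$gap_equal_impact,
    table = tab
  ), class = "gap_decomposition")
}

as_cause_vector <- function(x) {
  if (inherits(x, "attribution_result")) {
    c(x$contributions, background = x$background, total = x$prevalence)
  } else if (is.numeric(x) && !is.null(names(x))) {
    if (!all(c("background", "total") %in% names(x))) {
      stop("named attribution vectors need 'background' and 'total' entries",
           call. = FALSE)
    }
    c(x[setdiff(names(x), c("background", "total"))],
      background = unname(x["background"]), total = unname(x["total"]))
  } else {
    stop("expected an attribution_result or a named numeric vector", call. = FALSE)
  }
}

#' @export
print.gap_decomposition <- function(x, ...) {
  cat(sprintf("Educational gap in disability: baseline %.3f\n", x$baseline_gap))
  cat(sprintf("  remaining with equal disease prevalence: %.3f (impact-driven part)\n",
              x$remaining_gap_equal_prevalence))
  cat(sprintf("  remaining with equal disabling impact:   %.3f (prevalence-driven part)\n",
              x$remaining_gap_equal_impact))
  invisible(x)
}
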