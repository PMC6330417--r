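#' Full attribution and gap-decomposition analysis
#'
#' Orchestrates the analysis shape of a disability-attribution study: per
#' sex, fit the additive hazard model, report age-standardized disabling
#' impacts, compute the age-standardized attribution of disability per
#' education level, run both counterfactual scenarios for the
#' recipient/donor pair, and decompose the educational gap.  Optionally
#' wraps the disabling impacts and contributions in bootstrap confidence
#' intervals.
#'
#' @param cohort A `survey_cohort`.
#' @param std_pop A [std_population()].
#' @param sexes Sexes to analyse (fitted separately).
#' @param recipient,donor Education levels compared (default low vs high).
#' @param n_boot Bootstrap replicates for impact/contribution CIs; 0
#'   (default) skips the bootstrap.
#' @param seed Top-level seed; all randomness (multi-start jitter,
#'   bootstrap resampling) derives from it via named substreams.
#' @param fit_options Named list of overrides passed to
#'   [fit_additive_hazard()] (`tol`, `max_iter`, `n_starts`,
#'   `use_weights`).
#' @return A `disability_analysis` list: per sex `fit`, `impacts`, `attribution`
#'   (one [attribution_result()] per education level), `counterfactuals`,
#'   `gap` ([decompose_gap()]), `table2` ([render_table2()]) and optional
#'   `bootstrap`; plus a `log` recording seed, options and convergence.
#' @export
run_full_analysis <- function(cohort, std_pop, sexes = sex_levels(),
                              recipient = "low", donor = "high",
                              n_boot = 0L, seed = 1L, fit_options = list()) {
  stopifnot(inherits(cohort, "survey_cohort"), inherits(std_pop, "std_population"))
  use_weights <- fit_options$use_weights %||% TRUE
  results <- list()
  log <- list(seed = seed, n_obs = nrow(cohort),
              started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              package_version = as.character(utils::packageVersion("disattrib")),
              fit = list())
  for (s in sexes) {
    fit <- fit_additive_hazard(
      cohort, sex = s,
      tol = fit_options$tol %||% 1e-8,
      max_iter = fit_options$max_iter %||% 100L,
      n_starts = fit_options$n_starts %||% 2L,
      seed = derive_seed(seed, paste0("fit-", s)),
      use_weights = use_weights,
      warn_empty = fit_options$warn_empty %||% TRUE
    )
    log$fit[[s]] <- list(converged = fit$converged, n_iter = fit$n_iter,
                         loglik = fit$loglik,
                         n_boundary = length(fit$boundary_flags))
    impacts <- disabling_impact(fit$params, std_pop, sex = s)
    present <- education_levels()[education_levels() %in%
                                    cohort$education[cohort$sex == s]]
    if (!all(c(recipient, donor) %in% present)) {
      stop("recipient and donor education levels must both have records",
           call. = FALSE)
    }
    attribution <- lapply(stats::setNames(nm = present), function(e) {
      standardized_attribution(fit$params, cohort, sex = s, education = e,
                               std_pop = std_pop, use_weights = use_weights)
    })
    cf <- list(
      swap_prevalence = run_scenario(
        fit$params, cohort,
        counterfactual_scenario("swap_prevalence", donor, recipient, s),
        std_pop, use_weights = use_weights),
      swap_impact = run_scenario(
        fit$params, cohort,
        counterfactual_scenario("swap_impact", donor, recipient, s),
        std_pop, use_weights = use_weights)
    )
    gap <- decompose_gap(attribution[[recipient]], attribution[[donor]],
                         cf$swap_prevalence, cf$swap_impact)
    boot <- NULL
    if (n_boot > 0L) {
      stat <- function(ch) {
        f <- fit_additive_hazard(ch, sex = s,
                                 tol = fit_options$tol %||% 1e-8,
                                 n_starts = 1L, use_weights = use_weights,
                                 warn_empty = FALSE)
        imp <- disabling_impact(f$params, std_pop, sex = s)
        at <- standardized_attribution(f$params, ch, sex = s,
                                       education = recipient,
                                       std_pop = std_pop,
                                       use_weights = use_weights)
        c(stats::setNames(as.vector(imp),
                          paste0("impact_", outer(rownames(imp), colnames(imp),
                                                  paste, sep = "_"))),
          stats::setNames(at$contributions,
                          paste0("contribution_", names(at$contributions), "_",
                                 recipient)),
          background = at$background, prevalence = at$prevalence)
      }
      boot <- bootstrap_ci(filter_cohort(cohort, sex = s), stat,
                           n_reps = n_boot,
                           seed = derive_seed(seed, paste0("boot-", s)))
    }
    results[[s]] <- list(fit = fit, impacts = impacts,
                         attribution = attribution, counterfactuals = cf,
                         gap = gap,
                         table2 = render_table2(gap),
                         bootstrap = boot)
  }
  log$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  structure(c(results, list(log = log)), class = "disability_analysis")
}

#' Render the gap decomposition as a seven-column table
#'
#' One row per cause (the diseases, then `background`, then the
#' `total` disability-prevalence row) and seven value columns: the
#' recipient (low) and donor (high) baseline attributions, the two
#' counterfactual attributions, and the three difference columns
#' (baseline gap, gap with equal prevalence, gap with equal impact).
#' Values are percentages at full precision; use [format_table2()] for a
#' one-decimal display matching survey-report conventions.
#'
#' @param gap A [decompose_gap()] result (or the output of
#'   [run_full_analysis()] for one sex via `$gap`).
#' @param percent Multiply proportions by 100 (default `TRUE`).
#' @return Data frame with columns `cause`, `low`, `high`,
#'   `cf_prevalence`, `cf_impact`, `gap_baseline`, `gap_equal_prevalence`,
#'   `gap_equal_impact`.
#' @export
render_table2 <- function(gap, percent = TRUE) {
  stopifnot(inherits(gap, "gap_decomposition"))
  tab <- gap$table
  if (percent) {
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) 100 * x)
  }
  tab
}

#' @rdname render_table2
#' @param table2 A table from [render_table2()].
#' @param digits Decimal places for display (default 1).
#' @export
format_table2 <- function(table2, digits = 1L) {
  num <- vapply(table2, is.numeric, logical(1))
  table2[num] <- lapply(table2[num], function(x) sprintf(paste0("%.", digits, "f"), x))
  table2
}

#' Check the additive-partition invariant of an emitted table
#'
#' Verifies that in every value column of a rendered table the cause rows
#' plus the background row sum to the total (disability prevalence) row.
#'
#' @param table2 A table from [render_table2()].
#' @param tol Tolerance (default 1e-10 on the table's scale).
#' @return `TRUE` invisibly; errors if the invariant fails.
#' @export
check_additivity <- function(table2, tol = 1e-10) {
  value_cols <- c("low", "high", "cf_prevalence", "cf_impact")
  for (col in intersect(value_cols, names(table2))) {
    parts <- table2[[col]][table2$cause != "total"]
    total <- table2[[col]][table2$cause == "total"]
    if (abs(sum(parts) - total) > tol * max(1, abs(total))) {
      stop(sprintf("additivity fails in column '%s': parts sum to %.12g, total %.12g",
                   col, sum(parts), total), call. = FALSE)
    }
  }
  invisible(TRUE)
}
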