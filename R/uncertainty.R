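#' Bootstrap confidence intervals for pipeline statistics
#'
#' Resamples survey records with replacement (each record keeps its
#' sampling weight), re-evaluates `statistic` on every replicate cohort,
#' and returns per-output confidence intervals.  The default `"normal"`
#' method reports `point +/- z * sd(replicates)` around the original-data
#' estimate; for parameters constrained to be non-negative its lower bound
#' can go below zero, whereas `"percentile"` intervals cannot.  Replicates
#' on which `statistic` throws are dropped and counted; more than 10%
#' failures flags the output.
#'
#' @param cohort A `survey_cohort`.
#' @param statistic Function taking a cohort and returning a (optionally
#'   named) numeric vector; must be deterministic given the cohort.
#' @param n_reps Number of bootstrap replicates (surveys conventionally
#'   use 1000; scale down for quick checks).
#' @param seed Integer seed; the same seed reproduces identical intervals.
#' @param ci_method `"normal"` or `"percentile"`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `statistic`, `point`, `lower`, `upper`;
#'   attributes `replicates` (matrix), `n_fail` and `flagged`.
#' @export
bootstrap_ci <- function(cohort, statistic, n_reps = 1000L, seed = 1L,
                         ci_method = c("normal", "percentile"), level = 0.95) {
  stopifnot(inherits(cohort, "survey_cohort"), is.function(statistic),
            n_reps >= 2L)
  ci_method <- match.arg(ci_method)
  point <- statistic(cohort)
  k <- length(point)
  if (is.null(names(point))) names(point) <- paste0("stat", seq_len(k))
  n <- nrow(cohort)
  reps <- matrix(NA_real_, n_reps, k, dimnames = list(NULL, names(point)))
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(n_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- cohort[idx, , drop = FALSE]
      attr(boot, "diseases") <- cohort_diseases(cohort)
      class(boot) <- class(cohort)
      val <- tryCatch(statistic(boot), error = function(e) NULL)
      if (!is.null(val) && length(val) == k && all(is.finite(val))) {
        reps[b, ] <- val
      }
    }
  })
  ok <- stats::complete.cases(reps)
  n_fail <- sum(!ok)
  if (sum(ok) < 2L) stop("bootstrap failed on nearly all replicates", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci_method == "normal") {
    sd_b <- apply(reps[ok, , drop = FALSE], 2L, stats::sd)
    lower <- point - z * sd_b
    upper <- point + z * sd_b
  } else {
    qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lower <- qs[1L, ]
    upper <- qs[2L, ]
  }
  out <- data.frame(statistic = names(point), point = unname(point),
                    lower = unname(lower), upper = unname(upper),
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  attr(out, "n_fail") <- n_fail
  attr(out, "flagged") <- n_fail > 0.1 * n_reps
  if (attr(out, "flagged")) {
    warning(sprintf("bootstrap: %d of %d replicates failed", n_fail, n_reps),
            call. = FALSE)
  }
  out
}
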