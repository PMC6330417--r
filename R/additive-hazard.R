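#' Parameters of the binomial additive hazard model
#'
#' The model for individual i is
#' \deqn{Y_i \sim Bernoulli(\pi_i), \quad \pi_i = 1 - e^{-\eta_i}, \quad
#'       \eta_i = \alpha_{ae} + \sum_d \gamma_c \delta_{de} X_{di}}
#' where \eqn{\alpha_{ae} \ge 0} is the background cumulative disability
#' rate for age band a and education e, and the age- and education-specific
#' disabling impact of disease d is factored (rank-one) as the product of a
#' shared age pattern \eqn{\gamma_c \ge 0} over four coarse age bands and a
#' disease-by-education effect \eqn{\delta_{de} \ge 0}.  The youngest-band
#' age pattern is fixed at 1 so that \eqn{\delta} is the impact at the
#' reference ages; this pins down the scale of the bilinear product.
#'
#' @param alpha 6 x 3 matrix (background band x education) of non-negative
#'   background cumulative rates.
#' @param gamma Length-4 non-negative age pattern with `gamma[1] == 1`.
#' @param delta m x 3 matrix (disease x education) of non-negative disease
#'   effects at reference age.
#' @param diseases Disease names (rownames of `delta`).
#' @return A `model_params` object.
#' @export
model_params <- function(alpha, gamma, delta, diseases = rownames(delta)) {
  alpha <- as.matrix(alpha)
  delta <- as.matrix(delta)
  if (is.null(diseases)) diseases <- paste0("disease_", seq_len(nrow(delta)))
  if (!identical(dim(alpha), c(6L, 3L))) {
    stop("`alpha` must be a 6 x 3 matrix (background band x education)", call. = FALSE)
  }
  if (length(gamma) != 4L) stop("`gamma` must have length 4", call. = FALSE)
  if (ncol(delta) != 3L) stop("`delta` must have 3 columns (education levels)", call. = FALSE)
  if (any(alpha < 0) || any(gamma < 0) || any(delta < 0)) {
    stop("all hazard parameters must be non-negative", call. = FALSE)
  }
  if (abs(gamma[1L] - 1) > 1e-12) {
    stop("`gamma[1]` is the reference age band and must equal 1", call. = FALSE)
  }
  dimnames(alpha) <- list(band_labels(background_bands()), education_levels())
  gamma <- as.numeric(gamma)
  names(gamma) <- band_labels(rank_bands())
  dimnames(delta) <- list(diseases, education_levels())
  structure(list(alpha = alpha, gamma = gamma, delta = delta),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Binomial additive hazard parameters\n")
  cat("Background cumulative rates (alpha):\n")
  print(round(x$alpha, 4))
  cat("Age pattern (gamma):\n")
  print(round(x$gamma, 4))
  cat("Disease effects at reference age (delta):\n")
  print(round(x$delta, 4))
  invisible(x)
}

#' Linear predictor (cumulative disability hazard) per record
#'
#' Computes \eqn{\eta_i = \alpha_{ae} + \gamma_c \sum_d \delta_{de} X_{di}}
#' for each record of a cohort; always non-negative because every parameter
#' is.
#'
#' @param params A [model_params()] object.
#' @param cohort A `survey_cohort` (single sex for a fitted model, but any
#'   rows are accepted: the parameters carry no sex index).
#' @return Numeric vector of cumulative hazards, one per record.
#' @export
linear_predictor <- function(params, cohort) {
  stopifnot(inherits(params, "model_params"))
  X <- disease_matrix(cohort)
  if (ncol(X) != nrow(params$delta)) {
    stop("cohort disease list does not match the model's delta matrix", call. = FALSE)
  }
  bg <- assign_band(cohort$age, background_bands())
  rk <- assign_band(cohort$age, rank_bands())
  edu <- match(cohort$education, education_levels())
  if (anyNA(edu)) stop("unknown education level in cohort", call. = FALSE)
  load <- rowSums(X * t(params$delta)[edu, , drop = FALSE])
  unname(params$alpha[cbind(bg, edu)] + params$gamma[rk] * load)
}

#' Disability probability from a cumulative hazard
#'
#' \eqn{\pi = 1 - e^{-\eta}}, evaluated with `expm1` for numerical accuracy
#' at small hazards.
#'
#' @param eta Non-negative cumulative hazard(s).
#' @return Probabilities in `[0, 1)`.
#' @examples
#' disability_prob(log(2)) # 0.5
#' @export
disability_prob <- function(eta) {
  if (any(eta < 0)) stop("cumulative hazard must be non-negative", call. = FALSE)
  -expm1(-eta)
}

#' Weighted negative log-likelihood of the additive hazard model
#'
#' \eqn{-\sum_i w_i [Y_i \log \pi_i + (1 - Y_i) \log(1 - \pi_i)]} with
#' \eqn{\log(1-\pi_i) = -\eta_i} exactly and \eqn{\pi_i} floored at 1e-12
#' so that a disabled record with zero hazard yields a large finite
#' penalty rather than `-Inf`.
#'
#' @param params A [model_params()] object.
#' @param cohort A `survey_cohort`.
#' @param use_weights If `TRUE` (default) sampling weights enter as
#'   frequency-style multipliers, normalized to mean 1.
#' @return The negative log pseudo-likelihood (a single number).
#' @export
neg_log_likelihood <- function(params, cohort, use_weights = TRUE) {
  assert_scalar_flag(use_weights, "use_weights")
  eta <- linear_predictor(params, cohort)
  pi <- pmax(disability_prob(eta), 1e-12)
  w <- if (use_weights) cohort$weight / mean(cohort$weight) else rep(1, nrow(cohort))
  y <- cohort$disability
  -sum(w * (y * log(pi) + (1 - y) * (-eta)))
}

# ---------------------------------------------------------------------------
# Fitting machinery.  Records are collapsed to unique
# (background band, rank band, education, disease pattern) cells with
# weight-of-disabled / weight-of-nondisabled sums: the weighted likelihood
# only depends on these aggregates, which makes evaluation cost independent
# of cohort size.

collapse_fit_data <- function(cohort, use_weights) {
  X <- disease_matrix(cohort)
  m <- ncol(X)
  bg <- assign_band(cohort$age, background_bands())
  rk <- assign_band(cohort$age, rank_bands())
  edu <- match(cohort$education, education_levels())
  w <- if (use_weights) cohort$weight / mean(cohort$weight) else rep(1, nrow(cohort))
  y <- cohort$disability
  pid <- as.vector(X %*% 2^(seq_len(m) - 1))
  key <- (((bg - 1) * 4 + (rk - 1)) * 3 + (edu - 1)) * 2^m + pid
  uk <- unique(key)
  gi <- match(key, uk)
  G <- length(uk)
  w1 <- as.vector(rowsum(w * y, gi))
  w0 <- as.vector(rowsum(w * (1 - y), gi))
  fo <- match(seq_len(G), gi)
  list(X = X[fo, , drop = FALSE], bg = bg[fo], rk = rk[fo], edu = edu[fo],
       w1 = w1, w0 = w0, m = m, G = G,
       n_obs = nrow(cohort), sum_weights = sum(cohort$weight))
}

# eta and the derivative of the NLL w.r.t. eta, per collapsed cell.
cell_eta <- function(dat, alpha, gamma, delta) {
  load <- rowSums(dat$X * t(delta)[dat$edu, , drop = FALSE])
  list(eta = alpha[cbind(dat$bg, dat$edu)] + gamma[dat$rk] * load, load = load)
}

cell_nll <- function(dat, eta) {
  pi <- pmax(-expm1(-eta), 1e-12)
  sum(dat$w0 * eta) - sum(dat$w1 * log(pi))
}

cell_dnll_deta <- function(dat, eta) {
  em <- exp(-eta)
  pi <- pmax(1 - em, 1e-12)
  dat$w0 - dat$w1 * em / pi
}

# Initial values: alpha from the weighted disability rate among the
# disease-free in each (band, education) cell; delta from crude
# with-versus-without hazard differences per disease and education, halved
# to discount multimorbidity double counting; gamma flat at 1.
initial_params <- function(dat, m) {
  alpha0 <- matrix(0, 6, 3)
  free_df <- rowSums(dat$X) == 0
  for (a in 1:6) for (e in 1:3) {
    sel <- dat$bg == a & dat$edu == e & free_df
    tot1 <- sum(dat$w1[sel]); tot0 <- sum(dat$w0[sel])
    if (tot1 + tot0 > 0) {
      p <- min(max(tot1 / (tot1 + tot0), 1e-4), 0.98)
      alpha0[a, e] <- -log(1 - p)
    } else {
      sel <- dat$bg == a & dat$edu == e
      tot1 <- sum(dat$w1[sel]); tot0 <- sum(dat$w0[sel])
      p <- if (tot1 + tot0 > 0) min(max(tot1 / (tot1 + tot0), 1e-4), 0.98) else 0.05
      alpha0[a, e] <- 0.5 * -log(1 - p)
    }
  }
  delta0 <- matrix(0.05, m, 3)
  for (e in 1:3) {
    sele <- dat$edu == e
    for (d in seq_len(m)) {
      has <- sele & dat$X[, d] == 1
      noth <- sele & dat$X[, d] == 0
      p1 <- sum(dat$w1[has]); t1 <- p1 + sum(dat$w0[has])
      p0 <- sum(dat$w1[noth]); t0 <- p0 + sum(dat$w0[noth])
      if (t1 > 0 && t0 > 0) {
        h1 <- -log(1 - min(max(p1 / t1, 1e-4), 0.98))
        h0 <- -log(1 - min(max(p0 / t0, 1e-4), 0.98))
        delta0[d, e] <- max((h1 - h0) / 2, 0.01)
      }
    }
  }
  list(alpha = alpha0, gamma = rep(1, 4), delta = delta0)
}

#' Fit the additive hazard model by constrained maximum likelihood
#'
#' Maximizes the weighted binomial likelihood over \eqn{\alpha \ge 0},
#' \eqn{\delta \ge 0} and \eqn{\gamma \ge 0} (with \eqn{\gamma_1 = 1}
#' fixed) by block-alternating bounded quasi-Newton (`L-BFGS-B`): holding
#' the age pattern fixed, the model is additive in \eqn{(\alpha, \delta)}
#' and solved under box constraints; holding \eqn{(\alpha, \delta)} fixed,
#' the free elements of \eqn{\gamma} are solved likewise; the blocks
#' alternate until the relative likelihood change falls below `tol`.
#' Multiple jittered starts guard against local optima of the bilinear
#' surface; the best likelihood is kept and the run is deterministic for a
#' given `seed`.
#'
#' The model is fitted for one sex at a time.  Diseases never observed in
#' an education stratum have the corresponding \eqn{\delta} pinned at 0,
#' and (band, education) cells with no respondents have \eqn{\alpha}
#' pinned at 0; both are reported in `boundary_flags`.
#'
#' @param cohort A `survey_cohort`.
#' @param sex `"male"` or `"female"`; the cohort is restricted to this sex.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum number of outer block iterations.
#' @param n_starts Number of initializations (first deterministic, rest
#'   jittered).
#' @param seed Seed for the jittered starts.
#' @param use_weights Use sampling weights in the likelihood (pseudo-ML).
#' @param warn_empty Warn when an education-by-band cell has no records.
#' @return An `ahaz_fit` with elements `params` ([model_params()]),
#'   `loglik`, `converged`, `n_iter`, `boundary_flags`, `n_obs`,
#'   `sum_weights` and the per-iteration `nll_trace` of the best start.
#' @export
fit_additive_hazard <- function(cohort, sex, tol = 1e-8, max_iter = 100L,
                                n_starts = 2L, seed = 1L, use_weights = TRUE,
                                warn_empty = TRUE) {
  stopifnot(inherits(cohort, "survey_cohort"))
  sex <- match.arg(sex, sex_levels())
  cohort <- filter_cohort(cohort, sex = sex)
  if (nrow(cohort) == 0L) stop("no records for sex ", sex, call. = FALSE)
  diseases <- cohort_diseases(cohort)
  m <- length(diseases)
  dat <- collapse_fit_data(cohort, use_weights)

  # cells pinned at zero
  wcell <- dat$w1 + dat$w0
  alpha_seen <- matrix(FALSE, 6, 3)
  for (g in seq_len(dat$G)) alpha_seen[dat$bg[g], dat$edu[g]] <- TRUE
  if (warn_empty && !all(alpha_seen)) {
    empty <- which(!alpha_seen, arr.ind = TRUE)
    warning(sprintf("%d education x age-band cell(s) contain no records; their background rates are pinned at 0",
                    nrow(empty)), call. = FALSE)
  }
  delta_seen <- matrix(FALSE, m, 3)
  for (e in 1:3) {
    sel <- dat$edu == e
    if (any(sel)) {
      delta_seen[, e] <- colSums(dat$X[sel, , drop = FALSE] * wcell[sel]) > 0
    }
  }
  alpha_free <- as.vector(alpha_seen)      # length 18
  delta_free <- as.vector(delta_seen)      # length 3m
  gamma_seen <- vapply(1:4, function(c) any(dat$rk == c), logical(1))
  gamma_free <- c(FALSE, gamma_seen[2:4])  # gamma_1 fixed at 1

  nll_ad <- function(theta, gamma) {
    alpha <- matrix(0, 6, 3); alpha[alpha_free] <- theta[seq_len(sum(alpha_free))]
    delta <- matrix(0, m, 3); delta[delta_free] <- theta[-seq_len(sum(alpha_free))]
    ce <- cell_eta(dat, alpha, gamma, delta)
    cell_nll(dat, ce$eta)
  }
  grad_ad <- function(theta, gamma) {
    alpha <- matrix(0, 6, 3); alpha[alpha_free] <- theta[seq_len(sum(alpha_free))]
    delta <- matrix(0, m, 3); delta[delta_free] <- theta[-seq_len(sum(alpha_free))]
    ce <- cell_eta(dat, alpha, gamma, delta)
    de <- cell_dnll_deta(dat, ce$eta)
    acell <- (dat$edu - 1L) * 6L + dat$bg
    ga <- numeric(18)
    agg <- rowsum(de, acell)
    ga[as.integer(rownames(agg))] <- agg[, 1L]
    gfac <- gamma[dat$rk]
    gd <- matrix(0, m, 3)
    for (e in 1:3) {
      sel <- dat$edu == e
      if (any(sel)) {
        gd[, e] <- crossprod(dat$X[sel, , drop = FALSE], de[sel] * gfac[sel])
      }
    }
    c(ga[alpha_free], as.vector(gd)[delta_free])
  }
  nll_g <- function(gfree, alpha, delta) {
    gamma <- c(1, gfree)
    ce <- cell_eta(dat, alpha, gamma, delta)
    cell_nll(dat, ce$eta)
  }
  grad_g <- function(gfree, alpha, delta) {
    gamma <- c(1, gfree)
    ce <- cell_eta(dat, alpha, gamma, delta)
    de <- cell_dnll_deta(dat, ce$eta)
    agg <- rowsum(de * ce$load, dat$rk)
    gg <- numeric(4)
    gg[as.integer(rownames(agg))] <- agg[, 1L]
    gg[2:4]
  }

  run_one <- function(init) {
    alpha <- init$alpha; gamma <- init$gamma; delta <- init$delta
    alpha[!alpha_seen] <- 0; delta[!delta_seen] <- 0
    nll <- cell_nll(dat, cell_eta(dat, alpha, gamma, delta)$eta)
    trace <- nll
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      theta0 <- c(as.vector(alpha)[alpha_free], as.vector(delta)[delta_free])
      oa <- stats::optim(theta0, fn = nll_ad, gr = grad_ad, gamma = gamma,
                         method = "L-BFGS-B", lower = 0,
                         control = list(maxit = 200L))
      alpha <- matrix(0, 6, 3); alpha[alpha_free] <- oa$par[seq_len(sum(alpha_free))]
      delta <- matrix(0, m, 3); delta[delta_free] <- oa$par[-seq_len(sum(alpha_free))]
      nll_new <- oa$value
      if (any(gamma_free)) {
        og <- stats::optim(gamma[2:4], fn = nll_g, gr = grad_g,
                           alpha = alpha, delta = delta,
                           method = "L-BFGS-B", lower = 0,
                           control = list(maxit = 200L))
        gamma <- c(1, og$par)
        nll_new <- og$value
      }
      trace <- c(trace, nll_new)
      if (nll_new > nll + 1e-6) {
        warning("likelihood decreased across a block iteration", call. = FALSE)
      }
      if (abs(nll - nll_new) < tol * (abs(nll_new) + 1)) {
        nll <- nll_new
        converged <- TRUE
        break
      }
      nll <- nll_new
    }
    list(alpha = alpha, gamma = gamma, delta = delta, nll = nll,
         converged = converged, n_iter = iter, trace = trace)
  }

  base_init <- initial_params(dat, m)
  inits <- list(base_init)
  if (n_starts > 1L) {
    with_seed(derive_seed(seed, "fit-starts"), {
      for (k in seq_len(n_starts - 1L)) {
        inits[[k + 1L]] <- list(
          alpha = base_init$alpha * exp(matrix(stats::rnorm(18, 0, 0.3), 6, 3)),
          gamma = c(1, pmax(base_init$gamma[2:4] * exp(stats::rnorm(3, 0, 0.2)), 0.1)),
          delta = base_init$delta * exp(matrix(stats::rnorm(3 * m, 0, 0.3), m, 3))
        )
      }
    })
  }
  fits <- lapply(inits, run_one)
  best <- fits[[which.min(vapply(fits, function(f) f$nll, numeric(1)))]]

  flags <- character(0)
  tolb <- 1e-8
  ai <- which(best$alpha < tolb | !alpha_seen, arr.ind = TRUE)
  if (nrow(ai)) {
    flags <- c(flags, sprintf("alpha[%s,%s]",
                              band_labels(background_bands())[ai[, 1]],
                              education_levels()[ai[, 2]]))
  }
  di <- which(best$delta < tolb | !delta_seen, arr.ind = TRUE)
  if (nrow(di)) {
    flags <- c(flags, sprintf("delta[%s,%s]", diseases[di[, 1]],
                              education_levels()[di[, 2]]))
  }
  structure(list(
    params = model_params(best$alpha, best$gamma, best$delta, diseases),
    loglik = -best$nll,
    converged = best$converged,
    n_iter = best$n_iter,
    boundary_flags = flags,
    n_obs = dat$n_obs,
    sum_weights = dat$sum_weights,
    nll_trace = best$trace,
    sex = sex
  ), class = "ahaz_fit")
}

#' @export
print.ahaz_fit <- function(x, ...) {
  cat(sprintf("Additive hazard fit (%s): n = %d, loglik = %.3f, %s after %d iterations\n",
              x$sex, x$n_obs, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  if (length(x$boundary_flags)) {
    cat("Parameters at the zero bound:", length(x$boundary_flags), "\n")
  }
  print(x$params)
  invisible(x)
}

#' Age-standardized disabling impacts
#'
#' The disabling impact of disease d for education e is the age-specific
#' cumulative disability rate \eqn{\beta_{cde} = \gamma_c \delta_{de}};
#' this reports its mean over a standard population's age structure, one
#' number per disease and education level.
#'
#' @param params A [model_params()] object.
#' @param std_pop Either a [std_population()] (its background-band weights
#'   are projected onto the four rank bands assuming uniform ages within
#'   bands) or a numeric vector of 4 non-negative rank-band weights.
#' @param sex Sex whose standard-population weights to use (ignored when
#'   `std_pop` is a plain weight vector).
#' @return m x 3 matrix of standardized impacts (disease x education).
#' @export
disabling_impact <- function(params, std_pop, sex = "male") {
  stopifnot(inherits(params, "model_params"))
  if (inherits(std_pop, "std_population")) {
    w <- project_to_rank_bands(std_weights(std_pop, sex))
  } else {
    stopifnot(is.numeric(std_pop), length(std_pop) == 4L, all(std_pop >= 0))
    w <- std_pop
  }
  gbar <- sum(params$gamma * w) / sum(w)
  params$delta * gbar
}
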