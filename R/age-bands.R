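#' Age groupings used by the additive hazard model
#'
#' The background cumulative disability rate varies over six age bands,
#' while the rank-one age pattern of the disease impacts varies over four
#' coarser bands.  Both groupings partition ages 25 and over into half-open
#' intervals `[lo, hi)`, so an age of exactly 40 falls in the 40+ band.
#'
#' @return A numeric vector of band breakpoints; the last interval is
#'   unbounded above (`Inf`).
#' @examples
#' background_bands()
#' rank_bands()
#' @export
background_bands <- function() c(25, 40, 50, 60, 70, 80, Inf)

#' @rdname background_bands
#' @export
rank_bands <- function() c(25, 40, 55, 70, Inf)

#' Human-readable labels for a set of age-band breakpoints
#'
#' @param breaks Band breakpoints as returned by [background_bands()] or
#'   [rank_bands()].
#' @return Character vector of labels such as `"25-39"` and `"80+"`.
#' @export
band_labels <- function(breaks) {
  k <- length(breaks) - 1L
  lab <- character(k)
  for (i in seq_len(k)) {
    lab[i] <- if (is.finite(breaks[i + 1L])) {
      sprintf("%d-%d", breaks[i], breaks[i + 1L] - 1L)
    } else {
      sprintf("%d+", breaks[i])
    }
  }
  lab
}

#' Assign ages to age bands
#'
#' Maps each age (in whole years) to the index of the unique half-open band
#' `[lo, hi)` containing it.
#'
#' @param age_years Integer vector of ages, all at least 25.
#' @param breaks Band breakpoints (see [background_bands()]).
#' @return Integer vector of band indices (1-based).
#' @examples
#' assign_band(c(39, 40, 85), background_bands())
#' @export
assign_band <- function(age_years, breaks) {
  if (!is.numeric(age_years) || anyNA(age_years)) {
    stop("`age_years` must be numeric with no missing values", call. = FALSE)
  }
  if (any(age_years < breaks[1L])) {
    stop(sprintf("ages below %d are outside the study population", breaks[1L]),
         call. = FALSE)
  }
  findInterval(age_years, breaks)
}

# Proportion of each background band falling in each rank band, assuming a
# uniform age distribution within background bands.  Only the [50,60)
# background band straddles a rank boundary (at 55); the open-ended 80+
# band lies wholly in the oldest rank band.
band_projection_matrix <- function() {
  M <- matrix(0, nrow = 6, ncol = 4,
              dimnames = list(band_labels(background_bands()),
                              band_labels(rank_bands())))
  M[1, 1] <- 1
  M[2, 2] <- 1
  M[3, 2] <- 0.5
  M[3, 3] <- 0.5
  M[4, 3] <- 1
  M[5, 4] <- 1
  M[6, 4] <- 1
  M
}

# Project weights on the 6 background bands onto the 4 rank bands.
project_to_rank_bands <- function(bg_weights) {
  stopifnot(length(bg_weights) == 6L)
  w <- as.vector(crossprod(band_projection_matrix(), bg_weights))
  names(w) <- band_labels(rank_bands())
  w
}
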