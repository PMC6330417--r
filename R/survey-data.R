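#' Chronic-condition groups analysed by default
#'
#' Thirteen groups of self-reported chronic conditions: spine disorders
#' (back/neck pain, deformity), arthritis, dementia, stroke, other
#' neurologic diseases, ischemic heart disease / peripheral artery disease,
#' other heart diseases, chronic obstructive pulmonary diseases,
#' psychiatric diseases, sensorial diseases, cancer, diabetes, and sequelae
#' of accidents.
#'
#' @return Character vector of 13 disease-group column names.
#' @export
disease_groups <- function() {
  c("spine_disorders", "arthritis", "dementia", "stroke", "neurologic",
    "ischemic_heart_pad", "other_heart", "copd", "psychiatric",
    "sensorial", "cancer", "diabetes", "accidents")
}

#' @rdname disease_groups
#' @export
education_levels <- function() c("low", "middle", "high")

sex_levels <- function() c("male", "female")

#' Construct a validated survey cohort
#'
#' A cohort is a plain `data.frame` with one row per respondent and columns
#' `id`, `sex` (`male`/`female`), `age` (whole years, 25+), `education`
#' (`low`/`middle`/`high` per ISCED 0-1 / 2-4 / 5-8), one 0/1 column per
#' chronic-disease group, `disability` (0/1, the GALI indicator with
#' "limited" or "severely limited" coded 1) and a positive sampling
#' `weight`.  The ordered disease list is stored as an attribute and fixes
#' the column order used internally.
#'
#' Rows with any missing or out-of-range field are rejected with messages
#' naming the offending row and field; no imputation is performed.
#'
#' @param df Data frame with the columns above.
#' @param diseases Ordered character vector of disease column names.
#' @return A `survey_cohort` data frame.
#' @export
survey_cohort <- function(df, diseases = disease_groups()) {
  required <- c("id", "sex", "age", "education", diseases, "disability", "weight")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  problems <- character(0)
  note <- function(rows, field, what) {
    if (length(rows) > 0L) {
      sprintf("row %d: %s %s", utils::head(rows, 5L), field, what)
    } else {
      character(0)
    }
  }
  df$id <- as.character(df$id)
  df$sex <- as.character(df$sex)
  df$education <- as.character(df$education)
  problems <- c(problems,
    note(which(is.na(df$sex) | !(df$sex %in% sex_levels())), "sex",
         "must be 'male' or 'female'"),
    note(which(is.na(df$age) | df$age < 25 | df$age != round(df$age)), "age",
         "must be a whole number of years, 25 or more"),
    note(which(is.na(df$education) | !(df$education %in% education_levels())),
         "education", "must be 'low', 'middle' or 'high'"),
    note(which(is.na(df$weight) | !is.finite(df$weight) | df$weight <= 0),
         "weight", "must be a positive number"))
  for (col in c(diseases, "disability")) {
    bad <- which(is.na(df[[col]]) | !(df[[col]] %in% c(0, 1)))
    problems <- c(problems, note(bad, col, "must be 0 or 1"))
  }
  if (length(problems) > 0L) {
    stop("invalid cohort rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df$age <- as.integer(df$age)
  for (col in c(diseases, "disability")) df[[col]] <- as.integer(df[[col]])
  attr(df, "diseases") <- diseases
  class(df) <- c("survey_cohort", "data.frame")
  df
}

#' Read or write a survey cohort as delimited text
#'
#' The on-disk format is a comma-delimited table with a header row
#' `id,sex,age,education,<disease columns>,disability,weight`.
#'
#' @param path Path to a CSV file.
#' @param diseases Ordered disease column names expected in the file.
#' @return `read_cohort()` returns a validated `survey_cohort`;
#'   `write_cohort()` invisibly returns `path`.
#' @export
read_cohort <- function(path, diseases = disease_groups()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- survey_cohort(df, diseases = diseases)
  message(sprintf("read %d survey records from %s", nrow(cohort), path))
  cohort
}

#' @rdname read_cohort
#' @param cohort A `survey_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "survey_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_diseases <- function(cohort) {
  d <- attr(cohort, "diseases")
  if (is.null(d)) stop("not a survey_cohort: missing disease attribute", call. = FALSE)
  d
}

disease_matrix <- function(cohort) {
  X <- as.matrix(as.data.frame(cohort)[cohort_diseases(cohort)])
  storage.mode(X) <- "double"
  X
}

filter_cohort <- function(cohort, sex = NULL, education = NULL, band = NULL) {
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(sex)) keep <- keep & cohort$sex %in% sex
  if (!is.null(education)) keep <- keep & cohort$education %in% education
  if (!is.null(band)) {
    keep <- keep & assign_band(cohort$age, background_bands()) %in% band
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "diseases") <- cohort_diseases(cohort)
  class(out) <- class(cohort)
  out
}

#' Standard population for direct age standardization
#'
#' Holds, per sex, the proportion of a reference population in each of the
#' six background age bands.  Weights are normalized to sum to one within
#' sex.  The on-disk format is comma-delimited with columns
#' `sex,band_lo,band_hi,weight` where the bands must coincide with
#' [background_bands()] (use `Inf` or an empty upper bound for the open
#' band).
#'
#' @param df Data frame with columns `sex`, `band_lo`, `band_hi`, `weight`.
#' @return A `std_population` object.
#' @export
std_population <- function(df) {
  required <- c("sex", "band_lo", "band_hi", "weight")
  if (!all(required %in% names(df))) {
    stop("standard population needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  breaks <- background_bands()
  labels <- band_labels(breaks)
  out <- list()
  for (s in unique(df$sex)) {
    if (!s %in% sex_levels()) stop("unknown sex in standard population: ", s, call. = FALSE)
    sub <- df[df$sex == s, , drop = FALSE]
    hi <- ifelse(is.na(sub$band_hi), Inf, sub$band_hi)
    idx <- match(paste(sub$band_lo, hi), paste(breaks[-7], breaks[-1]))
    if (anyNA(idx) || length(unique(idx)) != 6L) {
      stop("standard population bands must match the six background bands",
           call. = FALSE)
    }
    w <- numeric(6)
    w[idx] <- sub$weight
    if (any(w < 0) || sum(w) <= 0) {
      stop("standard population weights must be non-negative and not all zero",
           call. = FALSE)
    }
    names(w) <- labels
    out[[s]] <- w / sum(w)
  }
  structure(out, class = "std_population")
}

#' @rdname std_population
#' @param path Path to a standard-population CSV file.
#' @export
read_std_pop <- function(path) {
  if (!file.exists(path)) stop("standard population file not found: ", path, call. = FALSE)
  std_population(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname std_population
#' @param weights Numeric vector of 6 non-negative band weights applied to
#'   both sexes (a convenience for simulated analyses).
#' @export
std_pop_from_weights <- function(weights) {
  stopifnot(length(weights) == 6L)
  df <- data.frame(
    sex = rep(sex_levels(), each = 6L),
    band_lo = rep(background_bands()[-7], 2L),
    band_hi = rep(background_bands()[-1], 2L),
    weight = rep(weights, 2L)
  )
  std_population(df)
}

std_weights <- function(std_pop, sex) {
  stopifnot(inherits(std_pop, "std_population"))
  w <- std_pop[[sex]]
  if (is.null(w)) stop("standard population has no weights for sex: ", sex, call. = FALSE)
  w
}
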