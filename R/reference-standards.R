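# Growth and blood-pressure reference computations: LMS z-scores/percentiles
# for BMI-for-age and height-for-age, and a Fourth-Report-style polynomial
# blood-pressure reference giving age/sex/height-specific percentiles.

#' Load an LMS growth-reference table
#'
#' Reads a CSV table of LMS parameters (Box-Cox power `L`, median `M`,
#' coefficient of variation `S`) by sex and age in months, in the dialect
#' `sex, age_months, L, M, S`. The packaged defaults are synthetic smooth
#' tables covering 84-228 months (7-19 years) for both sexes; they are
#' plausible but are not the official WHO tables.
#'
#' @param path CSV file path.
#' @return a data.frame of class `lms_table` with columns
#'   `sex, age_months, L, M, S`.
#' @export
load_lms_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(tab))) {
    stopf("LMS table %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  tab$sex <- tolower(tab$sex)
  if (!all(tab$sex %in% c("male", "female"))) {
    bad <- which(!tab$sex %in% c("male", "female"))[1]
    stopf("LMS table %s line %d: sex must be male/female", path, bad + 1L)
  }
  for (col in c("age_months", "L", "M", "S")) {
    if (any(is.na(tab[[col]]))) {
      stopf("LMS table %s: missing values in column %s", path, col)
    }
  }
  if (any(tab$M <= 0)) stopf("LMS table %s: M must be > 0", path)
  if (any(tab$S <= 0)) stopf("LMS table %s: S must be > 0", path)
  for (s in unique(tab$sex)) {
    a <- tab$age_months[tab$sex == s]
    if (is.unsorted(a, strictly = TRUE)) {
      stopf("LMS table %s: age_months must be strictly increasing within sex %s", path, s)
    }
    if (min(a) > 84 || max(a) < 228) {
      stopf("LMS table %s: sex %s must span at least 84-228 months", path, s)
    }
  }
  class(tab) <- c("lms_table", "data.frame")
  tab
}

# Interpolate LMS parameters linearly in age (months), vectorized over
# (sex, age_months). No extrapolation outside the tabulated range.
lms_interp <- function(table, sex, age_months) {
  sex <- tolower(as.character(sex))
  n <- max(length(sex), length(age_months))
  sex <- rep_len(sex, n)
  age_months <- rep_len(age_months, n)
  out <- data.frame(L = rep(NA_real_, n), M = NA_real_, S = NA_real_)
  for (s in unique(sex)) {
    rows <- table[table$sex == s, , drop = FALSE]
    if (nrow(rows) == 0L) stopf("no LMS reference rows for sex '%s'", s)
    idx <- which(sex == s)
    a <- age_months[idx]
    if (any(a < min(rows$age_months) | a > max(rows$age_months), na.rm = TRUE)) {
      stopf("age %s months outside LMS reference range [%g, %g]",
            paste(a[a < min(rows$age_months) | a > max(rows$age_months)][1]),
            min(rows$age_months), max(rows$age_months))
    }
    for (col in c("L", "M", "S")) {
      out[[col]][idx] <- stats::approx(rows$age_months, rows[[col]], xout = a,
                                       method = "linear", ties = "ordered")$y
    }
  }
  out
}

# Core LMS transform: z = ((x/M)^L - 1) / (L*S), with the log limit at L = 0.
lms_z <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) < 1e-7, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

# Inverse LMS: the measurement at a given z-score.
lms_q <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) < 1e-7, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' BMI-for-age z-score and percentile by the LMS method
#'
#' Computes `z = ((bmi/M)^L - 1) / (L*S)` with the LMS row linearly
#' interpolated in age between tabulated months; ages outside the table are
#' an error (no extrapolation).
#'
#' @param bmi body-mass index, kg/m^2 (vectorized).
#' @param age_months age in months, within the table's coverage.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param table an `lms_table`, e.g. from [load_lms_table()].
#' @return numeric z-scores. `bmi_percentile()` returns `100 * pnorm(z)`.
#' @export
bmi_zscore <- function(bmi, age_months, sex, table) {
  if (any(bmi <= 0, na.rm = TRUE)) stopf("bmi must be positive")
  p <- lms_interp(table, sex, age_months)
  lms_z(bmi, p$L, p$M, p$S)
}

#' @rdname bmi_zscore
#' @export
bmi_percentile <- function(bmi, age_months, sex, table) {
  100 * stats::pnorm(bmi_zscore(bmi, age_months, sex, table))
}

#' BMI value at a given z-score or percentile of the reference
#'
#' Inverse of [bmi_zscore()]; used for the obesity bands of the BMI rubric
#' (e.g. 120% of the 95th-percentile BMI).
#'
#' @param z reference z-score.
#' @inheritParams bmi_zscore
#' @return BMI in kg/m^2.
#' @export
bmi_at_zscore <- function(z, age_months, sex, table) {
  p <- lms_interp(table, sex, age_months)
  lms_q(z, p$L, p$M, p$S)
}

#' Height-for-age z-score by the LMS method
#'
#' @param height_cm standing height in cm.
#' @inheritParams bmi_zscore
#' @return numeric z-scores.
#' @export
height_zscore <- function(height_cm, age_months, sex, table) {
  if (any(height_cm <= 0, na.rm = TRUE)) stopf("height must be positive")
  p <- lms_interp(table, sex, age_months)
  lms_z(height_cm, p$L, p$M, p$S)
}

#' Load blood-pressure reference models
#'
#' Reads a CSV in the dialect `sex, measure, term, coefficient` describing,
#' per (sex, measure), a polynomial regression of expected blood pressure on
#' centered age and height z-score:
#' `expected = intercept + sum_k age_k * (age - 10)^k + sum_k height_k * z^k`,
#' with a residual standard deviation `residual_sd` (mmHg). Terms are named
#' `intercept`, `age1`, `age2`, ..., `height1`, ..., `residual_sd`. This is
#' the Fourth-Report-style functional form behind pediatric blood-pressure
#' percentile tables; the packaged default coefficients are synthetic.
#'
#' @param path CSV file path.
#' @return nested list: `models[[sex]][[measure]]` with elements `intercept`,
#'   `age_coeffs`, `height_coeffs`, `residual_sd`.
#' @export
load_bp_models <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "measure", "term", "coefficient")
  if (!all(need %in% names(tab))) {
    stopf("BP reference %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  tab$sex <- tolower(tab$sex)
  tab$measure <- toupper(tab$measure)
  models <- list()
  for (s in unique(tab$sex)) {
    for (m in unique(tab$measure[tab$sex == s])) {
      rows <- tab[tab$sex == s & tab$measure == m, , drop = FALSE]
      terms <- stats::setNames(rows$coefficient, rows$term)
      if (is.na(terms["residual_sd"]) || terms[["residual_sd"]] <= 0) {
        stopf("BP reference %s: residual_sd must be > 0 for %s/%s", path, s, m)
      }
      get_poly <- function(prefix) {
        nm <- grep(paste0("^", prefix, "[0-9]+$"), names(terms), value = TRUE)
        if (length(nm) == 0L) return(numeric(0))
        k <- as.integer(sub(prefix, "", nm))
        coefs <- numeric(max(k))
        coefs[k] <- terms[nm]
        coefs
      }
      models[[s]][[m]] <- list(
        intercept = unname(terms[["intercept"]]),
        age_coeffs = get_poly("age"),
        height_coeffs = get_poly("height"),
        residual_sd = unname(terms[["residual_sd"]])
      )
    }
  }
  models
}

# Evaluate the expected BP for one model, vectorized over age/height_z.
bp_expected <- function(model, age_years, height_z) {
  out <- rep(model$intercept, length.out = max(length(age_years), length(height_z)))
  a <- age_years - 10
  for (k in seq_along(model$age_coeffs)) out <- out + model$age_coeffs[k] * a^k
  for (k in seq_along(model$height_coeffs)) out <- out + model$height_coeffs[k] * height_z^k
  out
}

#' Age-, sex- and height-specific blood-pressure percentile
#'
#' Percentile of an observed pressure under the reference model:
#' `100 * pnorm((bp - expected) / residual_sd)`.
#'
#' @param bp observed pressure, mmHg (vectorized).
#' @param age_years age in years (7-19).
#' @param sex `"male"` or `"female"`.
#' @param height_z height-for-age z-score, e.g. from [height_zscore()].
#' @param models BP reference models from [load_bp_models()].
#' @param measure `"SBP"` or `"DBP"`.
#' @return percentiles in (0, 100).
#' @export
bp_percentile <- function(bp, age_years, sex, height_z, models, measure = c("SBP", "DBP")) {
  measure <- match.arg(toupper(measure), c("SBP", "DBP"))
  sex <- tolower(as.character(sex))
  n <- max(length(bp), length(age_years), length(sex), length(height_z))
  bp <- rep_len(bp, n); age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n); height_z <- rep_len(height_z, n)
  out <- rep(NA_real_, n)
  for (s in unique(sex)) {
    model <- models[[s]][[measure]]
    if (is.null(model)) stopf("no BP reference model for sex '%s', measure %s", s, measure)
    idx <- which(sex == s)
    mu <- bp_expected(model, age_years[idx], height_z[idx])
    out[idx] <- 100 * stats::pnorm((bp[idx] - mu) / model$residual_sd)
  }
  out
}

# BP value at a given reference percentile (used by the stage-2 offset rule
# and by the synthetic generator's band preimages).
bp_at_percentile <- function(pct, age_years, sex, height_z, models, measure) {
  measure <- match.arg(toupper(measure), c("SBP", "DBP"))
  sex <- tolower(as.character(sex))
  n <- max(length(pct), length(age_years), length(sex), length(height_z))
  pct <- rep_len(pct, n); age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n); height_z <- rep_len(height_z, n)
  out <- rep(NA_real_, n)
  for (s in unique(sex)) {
    model <- models[[s]][[measure]]
    if (is.null(model)) stopf("no BP reference model for sex '%s', measure %s", s, measure)
    idx <- which(sex == s)
    mu <- bp_expected(model, age_years[idx], height_z[idx])
    out[idx] <- mu + stats::qnorm(pct[idx] / 100) * model$residual_sd
  }
  out
}

#' Load the full set of packaged (or user-supplied) reference tables
#'
#' @param bmi_lms,height_lms paths to LMS CSV tables; defaults to the
#'   packaged synthetic references.
#' @param bp path to the BP reference CSV; defaults to the packaged synthetic
#'   reference.
#' @return list with elements `bmi` (lms_table), `height` (lms_table),
#'   `bp` (BP model list).
#' @export
load_reference_tables <- function(bmi_lms = NULL, height_lms = NULL, bp = NULL) {
  list(
    bmi = load_lms_table(bmi_lms %||% cvh8_extdata("synthetic_bmi_lms.csv")),
    height = load_lms_table(height_lms %||% cvh8_extdata("synthetic_height_lms.csv")),
    bp = load_bp_models(bp %||% cvh8_extdata("synthetic_bp_reference.csv"))
  )
}
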