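# Synthetic multiwave cohort generator. Emulates the structure of an
# 11-wave (1989-2018) child/adolescent survey: urban/rural strata, 15
# provinces with staggered entry, blood measures only in the three
# biomarker waves, and component scores that follow known two-segment
# linear trends. Raw measurements are back-solved from target score bands
# (inverse-rubric sampling), so the ground-truth component scores are exact
# by construction.

CHNS_WAVES <- c(1989, 1991, 1993, 1997, 2000, 2004, 2006, 2009, 2011, 2015, 2018)

PROVINCE_ENTRY <- c(
  Heilongjiang = 1997, Liaoning = 1989, Jiangsu = 1989, Shandong = 1989,
  Henan = 1989, Hubei = 1989, Hunan = 1989, Guangxi = 1989, Guizhou = 1989,
  Beijing = 2011, Shanghai = 2011, Chongqing = 2011, Shaanxi = 2015,
  Zhejiang = 2015, Yunnan = 2015
)

DEFAULT_COMPONENT_BASELINES <- c(
  diet = 51, physical_activity = 70, nicotine = 95, sleep = 85,
  bmi = 90, lipids = 85, glucose = 95, blood_pressure = 90
)

#' Create a simulation scenario
#'
#' A scenario bundles wave structure, sample sizes, per-component score
#' trends, cross-lagged coefficients, and missingness rules.
#'
#' @param name scenario label.
#' @param waves survey years (default the 11 waves 1989-2018).
#' @param n_per_wave individuals per wave (cohort generation).
#' @param urban_fraction probability of urban residence.
#' @param trend_specs data.frame `component, stratum, baseline, break_year,
#'   slope_before, slope_after, noise_sd`; `break_year = NA` means a single
#'   linear segment. `component` may also be `"factor"` or `"behavior"`,
#'   which applies the trend to every member component.
#' @param clpm_spec data.frame `from, to, coefficient` of lagged paths for
#'   the community-level panel generator.
#' @param missing_spec list: `blood_waves` (waves with biomarkers),
#'   `pa_from` (first wave with physical-activity data), `random_rate` and
#'   `random_components` (per-record missingness).
#' @param seed default RNG seed for the generators.
#' @return list of class `cvh_scenario`.
#' @export
cvh_scenario <- function(name, waves = CHNS_WAVES, n_per_wave = 400L,
                         urban_fraction = 0.28, trend_specs = NULL,
                         clpm_spec = NULL, missing_spec = NULL, seed = 1L) {
  if (is.unsorted(waves, strictly = TRUE)) stopf("waves must be strictly increasing")
  if (!is.null(trend_specs)) {
    stopifnot(all(c("component", "stratum", "baseline", "break_year",
                    "slope_before", "slope_after", "noise_sd") %in% names(trend_specs)))
    if (any(trend_specs$noise_sd < 0)) stopf("noise_sd must be >= 0")
  }
  structure(list(
    name = name, waves = waves, n_per_wave = n_per_wave,
    urban_fraction = urban_fraction, trend_specs = trend_specs,
    clpm_spec = clpm_spec,
    missing_spec = missing_spec %||% list(blood_waves = c(2009, 2015, 2018),
                                          pa_from = 2000, random_rate = 0.02,
                                          random_components = c("sleep", "blood_pressure")),
    seed = seed
  ), class = "cvh_scenario")
}

trend_row <- function(component, stratum, baseline, break_year,
                      slope_before, slope_after, noise_sd = 0.3) {
  data.frame(component = component, stratum = stratum, baseline = baseline,
             break_year = break_year, slope_before = slope_before,
             slope_after = slope_after, noise_sd = noise_sd)
}

#' Packaged simulation scenarios
#'
#' Ground-truth trend parameters (break years and post-break slopes) and
#' cross-lagged coefficients follow the reported population trends this
#' package is designed to study; pre-break slopes and baselines, which are
#' not reported numerically, are fixed plausible choices (see the methods
#' vignette). The `clpm_fig4` scenario uses cross paths diet -> BMI 0.190
#' and BMI -> sleep 0.089 with all autoregressions 0.6.
#'
#' @return named list of [cvh_scenario()] objects.
#' @export
cvh_scenarios <- function() {
  sc <- list(
    rural_diet_trend = cvh_scenario("rural_diet_trend",
      trend_specs = trend_row("diet", "rural", 32, 1997, 0.5, -0.18)),
    urban_diet_trend = cvh_scenario("urban_diet_trend",
      trend_specs = trend_row("diet", "urban", 34, 1994, 0.5, -0.03)),
    rural_bmi_trend = cvh_scenario("rural_bmi_trend",
      trend_specs = trend_row("bmi", "rural", 90, 2005, 0.1, -0.56)),
    urban_bmi_trend = cvh_scenario("urban_bmi_trend",
      trend_specs = trend_row("bmi", "urban", 90, 2002, 0.1, -0.63)),
    sleep_trend_rural = cvh_scenario("sleep_trend_rural",
      trend_specs = trend_row("sleep", "rural", 85, NA, -0.69, NA)),
    sleep_trend_urban = cvh_scenario("sleep_trend_urban",
      trend_specs = trend_row("sleep", "urban", 85, NA, -0.69, NA)),
    rural_factor_trend = cvh_scenario("rural_factor_trend",
      trend_specs = trend_row("factor", "rural", 92, 2005, 0.1, -0.53)),
    urban_factor_trend = cvh_scenario("urban_factor_trend",
      trend_specs = trend_row("factor", "urban", 92, 2003, 0.1, -0.50)),
    clpm_fig4 = cvh_scenario("clpm_fig4",
      clpm_spec = rbind(
        data.frame(from = CLPM_VARS, to = CLPM_VARS, coefficient = 0.6),
        data.frame(from = c("diet", "bmi"), to = c("bmi", "sleep"),
                   coefficient = c(0.190, 0.089))
      ))
  )
  # demo: several trends plus the cross-lagged structure, for the pipeline
  sc$demo <- cvh_scenario("demo",
    n_per_wave = 300L,
    trend_specs = rbind(
      trend_row("diet", "rural", 32, 1997, 0.5, -0.18),
      trend_row("diet", "urban", 34, 1994, 0.5, -0.03),
      trend_row("bmi", "rural", 90, 2005, 0.1, -0.56),
      trend_row("bmi", "urban", 90, 2002, 0.1, -0.63),
      trend_row("sleep", "rural", 85, NA, -0.69, NA),
      trend_row("sleep", "urban", 85, NA, -0.69, NA)
    ),
    clpm_spec = sc$clpm_fig4$clpm_spec)
  sc
}

# Piecewise-linear trend mean at given years.
trend_mean <- function(spec_row, years) {
  t0 <- min(years)
  m <- spec_row$baseline + spec_row$slope_before * (years - t0)
  if (!is.na(spec_row$break_year)) {
    m <- m + (spec_row$slope_after - spec_row$slope_before) *
      pmax(years - spec_row$break_year, 0)
  }
  m
}

#' Generate an annual mean-score series from a scenario trend
#'
#' `mean(t) = baseline + s1 (t - t0) + (s2 - s1) max(t - break, 0) +
#' N(0, noise_sd^2 / n)`.
#'
#' @param scenario a [cvh_scenario()].
#' @param component,stratum which trend spec to use.
#' @param n_per_year notional per-year sample size (scales the noise on the
#'   annual mean and is used as the WLS weight downstream).
#' @param seed RNG seed (default the scenario's).
#' @return an [annual_series()].
#' @export
generate_trend_series <- function(scenario, component, stratum,
                                  n_per_year = 1L, seed = scenario$seed) {
  ts <- scenario$trend_specs
  row <- ts[ts$component == component & ts$stratum == stratum, , drop = FALSE]
  if (nrow(row) != 1L) {
    stopf("scenario '%s' has no trend spec for (%s, %s)", scenario$name, component, stratum)
  }
  years <- scenario$waves
  mu <- trend_mean(row[1, ], years)
  obs <- with_seed(seed, mu + stats::rnorm(length(years), 0, row$noise_sd / sqrt(n_per_year)))
  annual_series(years, obs, n = rep(as.integer(n_per_year), length(years)),
                se = rep(row$noise_sd / sqrt(n_per_year), length(years)),
                stratum = stratum)
}

# --- inverse-rubric samplers ---------------------------------------------

# Draw one of the two achievable scores adjacent to the target mean so that
# the expected score equals the target exactly.
draw_target_scores <- function(target, achievable, n) {
  achievable <- sort(achievable)
  target <- pmin(pmax(rep_len(target, n), min(achievable)), max(achievable))
  hi_idx <- pmin(findInterval(target, achievable, left.open = TRUE) + 1L, length(achievable))
  lo_idx <- pmax(hi_idx - 1L, 1L)
  lo <- achievable[lo_idx]; hi <- achievable[hi_idx]
  p_hi <- ifelse(hi > lo, (target - lo) / (hi - lo), 0)
  ifelse(stats::runif(n) < p_hi, hi, lo)
}

# Uniform draw inside [lo, hi) with a relative inset so measurement rounding
# cannot push a value across a band boundary.
runif_inset <- function(n, lo, hi, inset = 0.03) {
  pad <- (hi - lo) * inset
  stats::runif(n, lo + pad, hi - pad)
}

# score -> interval on a left-closed band table; the top band is capped.
band_preimage <- function(bands, score, top_cap) {
  i <- match(score, bands$points)
  lo <- bands$lower[i]
  hi <- ifelse(i < nrow(bands), bands$lower[i + 1L], top_cap)
  cbind(lo, hi)
}

#' Generate a synthetic participant cohort
#'
#' Individuals are drawn per wave with age ~ U(7, 19), balanced sex, the
#' configured urban fraction, and provinces honoring their survey entry
#' years. For each component, a target score is drawn around the scenario's
#' trend mean (components without a trend spec sit at fixed baselines) and
#' the raw measurements are back-solved into the corresponding rubric band's
#' preimage under `config`, so scoring the cohort with the same `config`
#' reproduces the intended scores exactly. Blood measures exist only in the
#' biomarker waves; physical activity only from its first collection wave.
#'
#' @param scenario a [cvh_scenario()].
#' @param config the scoring configuration the preimages are computed
#'   against (default packaged).
#' @param seed RNG seed (default the scenario's).
#' @return data.frame of participant records (see README column dictionary),
#'   with the intended component scores attached as attribute
#'   `"true_scores"`.
#' @export
generate_cohort <- function(scenario, config = le8_config(), seed = scenario$seed) {
  with_seed(seed, generate_cohort_impl(scenario, config))
}

generate_cohort_impl <- function(scenario, config) {
  rub <- config$rubrics
  refs <- config$references
  cuts <- config$diet_cutoffs
  waves <- scenario$waves
  npw <- rep_len(scenario$n_per_wave, length(waves))
  n <- sum(npw)
  if (n == 0L) stopf("scenario has no individuals (n_per_wave = 0 everywhere)")
  wave <- rep(waves, npw)

  urban <- stats::runif(n) < scenario$urban_fraction
  stratum <- ifelse(urban, "urban", "rural")
  province <- vapply(wave, function(t) {
    avail <- names(PROVINCE_ENTRY)[PROVINCE_ENTRY <= t]
    if (t == 1997) avail <- setdiff(avail, "Liaoning")
    sample(avail, 1L)
  }, character(1))
  community <- paste(province, stratum, sample.int(3L, n, replace = TRUE), sep = "_")
  age <- round(stats::runif(n, 7, 18.99), 1)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")

  # target score means per component
  targets <- matrix(rep(DEFAULT_COMPONENT_BASELINES, each = n), nrow = n,
                    dimnames = list(NULL, LE8_COMPONENTS))
  ts <- scenario$trend_specs
  if (!is.null(ts)) {
    for (r in seq_len(nrow(ts))) {
      comps <- switch(ts$component[r],
                      factor = FACTOR_COMPONENTS,
                      behavior = BEHAVIOR_COMPONENTS,
                      ts$component[r])
      idx <- stratum == ts$stratum[r]
      for (comp in comps) targets[idx, comp] <- trend_mean(ts[r, ], wave[idx])
    }
  }

  true_scores <- matrix(NA_real_, n, 8, dimnames = list(NULL, LE8_COMPONENTS))
  for (comp in LE8_COMPONENTS) {
    achievable <- switch(comp,
      diet = rub$diet$points,
      physical_activity = rub$physical_activity$bands$points,
      nicotine = sort(unique(c(rub$nicotine$categories,
                               pmax(rub$nicotine$categories - rub$nicotine$secondhand_penalty, 0)))),
      sleep = rub$sleep$bands$points,
      bmi = c(rub$bmi$percentile_bands$points, rub$bmi$ratio_bands$points),
      lipids = rub$lipids$bands$points,
      glucose = c(rub$glucose$fpg_bands$points, rub$glucose$hba1c_bands$points),
      blood_pressure = rub$blood_pressure$points)
    true_scores[, comp] <- draw_target_scores(targets[, comp], unique(achievable), n)
  }

  rec <- data.frame(id = sprintf("P%06d", seq_len(n)), wave_year = wave,
                    community = community, province = province, urban = urban,
                    age_years = age, sex = sex, stringsAsFactors = FALSE)

  # --- diet: adherence preimage w.r.t. the packaged cutoffs ---------------
  ac <- cuts$adherence_cutoffs
  g_names <- names(cuts$groups)
  adh_lo <- c(length(g_names), ac)           # totals live in [n_groups, 5*n_groups]
  adh_hi <- c(ac, 5 * length(g_names) + 1)
  di <- match(true_scores[, "diet"], rub$diet$points)
  total <- floor(stats::runif(n, pmax(adh_lo[di], length(g_names)),
                              pmin(adh_hi[di], 5 * length(g_names) + 1)))
  pts <- matrix(1L, n, length(g_names), dimnames = list(NULL, g_names))
  rem <- as.integer(total) - length(g_names)
  for (i in seq_len(n)) {
    while (rem[i] > 0L) {
      open <- which(pts[i, ] < 5L)
      j <- if (length(open) == 1L) open else sample(open, 1L)
      pts[i, j] <- pts[i, j] + 1L
      rem[i] <- rem[i] - 1L
    }
  }
  salt_day <- NULL
  for (g in g_names) {
    spec_g <- cuts$groups[[g]]
    edges <- c(spec_g$range[1], spec_g$cutoffs, spec_g$range[2])
    q <- if (spec_g$direction == "higher") pts[, g] else 6L - pts[, g]
    val <- runif_inset(n, edges[q], edges[q + 1L])
    if (g == "salt") salt_day <- val else rec[[paste0("food_", g)]] <- round(val, 1)
  }
  rec$energy_kcal <- round(stats::runif(n, 1200, 2600))
  rec$household_energy_kcal <- round(rec$energy_kcal * stats::runif(n, 2.5, 4))
  rec$household_salt_g <- round(salt_day * 3 * rec$household_energy_kcal / rec$energy_kcal, 2)
  rec$household_oil_g <- round(stats::runif(n, 100, 300), 1)

  # --- physical activity --------------------------------------------------
  pre <- band_preimage(rub$physical_activity$bands, true_scores[, "physical_activity"], 700)
  pa <- runif_inset(n, pre[, 1], pre[, 2])
  rec$pa_minutes_week <- ifelse(pre[, 2] <= 1, 0, round(pa))

  # --- nicotine ------------------------------------------------------------
  cats <- rub$nicotine$categories
  pen <- rub$nicotine$secondhand_penalty
  smoking <- character(n); secondhand <- logical(n)
  for (i in seq_len(n)) {
    s <- true_scores[i, "nicotine"]
    plain <- names(cats)[cats == s]
    penal <- names(cats)[pmax(cats - pen, 0) == s]
    if (length(plain)) { smoking[i] <- plain[1]; secondhand[i] <- FALSE }
    else { smoking[i] <- penal[1]; secondhand[i] <- TRUE }
  }
  rec$smoking <- smoking; rec$secondhand <- secondhand

  # --- sleep ---------------------------------------------------------------
  rec_hours <- sleep_recommendation(age, rub)
  pre <- band_preimage(rub$sleep$bands, true_scores[, "sleep"], 1.5)
  pre[, 1] <- pmax(pre[, 1], -4.5)
  # wide inset: hours are recorded to 0.1 h, which must not cross a band edge
  rec$sleep_hours <- round(rec_hours + runif_inset(n, pre[, 1], pre[, 2], inset = 0.08), 1)

  # --- bmi (and height/weight) ---------------------------------------------
  hz <- pmax(pmin(stats::rnorm(n), 2.5), -2.5)
  height <- round(lms_q(hz, 1, lms_interp(refs$height, sex, age * 12)$M,
                        lms_interp(refs$height, sex, age * 12)$S), 1)
  lms_b <- lms_interp(refs$bmi, sex, age * 12)
  p95 <- lms_q(stats::qnorm(0.95), lms_b$L, lms_b$M, lms_b$S)
  bmi <- numeric(n)
  s_bmi <- true_scores[, "bmi"]
  pb <- rub$bmi$percentile_bands
  for (band in seq_len(nrow(pb))) {
    i <- which(s_bmi == pb$points[band])
    if (!length(i)) next
    plo <- max(pb$lower[band], 5)
    phi <- if (band < nrow(pb)) pb$lower[band + 1L] else 95
    z <- stats::qnorm(runif_inset(length(i), plo, phi) / 100)
    bmi[i] <- lms_q(z, lms_b$L[i], lms_b$M[i], lms_b$S[i])
  }
  rb <- rub$bmi$ratio_bands
  pre <- band_preimage(rb, s_bmi, max(rb$lower) + 0.15)
  i <- which(s_bmi %in% rb$points & !s_bmi %in% pb$points)
  if (length(i)) bmi[i] <- runif_inset(length(i), pre[i, 1], pre[i, 2]) * p95[i]
  rec$height_cm <- height
  rec$weight_kg <- round(bmi * (height / 100)^2, 1)

  # --- blood pressure -------------------------------------------------------
  rbp <- rub$blood_pressure
  sbp <- dbp <- numeric(n)
  youth <- age < rbp$adult_age
  sd_s <- vapply(sex, function(s) refs$bp[[s]]$SBP$residual_sd, numeric(1))
  mu_s <- bp_at_percentile(50, age, sex, hz, refs$bp, "SBP")
  mu_d <- bp_at_percentile(50, age, sex, hz, refs$bp, "DBP")
  z95 <- stats::qnorm(0.95)
  z_lo <- c(-1.5, stats::qnorm(rbp$youth_percentiles / 100))
  s_bp <- true_scores[, "blood_pressure"]
  for (j in seq_along(rbp$points)) {
    i <- which(s_bp == rbp$points[j] & youth)
    if (length(i)) {
      z2 <- z95 + rbp$stage2_offset_mmhg / sd_s[i]
      zlo <- switch(j, rep(z_lo[1], length(i)), rep(z_lo[2], length(i)),
                    rep(z_lo[3], length(i)), z2)
      zhi <- switch(j, rep(z_lo[2], length(i)), rep(z_lo[3], length(i)), z2, z2 + 0.8)
      sbp[i] <- mu_s[i] + runif_inset(length(i), zlo, zhi) * sd_s[i]
      dbp[i] <- mu_d[i]
    }
    i <- which(s_bp == rbp$points[j] & !youth)
    if (length(i)) {
      edges <- c(95, rbp$adult_sbp, 160)
      sbp[i] <- runif_inset(length(i), edges[j], edges[j + 1L])
      dbp[i] <- runif_inset(length(i), 55, rbp$adult_dbp[1])
    }
  }
  rec$sbp_mmhg <- round(sbp, 1)
  rec$dbp_mmhg <- round(dbp, 1)

  # --- lipids ---------------------------------------------------------------
  pre <- band_preimage(rub$lipids$bands, true_scores[, "lipids"], 260)
  pre[, 1] <- pmax(pre[, 1], 90)
  rec$non_hdl_mgdl <- round(runif_inset(n, pre[, 1], pre[, 2]), 1)

  # --- glucose --------------------------------------------------------------
  s_gl <- true_scores[, "glucose"]
  fpg <- rep(NA_real_, n); a1c <- rep(NA_real_, n); dx <- rep(FALSE, n)
  fb <- rub$glucose$fpg_bands
  for (j in seq_len(nrow(fb))) {
    i <- which(s_gl == fb$points[j])
    lo <- max(fb$lower[j], 80)
    hi <- if (j < nrow(fb)) fb$lower[j + 1L] else rub$glucose$diabetes_fpg
    if (length(i)) fpg[i] <- runif_inset(length(i), lo, hi)
  }
  hb <- rub$glucose$hba1c_bands
  pre <- band_preimage(hb, s_gl, 12)
  i <- which(s_gl %in% hb$points & !s_gl %in% fb$points)
  if (length(i)) {
    dx[i] <- TRUE
    a1c[i] <- runif_inset(length(i), pmax(pre[i, 1], 6), pre[i, 2])
    fpg[i] <- stats::runif(length(i), 130, 220)
  }
  rec$fpg_mgdl <- round(fpg, 1)
  rec$hba1c_pct <- round(a1c, 2)
  rec$diabetes_dx <- dx

  # --- missingness ----------------------------------------------------------
  ms <- scenario$missing_spec
  blood_off <- !rec$wave_year %in% ms$blood_waves
  rec$non_hdl_mgdl[blood_off] <- NA
  rec$fpg_mgdl[blood_off] <- NA
  rec$hba1c_pct[blood_off] <- NA
  rec$diabetes_dx[blood_off] <- NA
  true_scores[blood_off, c("lipids", "glucose")] <- NA
  if (!is.null(ms$pa_from)) {
    off <- rec$wave_year < ms$pa_from
    rec$pa_minutes_week[off] <- NA
    true_scores[off, "physical_activity"] <- NA
  }
  if ((ms$random_rate %||% 0) > 0) {
    for (comp in ms$random_components %||% character(0)) {
      drop_i <- stats::runif(n) < ms$random_rate
      true_scores[drop_i, comp] <- NA
      cols <- switch(comp,
                     physical_activity = "pa_minutes_week",
                     sleep = "sleep_hours",
                     blood_pressure = c("sbp_mmhg", "dbp_mmhg"),
                     nicotine = "smoking",
                     lipids = "non_hdl_mgdl",
                     character(0))
      for (cl in cols) rec[[cl]][drop_i] <- NA
    }
  }
  attr(rec, "true_scores") <- true_scores
  rec
}

#' Generate a community-level cross-lagged panel with known coefficients
#'
#' Simulates a first-order vector-autoregressive block process
#' `X_{t+1} = A X_t + e`, with `A` taken from the scenario's `clpm_spec`,
#' residuals scaled so every variable has unit population variance, and
#' output standardized within block.
#'
#' @param scenario a [cvh_scenario()] with a `clpm_spec`.
#' @param n_units number of communities.
#' @param n_blocks number of wave blocks (default 3).
#' @param seed RNG seed (default the scenario's).
#' @return a `clpm_panel` data.frame.
#' @export
generate_clpm_panel <- function(scenario, n_units = 200L, n_blocks = 3L,
                                seed = scenario$seed) {
  spec <- scenario$clpm_spec
  if (is.null(spec)) stopf("scenario '%s' has no clpm_spec", scenario$name)
  vars <- CLPM_VARS
  A <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  A[cbind(match(spec$to, vars), match(spec$from, vars))] <- spec$coefficient
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stopf("unstable path matrix: spectral radius >= 1")
  }
  p <- length(vars)
  blocks <- paste0("B", seq_len(n_blocks))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_units * p), n_units, p, dimnames = list(NULL, vars))
    Sigma <- diag(p)
    out <- list(data.frame(unit = sprintf("C%04d", seq_len(n_units)), block = blocks[1], X))
    for (t in seq_len(n_blocks - 1L)) {
      pred_var <- diag(A %*% Sigma %*% t(A))
      resid_var <- 1 - pred_var
      if (any(resid_var <= 0)) stopf("clpm_spec implies variance >= 1 for some variable")
      E <- matrix(stats::rnorm(n_units * p), n_units, p) %*% diag(sqrt(resid_var))
      X <- X %*% t(A) + E
      colnames(X) <- vars
      Sigma <- A %*% Sigma %*% t(A) + diag(resid_var)
      out[[t + 1L]] <- data.frame(unit = sprintf("C%04d", seq_len(n_units)),
                                  block = blocks[t + 1L], X)
    }
    panel <- do.call(rbind, out)
    for (v in vars) {
      for (b in blocks) {
        i <- panel$block == b
        panel[[v]][i] <- as.numeric(scale(panel[[v]][i]))
      }
    }
    structure(panel[order(panel$unit, panel$block), ],
              class = c("clpm_panel", "data.frame"), vars = vars, n_dropped = 0L)
  })
}
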