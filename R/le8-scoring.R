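# Pediatric Life's Essential 8 component scoring. All functions are
# vectorized over records; missingness in an input makes the corresponding
# component score missing (NA), never an error.

BEHAVIOR_COMPONENTS <- c("diet", "physical_activity", "nicotine", "sleep")
FACTOR_COMPONENTS <- c("bmi", "lipids", "glucose", "blood_pressure")
LE8_COMPONENTS <- c(BEHAVIOR_COMPONENTS, FACTOR_COMPONENTS)

#' Allocate a household food total to one individual
#'
#' Household-weighed items (cooking oil, salt/condiments) are split across
#' household members in proportion to each member's share of household energy
#' intake.
#'
#' @param household_total household consumption over the survey window (g).
#' @param individual_energy individual energy intake (kcal/day).
#' @param household_energy household energy intake (kcal/day), > 0.
#' @return the individual's share (g, same window as `household_total`).
#' @export
allocate_household_intake <- function(household_total, individual_energy, household_energy) {
  if (any(household_energy <= 0, na.rm = TRUE)) {
    stopf("household energy must be positive to allocate intakes")
  }
  if (any(individual_energy < 0 | individual_energy > household_energy, na.rm = TRUE)) {
    stopf("individual energy must lie in [0, household energy]")
  }
  household_total * individual_energy / household_energy
}

#' Convert raw food items into food-group equivalents
#'
#' Maps raw items onto target food groups using multiplicative conversion
#' factors (e.g. soybean milk to its soybean equivalent by protein content).
#' Items absent from the table pass through under their own name, or raise an
#' error in strict mode.
#'
#' @param raw_intakes named numeric vector, item -> g/day.
#' @param conversion_table data.frame with columns `item, group, factor`.
#' @param strict error on unmapped items instead of passing them through.
#' @return named numeric vector, food group -> g/day.
#' @export
convert_food_equivalents <- function(raw_intakes, conversion_table, strict = FALSE) {
  if (length(raw_intakes) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(conversion_table$factor <= 0)) stopf("conversion factors must be positive")
  items <- names(raw_intakes)
  hit <- match(items, conversion_table$item)
  if (strict && any(is.na(hit))) {
    stopf("unmapped food item(s): %s", paste(items[is.na(hit)], collapse = ", "))
  }
  group <- ifelse(is.na(hit), items, conversion_table$group[hit])
  grams <- as.numeric(raw_intakes) * ifelse(is.na(hit), 1, conversion_table$factor[hit])
  out <- tapply(grams, group, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Diet adherence total from population quintile points
#'
#' Each food group contributes 1-5 points for the population intake quintile
#' it falls in (reversed for "less is better" groups such as salt and
#' sugar-sweetened beverages). Groups missing for an individual are averaged
#' out (the total is rescaled to the full group count) so totals stay
#' comparable; individuals missing every group get `NA`.
#'
#' @param intakes data.frame/list with one numeric element per food group
#'   (g/day).
#' @param cutoffs a `diet_cutoffs` object.
#' @return numeric adherence totals on the `8 * (1..5)` scale.
#' @export
diet_adherence <- function(intakes, cutoffs) {
  groups <- intersect(names(cutoffs$groups), names(intakes))
  if (length(groups) == 0L) stopf("no configured food group present in intakes")
  intakes <- as.data.frame(intakes)
  pts <- matrix(NA_real_, nrow = nrow(intakes), ncol = length(groups))
  for (j in seq_along(groups)) {
    g <- cutoffs$groups[[groups[j]]]
    idx <- findInterval(intakes[[groups[j]]], g$cutoffs) + 1L
    pts[, j] <- if (g$direction == "higher") idx else 6L - idx
  }
  n_cfg <- length(cutoffs$groups)
  rowMeans(pts, na.rm = TRUE) * n_cfg
}

#' Score the diet component (DASH-style population quintiles)
#'
#' The adherence total from [diet_adherence()] is mapped through the
#' population adherence quintile cutoffs to the configured rubric points
#' (default 0/25/50/80/100).
#'
#' @param food_groups data.frame/list of food-group intakes (g/day),
#'   including `salt` when available.
#' @param rubric an `le8_rubrics` object (its `diet` element is used).
#' @param cutoffs a `diet_cutoffs` object.
#' @return scores 0-100 (NA where no group observed).
#' @export
score_diet <- function(food_groups, rubric, cutoffs) {
  adh <- diet_adherence(food_groups, cutoffs)
  out <- rep(NA_real_, length(adh))
  ok <- !is.na(adh)
  out[ok] <- rubric$diet$points[findInterval(adh[ok], cutoffs$adherence_cutoffs) + 1L]
  out
}

#' Score weekly physical activity
#'
#' @param pa_minutes_week minutes of physical activity per week (>= 0).
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100.
#' @export
score_physical_activity <- function(pa_minutes_week, rubric) {
  if (any(pa_minutes_week < 0, na.rm = TRUE)) stopf("physical-activity minutes must be >= 0")
  out <- rep(NA_real_, length(pa_minutes_week))
  ok <- !is.na(pa_minutes_week)
  out[ok] <- band_points(pa_minutes_week[ok], rubric$physical_activity$bands)
  out
}

#' Score nicotine exposure
#'
#' Active-smoking category points with a secondhand-smoke penalty, clamped to
#' `[0, 100]`.
#'
#' @param smoking one of `"never"`, `"former_gt30d"`, `"current_le30d"`.
#' @param secondhand logical: lives with people who smoke.
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100.
#' @export
score_nicotine <- function(smoking, secondhand, rubric) {
  n <- max(length(smoking), length(secondhand))
  smoking <- rep_len(as.character(smoking), n)
  secondhand <- rep_len(secondhand, n)
  known <- names(rubric$nicotine$categories)
  bad <- !is.na(smoking) & !smoking %in% known
  if (any(bad)) stopf("unknown smoking category '%s'", smoking[bad][1])
  base <- rubric$nicotine$categories[smoking]
  pen <- ifelse(!is.na(secondhand) & secondhand, rubric$nicotine$secondhand_penalty, 0)
  pmin(pmax(unname(base) - pen, 0), 100)
}

# Recommended nightly sleep by age (schooling band).
sleep_recommendation <- function(age_years, rubric) {
  rec <- rubric$sleep$recommended
  if (any(age_years < min(rec$age_min) | age_years >= max(rec$age_max), na.rm = TRUE)) {
    stopf("age outside the sleep-recommendation bands [%g, %g)",
          min(rec$age_min), max(rec$age_max))
  }
  rec$hours[findInterval(age_years, rec$age_min)]
}

#' Score sleep duration against the age-specific recommendation
#'
#' The recommendation follows the Healthy China Initiative schooling bands
#' (default: 10 h for ages 7-12, 9 h for 13-15, 8 h for 16-19); the score
#' depends on the shortfall below the recommendation.
#'
#' @param sleep_hours nightly sleep (hours, in (0, 24)).
#' @param age_years age in years.
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100.
#' @export
score_sleep <- function(sleep_hours, age_years, rubric) {
  if (any(sleep_hours <= 0 | sleep_hours >= 24, na.rm = TRUE)) {
    stopf("sleep hours must be in (0, 24)")
  }
  n <- max(length(sleep_hours), length(age_years))
  sleep_hours <- rep_len(sleep_hours, n)
  age_years <- rep_len(age_years, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(sleep_hours) & !is.na(age_years)
  rec <- sleep_recommendation(age_years[ok], rubric)
  out[ok] <- band_points(sleep_hours[ok] - rec, rubric$sleep$bands)
  out
}

#' Score body-mass index from age/sex growth references
#'
#' BMI-for-age percentile bands below the 95th percentile; at or above it,
#' bands on the ratio of BMI to the 95th-percentile BMI (overweight/obesity
#' severity).
#'
#' @param bmi kg/m^2.
#' @param age_years age in years.
#' @param sex `"male"`/`"female"`.
#' @param references reference list from [load_reference_tables()].
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100.
#' @export
score_bmi <- function(bmi, age_years, sex, references, rubric) {
  n <- max(length(bmi), length(age_years), length(sex))
  bmi <- rep_len(bmi, n); age_years <- rep_len(age_years, n); sex <- rep_len(sex, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(bmi) & !is.na(age_years) & !is.na(sex)
  if (!any(ok)) return(out)
  months <- age_years[ok] * 12
  pct <- bmi_percentile(bmi[ok], months, sex[ok], references$bmi)
  p95 <- bmi_at_zscore(stats::qnorm(0.95), months, sex[ok], references$bmi)
  score <- rep(NA_real_, sum(ok))
  below <- bmi[ok] < p95
  score[below] <- band_points(pct[below], rubric$bmi$percentile_bands)
  score[!below] <- band_points(bmi[ok][!below] / p95[!below], rubric$bmi$ratio_bands)
  out[ok] <- score
  out
}

#' Score blood lipids (non-HDL cholesterol)
#'
#' @param non_hdl_mgdl non-HDL cholesterol, mg/dL.
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100 (NA when missing).
#' @export
score_lipids <- function(non_hdl_mgdl, rubric) {
  if (any(non_hdl_mgdl <= 0, na.rm = TRUE)) stopf("non-HDL cholesterol must be positive")
  out <- rep(NA_real_, length(non_hdl_mgdl))
  ok <- !is.na(non_hdl_mgdl)
  out[ok] <- band_points(non_hdl_mgdl[ok], rubric$lipids$bands)
  out
}

#' Score blood glucose
#'
#' Without diabetes (no diagnosis, FPG below the diabetic threshold): fasting
#' plasma glucose bands. With diabetes (doctor diagnosis, with precedence, or
#' FPG at/above the threshold): HbA1c severity bands. When only HbA1c is
#' observed, configurable HbA1c thresholds decide the track.
#'
#' @param fpg_mgdl fasting plasma glucose, mg/dL.
#' @param hba1c_pct glycated hemoglobin, %.
#' @param diabetes_dx logical doctor's diagnosis.
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100 (NA when all three inputs missing).
#' @export
score_glucose <- function(fpg_mgdl, hba1c_pct, diabetes_dx, rubric) {
  n <- max(length(fpg_mgdl), length(hba1c_pct), length(diabetes_dx))
  fpg <- rep_len(fpg_mgdl, n); a1c <- rep_len(hba1c_pct, n)
  dx <- rep_len(diabetes_dx, n)
  r <- rubric$glucose
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(fpg[i]) && is.na(a1c[i]) && is.na(dx[i])) next
    # diagnosis flag has precedence; otherwise FPG, then HbA1c, decides track
    diabetic <- if (!is.na(dx[i])) isTRUE(dx[i])
      else if (!is.na(fpg[i])) fpg[i] >= r$diabetes_fpg
      else a1c[i] >= r$nondiabetic_hba1c[2]
    if (diabetic) {
      out[i] <- if (!is.na(a1c[i])) band_points(a1c[i], r$hba1c_bands) else r$hba1c_bands$points[1]
    } else if (!is.na(fpg[i])) {
      out[i] <- band_points(min(fpg[i], r$diabetes_fpg - 1e-9), r$fpg_bands)
    } else if (!is.na(a1c[i])) {
      out[i] <- if (a1c[i] < r$nondiabetic_hba1c[1]) max(r$fpg_bands$points)
        else if (a1c[i] < r$nondiabetic_hba1c[2]) r$fpg_bands$points[2]
        else band_points(a1c[i], r$hba1c_bands)
    }
  }
  out
}

#' Score blood pressure (AAP-style categories)
#'
#' Below the configured adult age (default 13): categories from the worse of
#' the SBP/DBP age-sex-height percentiles (normal < 90th, elevated 90-95th,
#' stage 1 at/above 95th, stage 2 at/above the 95th-percentile pressure plus
#' an mmHg offset). From the adult age on: adult mmHg cutoffs
#' (120/130/140 systolic; 80/90 diastolic, elevated requires DBP < 80).
#'
#' @param sbp_mmhg,dbp_mmhg systolic/diastolic pressure, mmHg.
#' @param age_years age in years.
#' @param sex `"male"`/`"female"`.
#' @param height_z height-for-age z-score.
#' @param references reference list from [load_reference_tables()].
#' @param rubric an `le8_rubrics` object.
#' @return scores 0-100 (NA when either pressure missing).
#' @export
score_blood_pressure <- function(sbp_mmhg, dbp_mmhg, age_years, sex, height_z,
                                 references, rubric) {
  n <- max(length(sbp_mmhg), length(dbp_mmhg), length(age_years))
  sbp <- rep_len(sbp_mmhg, n); dbp <- rep_len(dbp_mmhg, n)
  age <- rep_len(age_years, n); sex <- rep_len(sex, n); hz <- rep_len(height_z, n)
  r <- rubric$blood_pressure
  out <- rep(NA_real_, n)
  ok <- !is.na(sbp) & !is.na(dbp) & !is.na(age) & !is.na(sex)
  if (!any(ok)) return(out)

  cat <- rep(NA_integer_, n)
  youth <- ok & age < r$adult_age
  if (any(youth)) {
    sp <- bp_percentile(sbp[youth], age[youth], sex[youth], hz[youth], references$bp, "SBP")
    dp <- bp_percentile(dbp[youth], age[youth], sex[youth], hz[youth], references$bp, "DBP")
    s95 <- bp_at_percentile(95, age[youth], sex[youth], hz[youth], references$bp, "SBP")
    d95 <- bp_at_percentile(95, age[youth], sex[youth], hz[youth], references$bp, "DBP")
    maxp <- pmax(sp, dp)
    cy <- 1L + findInterval(maxp, r$youth_percentiles)
    stage2 <- sbp[youth] >= s95 + r$stage2_offset_mmhg | dbp[youth] >= d95 + r$stage2_offset_mmhg
    cy[stage2] <- 4L
    cat[youth] <- cy
  }
  adult <- ok & age >= r$adult_age
  if (any(adult)) {
    cs <- 1L + findInterval(sbp[adult], r$adult_sbp)
    cd <- c(1L, 3L, 4L)[1L + findInterval(dbp[adult], r$adult_dbp)]
    cat[adult] <- pmax(cs, cd)
  }
  out[ok] <- r$points[cat[ok]]
  out
}

#' Compute all eight component scores for participant records
#'
#' Vectorized scoring of a record table (one row per child-wave observation;
#' see the column dictionary in the package README). BMI is recomputed from
#' height and weight (rounded to measurement precision, 0.1 cm / 0.1 kg) even
#' if a BMI column exists. Salt intake is allocated from household totals by
#' the individual-to-household energy ratio when household fields are
#' present; a `salt_g_day` column is used as a fallback. Missing inputs give
#' missing component scores, never errors.
#'
#' @param records data.frame of participant records.
#' @param config an [le8_config()] list.
#' @return data.frame with the records' `id` and `wave_year` (when present)
#'   and one 0-100 (or NA) column per component.
#' @export
component_scores <- function(records, config = le8_config()) {
  records <- as.data.frame(records)
  n <- nrow(records)
  col <- function(name, default = NA_real_) {
    if (name %in% names(records)) records[[name]] else rep(default, n)
  }
  rub <- config$rubrics

  # diet: food-group columns food_<group> plus salt allocated from household totals
  groups <- names(config$diet_cutoffs$groups)
  intakes <- as.data.frame(stats::setNames(
    lapply(setdiff(groups, "salt"), function(g) col(paste0("food_", g))),
    setdiff(groups, "salt")))
  hh_salt <- col("household_salt_g"); en <- col("energy_kcal"); hh_en <- col("household_energy_kcal")
  salt <- rep(NA_real_, n)
  okh <- !is.na(hh_salt) & !is.na(en) & !is.na(hh_en) & hh_en > 0
  salt[okh] <- allocate_household_intake(hh_salt[okh], pmin(en[okh], hh_en[okh]), hh_en[okh]) / 3
  fallback <- !okh & !is.na(col("salt_g_day"))
  salt[fallback] <- col("salt_g_day")[fallback]
  intakes$salt <- salt

  age <- col("age_years"); sex <- col("sex", NA_character_)
  height <- round(col("height_cm"), 1); weight <- round(col("weight_kg"), 1)
  bmi <- weight / (height / 100)^2
  hz <- rep(NA_real_, n)
  okh2 <- !is.na(height) & !is.na(age) & !is.na(sex)
  if (any(okh2)) hz[okh2] <- height_zscore(height[okh2], age[okh2] * 12, sex[okh2],
                                           config$references$height)

  smoking <- col("smoking", NA_character_)
  secondhand <- col("secondhand", NA)
  if (is.numeric(secondhand)) secondhand <- secondhand > 0
  dx <- col("diabetes_dx", NA)
  if (is.numeric(dx)) dx <- dx > 0

  out <- data.frame(
    diet = score_diet(intakes, rub, config$diet_cutoffs),
    physical_activity = score_physical_activity(col("pa_minutes_week"), rub),
    nicotine = score_nicotine(smoking, secondhand, rub),
    sleep = score_sleep(col("sleep_hours"), age, rub),
    bmi = score_bmi(bmi, age, sex, config$references, rub),
    lipids = score_lipids(col("non_hdl_mgdl"), rub),
    glucose = score_glucose(col("fpg_mgdl"), col("hba1c_pct"), dx, rub),
    blood_pressure = score_blood_pressure(col("sbp_mmhg"), col("dbp_mmhg"), age,
                                          sex, hz, config$references, rub)
  )
  keep <- intersect(c("id", "wave_year", "community", "province", "region", "urban",
                      "age_years", "sex"), names(records))
  cbind(records[keep], out)
}

#' Overall cardiovascular-health profile from component scores
#'
#' The overall score is the unweighted mean of the component scores present;
#' behavior and factor subscores are the means of their present members.
#' Records with fewer than `min_components` observed components are marked
#' excluded (scores NA). Categories: 80-100 high, 50-79 moderate, 0-49 low.
#'
#' @param scores data.frame containing the eight component columns (e.g. from
#'   [component_scores()]); extra columns are carried through.
#' @param min_components minimum observed components for inclusion
#'   (default 4).
#' @return the input with `n_components`, `included`, `overall`,
#'   `behavior_subscore`, `factor_subscore` and `category` appended.
#' @export
overall_cvh <- function(scores, min_components = 4L) {
  stopifnot(min_components >= 1L, min_components <= 8L)
  scores <- as.data.frame(scores)
  miss <- setdiff(LE8_COMPONENTS, names(scores))
  if (length(miss)) stopf("missing component columns: %s", paste(miss, collapse = ", "))
  comp <- as.matrix(scores[LE8_COMPONENTS])
  n_comp <- rowSums(!is.na(comp))
  included <- n_comp >= min_components
  overall <- ifelse(included, rowMeans(comp, na.rm = TRUE), NA_real_)
  behavior <- rowMeans(comp[, BEHAVIOR_COMPONENTS, drop = FALSE], na.rm = TRUE)
  factorsc <- rowMeans(comp[, FACTOR_COMPONENTS, drop = FALSE], na.rm = TRUE)
  behavior[is.nan(behavior) | !included] <- NA_real_
  factorsc[is.nan(factorsc) | !included] <- NA_real_
  category <- as.character(cut(overall, c(-Inf, 50, 80, Inf),
                               labels = c("low", "moderate", "high"), right = FALSE))
  cbind(scores,
        data.frame(n_components = n_comp, included = included, overall = overall,
                   behavior_subscore = behavior, factor_subscore = factorsc,
                   category = category, stringsAsFactors = FALSE))
}

#' Map provinces to the six geographical regions
#'
#' @param province character vector of province names.
#' @param mapping data.frame `province, region`; default packaged mapping of
#'   the 15 survey provinces.
#' @return character vector of region labels.
#' @export
assign_region <- function(province, mapping = NULL) {
  mapping <- mapping %||% load_region_map()
  idx <- match(province, mapping$province)
  if (any(is.na(idx) & !is.na(province))) {
    stopf("unknown province: %s", province[is.na(idx) & !is.na(province)][1])
  }
  mapping$region[idx]
}

#' Score records and build CVH profiles in one call
#'
#' Convenience wrapper: [component_scores()] followed by [overall_cvh()],
#' with regions assigned from provinces when available.
#'
#' @inheritParams component_scores
#' @inheritParams overall_cvh
#' @return scored profile data.frame.
#' @export
score_records <- function(records, config = le8_config(), min_components = 4L) {
  scored <- component_scores(records, config)
  if ("province" %in% names(scored) && !"region" %in% names(scored)) {
    scored$region <- assign_region(scored$province, config$region_map)
  }
  overall_cvh(scored, min_components)
}
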