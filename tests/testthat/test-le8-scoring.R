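# Component scoring, composites, inclusion filter, region mapping.

cfg <- le8_config()
rub <- cfg$rubrics

test_that("household allocation is proportional to the energy share", {
  expect_equal(allocate_household_intake(30, 600, 3000), 6)
  expect_equal(allocate_household_intake(30, 0, 3000), 0)
  expect_equal(allocate_household_intake(30, 3000, 3000), 30)
  expect_error(allocate_household_intake(30, 100, 0), "positive")
  expect_error(allocate_household_intake(30, 4000, 3000), "household energy")
})

test_that("food-equivalent conversion groups and sums intakes", {
  conv <- data.frame(item = c("soybean_milk", "soybean_flour", "yogurt"),
                     group = c("beans", "beans", "milk"),
                     factor = c(0.1, 0.8, 1.1))
  out <- convert_food_equivalents(c(soybean_milk = 200), conv)
  expect_equal(out[["beans"]], 20)
  expect_length(convert_food_equivalents(stats::setNames(numeric(0), character(0)), conv), 0)
  out <- convert_food_equivalents(c(soybean_milk = 200, soybean_flour = 25), conv)
  expect_equal(out[["beans"]], 20 + 20)
  out <- convert_food_equivalents(c(rice = 100), conv)
  expect_equal(out[["rice"]], 100)
  expect_error(convert_food_equivalents(c(rice = 100), conv, strict = TRUE), "unmapped")
})

test_that("diet score places individuals by population quintile rank", {
  # population of 1000 with perfectly rank-aligned intakes in every group
  n <- 1000
  groups <- load_diet_cutoffs()$groups
  intakes <- as.data.frame(lapply(names(groups), function(g) {
    r <- groups[[g]]$range
    v <- seq(r[1] + 0.01, r[2] - 0.01, length.out = n)
    if (groups[[g]]$direction == "lower") rev(v) else v
  }))
  names(intakes) <- names(groups)
  cuts <- estimate_diet_cutoffs(intakes)
  s <- score_diet(intakes, rub, cuts)
  expect_equal(s[n], 100)   # population maximum adherence
  expect_equal(s[1], 0)     # population minimum
  expect_equal(s[500], 50)  # middle quintile
  expect_true(all(s %in% rub$diet$points))
})

test_that("physical-activity bands are left-closed with the documented points", {
  expect_equal(score_physical_activity(430, rub), 100)
  expect_equal(score_physical_activity(0, rub), 0)
  expect_equal(score_physical_activity(360, rub), 90)
  expect_equal(score_physical_activity(359, rub), 80)
  expect_equal(score_physical_activity(c(1, 119, 120, 240, 300), rub),
               c(20, 20, 40, 60, 80))
  expect_error(score_physical_activity(-5, rub), ">= 0")
})

test_that("nicotine categories and the secondhand penalty clamp at zero", {
  expect_equal(score_nicotine("never", FALSE, rub), 100)
  expect_equal(score_nicotine("never", TRUE, rub), 80)
  expect_equal(score_nicotine("former_gt30d", TRUE, rub), 30)
  expect_equal(score_nicotine("current_le30d", TRUE, rub), 0)
  expect_error(score_nicotine("pipe", FALSE, rub), "unknown smoking")
})

test_that("sleep scores follow the schooling-band recommendations", {
  expect_equal(score_sleep(10, 10, rub), 100)   # primary school, meets 10 h
  expect_equal(score_sleep(8, 17, rub), 100)    # high school, meets 8 h
  expect_equal(score_sleep(7.5, 14, rub), 70)   # deficit 1.5 h
  expect_equal(score_sleep(9, 10, rub), 90)
  expect_equal(score_sleep(5, 10, rub), 0)      # deficit 5 h
  expect_error(score_sleep(0, 10, rub), "in \\(0, 24\\)")
  expect_error(score_sleep(8, 25, rub), "recommendation bands")
})

test_that("BMI score bands switch to severity ratios above the 95th percentile", {
  refs <- cfg$references
  m <- lms_at(refs$bmi, "male", 120)
  expect_equal(score_bmi(m$M, 10, "male", refs, rub), 100)
  p95 <- bmi_at_zscore(qnorm(0.95), 120, "male", refs$bmi)
  expect_equal(score_bmi(p95, 10, "male", refs, rub), 30)
  expect_equal(score_bmi(1.25 * p95, 10, "male", refs, rub), 15)
  expect_equal(score_bmi(1.5 * p95, 10, "male", refs, rub), 0)
  p85 <- bmi_at_zscore(qnorm(0.85), 120, "male", refs$bmi)
  expect_equal(score_bmi(p85 - 1e-6, 10, "male", refs, rub), 100)
  expect_equal(score_bmi(p85 + 1e-6, 10, "male", refs, rub), 70)
})

test_that("lipid and glucose bands follow the rubric thresholds", {
  expect_equal(score_lipids(94.9, rub), 100)
  expect_equal(score_lipids(c(130, 160, 190, 220, 400), rub), c(60, 40, 20, 0, 0))
  expect_true(is.na(score_lipids(NA, rub)))

  expect_equal(score_glucose(89.9, NA, FALSE, rub), 100)
  expect_equal(score_glucose(110, NA, FALSE, rub), 60)
  expect_equal(score_glucose(NA, 7.5, TRUE, rub), 30)
  expect_equal(score_glucose(NA, 9.5, TRUE, rub), 10)
  expect_equal(score_glucose(140, NA, NA, rub), 40)  # FPG in diabetic range, no dx known
  expect_true(is.na(score_glucose(NA, NA, NA, rub)))
})

test_that("blood-pressure categories use percentiles below 13 and adult cutoffs after", {
  refs <- list(bp = flat_bp_models(intercept_sbp = 100, intercept_dbp = 60, sd = 10))
  expect_equal(score_blood_pressure(100, 60, 10, "male", 0, refs, rub), 100)
  # 96th percentile systolic at age 10 -> stage 1
  s96 <- 100 + qnorm(0.96) * 10
  expect_equal(score_blood_pressure(s96, 60, 10, "male", 0, refs, rub), 50)
  # 92nd percentile -> elevated
  expect_equal(score_blood_pressure(100 + qnorm(0.92) * 10, 60, 10, "male", 0, refs, rub), 75)
  # stage 2: above the 95th-percentile pressure + 12 mmHg
  expect_equal(score_blood_pressure(100 + qnorm(0.95) * 10 + 13, 60, 10, "male", 0, refs, rub), 0)
  # adolescents: adult thresholds
  expect_equal(score_blood_pressure(125, 75, 15, "male", 0, refs, rub), 75)
  expect_equal(score_blood_pressure(118, 75, 15, "male", 0, refs, rub), 100)
  expect_equal(score_blood_pressure(118, 85, 15, "male", 0, refs, rub), 50)
  expect_equal(score_blood_pressure(142, 75, 15, "male", 0, refs, rub), 0)
  expect_true(is.na(score_blood_pressure(120, NA, 15, "male", 0, refs, rub)))
})

test_that("component_scores composes the individual scorers", {
  rec <- optimal_record(cfg)
  cs <- component_scores(rec, cfg)
  expect_true(all(as.numeric(cs[cvh8:::LE8_COMPONENTS]) == 100))
  # missing blood panel: lipids and glucose absent, six components remain
  rec2 <- rec
  rec2$non_hdl_mgdl <- NA; rec2$fpg_mgdl <- NA; rec2$diabetes_dx <- NA
  cs2 <- component_scores(rec2, cfg)
  expect_true(is.na(cs2$lipids) && is.na(cs2$glucose))
  expect_equal(sum(!is.na(cs2[cvh8:::LE8_COMPONENTS])), 6)
  # composition equals scoring each component independently
  expect_equal(cs$physical_activity, score_physical_activity(rec$pa_minutes_week, rub))
  expect_equal(cs$sleep, score_sleep(rec$sleep_hours, rec$age_years, rub))
  expect_equal(cs$lipids, score_lipids(rec$non_hdl_mgdl, rub))
  # scoring is pure: identical record and configuration, identical output
  expect_identical(cs, component_scores(optimal_record(cfg), cfg))
})

test_that("overall profile averages present components and applies the inclusion filter", {
  base <- as.data.frame(stats::setNames(as.list(rep(NA_real_, 8)), cvh8:::LE8_COMPONENTS))
  all100 <- base; all100[1, ] <- 100
  p <- overall_cvh(all100)
  expect_equal(p$overall, 100); expect_equal(p$category, "high")
  four <- base; four[1, c("diet", "sleep", "bmi", "lipids")] <- c(100, 50, 50, 0)
  p <- overall_cvh(four)
  expect_equal(p$overall, 50)
  expect_equal(p$category, "moderate")   # boundary 50 is moderate
  expect_equal(p$behavior_subscore, 75)
  expect_equal(p$factor_subscore, 25)
  three <- base; three[1, c("diet", "sleep", "bmi")] <- 100
  p <- overall_cvh(three)
  expect_false(p$included); expect_true(is.na(p$overall))
  # category boundaries at 49/50 and 79/80
  s <- base[rep(1, 4), ]; s$diet <- c(49.9, 50, 79.9, 80)
  s[c("physical_activity", "sleep", "bmi")] <- s$diet
  p <- overall_cvh(s, min_components = 4)
  expect_equal(p$category, c("low", "moderate", "moderate", "high"))
})

test_that("overall score is invariant to which components carry the values", {
  vals <- c(90, 60, 30, 75, 100)
  base <- stats::setNames(as.list(rep(NA_real_, 8)), cvh8:::LE8_COMPONENTS)
  set.seed(21)
  res <- replicate(10, {
    s <- as.data.frame(base)
    s[1, sample(cvh8:::LE8_COMPONENTS, 5)] <- sample(vals)
    overall_cvh(s)$overall
  })
  expect_true(all(abs(res - mean(vals)) < 1e-12))
})

test_that("a constant rubric scores every record at the constant", {
  cfg_c <- cfg
  cfg_c$rubrics$diet$points <- rep(60, 5)
  cfg_c$rubrics$physical_activity$bands$points[] <- 60
  cfg_c$rubrics$nicotine$categories[] <- 60
  cfg_c$rubrics$nicotine$secondhand_penalty <- 0
  cfg_c$rubrics$sleep$bands$points[] <- 60
  cfg_c$rubrics$bmi$percentile_bands$points[] <- 60
  cfg_c$rubrics$bmi$ratio_bands$points[] <- 60
  cfg_c$rubrics$lipids$bands$points[] <- 60
  cfg_c$rubrics$glucose$fpg_bands$points[] <- 60
  cfg_c$rubrics$glucose$hba1c_bands$points[] <- 60
  cfg_c$rubrics$blood_pressure$points[] <- 60
  scen <- cvh_scenarios()$demo
  scen$n_per_wave <- 30L
  coh <- generate_cohort(scen, seed = 8)
  prof <- score_records(coh, cfg_c)
  expect_true(all(abs(prof$overall[prof$included] - 60) < 1e-9))
})

test_that("provinces map onto the six regions", {
  expect_equal(assign_region("Shandong"), "East China")
  expect_equal(assign_region("Guizhou"), "Southwest China")
  expect_equal(assign_region("Heilongjiang"), "Northeast China")
  expect_equal(length(unique(load_region_map()$region)), 6)
  expect_error(assign_region("Atlantis"), "unknown province")
})
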