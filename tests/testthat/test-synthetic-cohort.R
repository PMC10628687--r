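# Synthetic cohort and panel generators.

test_that("trend series are exact piecewise lines without noise and reproducible", {
  scen <- cvh_scenarios()$rural_bmi_trend
  scen$trend_specs$noise_sd <- 0
  ser <- generate_trend_series(scen, "bmi", "rural", seed = 1)
  yrs <- scen$waves
  mu <- 90 + 0.1 * (yrs - 1989) + (-0.56 - 0.1) * pmax(yrs - 2005, 0)
  expect_equal(ser$mean, mu, tolerance = 1e-12)
  scen2 <- cvh_scenarios()$rural_bmi_trend
  expect_identical(generate_trend_series(scen2, "bmi", "rural", seed = 7),
                   generate_trend_series(scen2, "bmi", "rural", seed = 7))
  expect_error(generate_trend_series(scen2, "glucose", "rural"), "no trend spec")
})

test_that("empirical post-break slope of generated series matches the target", {
  scen <- cvh_scenarios()$urban_bmi_trend
  slopes <- vapply(1:300, function(s) {
    ser <- generate_trend_series(scen, "bmi", "urban", seed = s)
    post <- ser$year >= 2005
    coef(lm(ser$mean[post] ~ ser$year[post]))[2]
  }, numeric(1))
  mcse <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.63)), 2 * mcse + 1e-6)
})

test_that("generated cohorts score back to their ground-truth components exactly", {
  cfg <- le8_config()
  scen <- cvh_scenarios()$demo
  scen$n_per_wave <- 60L
  coh <- generate_cohort(scen, config = cfg, seed = 19)
  truth <- attr(coh, "true_scores")
  prof <- score_records(coh, cfg)
  for (comp in colnames(truth)) {
    ok <- !is.na(truth[, comp])
    expect_true(all(abs(prof[[comp]][ok] - truth[ok, comp]) < 1e-9), label = comp)
    expect_true(all(is.na(prof[[comp]][!ok])), label = paste(comp, "missing"))
  }
})

test_that("generated records satisfy the physiological and design invariants", {
  scen <- cvh_scenarios()$demo
  scen$n_per_wave <- 80L
  coh <- generate_cohort(scen, seed = 23)
  expect_true(all(coh$age_years >= 7 & coh$age_years < 19.01))
  expect_true(all(coh$sleep_hours > 0 & coh$sleep_hours < 24, na.rm = TRUE))
  expect_true(all(coh$height_cm > 100 & coh$height_cm < 210))
  bmi <- coh$weight_kg / (coh$height_cm / 100)^2
  expect_true(all(bmi > 10 & bmi < 45))
  expect_true(all(coh$sbp_mmhg > 70 & coh$sbp_mmhg < 180, na.rm = TRUE))
  expect_true(all(coh$pa_minutes_week >= 0, na.rm = TRUE))
  # biomarkers only in the blood waves; at most 6 components elsewhere
  blood <- coh$wave_year %in% c(2009, 2015, 2018)
  expect_true(all(is.na(coh$non_hdl_mgdl[!blood])))
  expect_true(all(is.na(coh$fpg_mgdl[!blood])))
  n_comp <- rowSums(!is.na(attr(coh, "true_scores")))
  expect_true(all(n_comp[!blood] <= 6))
  # physical activity only collected from 2000 on
  expect_true(all(is.na(coh$pa_minutes_week[coh$wave_year < 2000])))
  # provinces honor their entry years
  expect_false(any(coh$province == "Heilongjiang" & coh$wave_year < 1997))
  expect_false(any(coh$province == "Beijing" & coh$wave_year < 2011))
  expect_false(any(coh$province == "Liaoning" & coh$wave_year == 1997))
  # reproducibility
  c2 <- generate_cohort(scen, seed = 23)
  expect_identical(coh, c2)
})

test_that("clpm panels have unit-variance blocks and an analytic VAR covariance", {
  scen <- cvh_scenarios()$clpm_fig4
  pan <- generate_clpm_panel(scen, n_units = 150, seed = 2)
  for (b in unique(pan$block)) {
    expect_equal(mean(pan$diet[pan$block == b]), 0, tolerance = 1e-12)
    expect_equal(sd(pan$bmi[pan$block == b]), 1, tolerance = 1e-12)
  }
  expect_identical(pan, generate_clpm_panel(scen, n_units = 150, seed = 2))

  # A = 0: blocks independent
  null_scen <- cvh_scenario("null0", clpm_spec = data.frame(
    from = "diet", to = "diet", coefficient = 0))
  pan0 <- generate_clpm_panel(null_scen, n_units = 4000, seed = 3)
  w <- cvh8:::panel_wide(pan0, cvh8:::CLPM_VARS)
  cc <- cor(w[, "diet.B1"], w[, "diet.B2"])
  expect_lt(abs(cc), 0.05)

  # analytic lag-1 covariance of the VAR(1) process at large n
  big <- generate_clpm_panel(scen, n_units = 100000, seed = 4, n_blocks = 2)
  wb <- cvh8:::panel_wide(big, cvh8:::CLPM_VARS)
  A <- matrix(0, 5, 5, dimnames = list(cvh8:::CLPM_VARS, cvh8:::CLPM_VARS))
  A[cbind(match(scen$clpm_spec$to, rownames(A)),
          match(scen$clpm_spec$from, colnames(A)))] <- scen$clpm_spec$coefficient
  lag1 <- cov(wb[, 6:10], wb[, 1:5])  # cov(X2, X1) = A * I
  expect_lt(max(abs(lag1 - A)), 0.01)

  # unstable systems are rejected
  bad <- cvh_scenario("bad", clpm_spec = data.frame(
    from = cvh8:::CLPM_VARS, to = cvh8:::CLPM_VARS, coefficient = 1.05))
  expect_error(generate_clpm_panel(bad, n_units = 50), "unstable")
})

test_that("cross-path recovery is insensitive to the autoregression strength", {
  for (auto in c(0.3, 0.8)) {
    spec <- rbind(
      data.frame(from = cvh8:::CLPM_VARS, to = cvh8:::CLPM_VARS, coefficient = auto),
      data.frame(from = "diet", to = "bmi", coefficient = 0.19))
    scen <- cvh_scenario(paste0("auto", auto), clpm_spec = spec)
    est <- vapply(1:60, function(s) {
      pan <- generate_clpm_panel(scen, n_units = 200, seed = s)
      p <- fit_clpm(pan)$paths
      p$estimate[p$from == "diet" & p$to == "bmi" & p$from_block == "B1"]
    }, numeric(1))
    expect_lt(abs(mean(est) - 0.19), 0.02)
  }
})

test_that("an empty wave is simply absent from the cohort", {
  scen <- cvh_scenarios()$demo
  scen$n_per_wave <- c(0L, rep(40L, 10))
  coh <- generate_cohort(scen, seed = 5)
  expect_false(1989 %in% coh$wave_year)
  expect_equal(nrow(coh), 400)
})
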