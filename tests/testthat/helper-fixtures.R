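# Shared fixtures built in code.

# Minimal LMS table: two ages per sex, simple round numbers.
tiny_lms <- function(L = c(-1.6, -1.4), M = c(16, 20), S = c(0.11, 0.13)) {
  tab <- rbind(
    data.frame(sex = "male", age_months = c(84, 228), L = L, M = M, S = S),
    data.frame(sex = "female", age_months = c(84, 228), L = L, M = M + 0.2, S = S)
  )
  class(tab) <- c("lms_table", "data.frame")
  tab
}

# BP model with only an intercept: percentile depends on (bp - intercept)/sd.
flat_bp_models <- function(intercept_sbp = 100, intercept_dbp = 60, sd = 10) {
  m <- function(int) list(intercept = int, age_coeffs = numeric(0),
                          height_coeffs = numeric(0), residual_sd = sd)
  list(male = list(SBP = m(intercept_sbp), DBP = m(intercept_dbp)),
       female = list(SBP = m(intercept_sbp), DBP = m(intercept_dbp)))
}

# One fully-observed record with optimal values for every component.
optimal_record <- function(cfg = le8_config()) {
  cuts <- cfg$diet_cutoffs$groups
  rec <- data.frame(id = "r1", wave_year = 2009, community = "Hubei_rural_1",
                    province = "Hubei", urban = FALSE, age_years = 10, sex = "male",
                    energy_kcal = 2000, household_energy_kcal = 6000,
                    household_oil_g = 150,
                    pa_minutes_week = 500, smoking = "never", secondhand = FALSE,
                    sleep_hours = 10.5, height_cm = 138, weight_kg = 31,
                    sbp_mmhg = 100, dbp_mmhg = 60, non_hdl_mgdl = 95,
                    fpg_mgdl = 90, hba1c_pct = NA_real_, diabetes_dx = FALSE,
                    stringsAsFactors = FALSE)
  for (g in setdiff(names(cuts), "salt")) {
    rec[[paste0("food_", g)]] <- cuts[[g]]$cutoffs[4] * 1.2  # top quintile
  }
  # salt in the lowest quintile: household total back-solved from the share
  rec$household_salt_g <- cuts$salt$cutoffs[1] * 0.5 * 3 *
    rec$household_energy_kcal / rec$energy_kcal
  # weight set so BMI sits at the reference median
  m <- lms_at(cfg$references$bmi, "male", 120)
  rec$weight_kg <- round(m$M * (rec$height_cm / 100)^2, 1)
  rec
}

# LMS parameters at a tabulated age (test-side interpolation-free lookup).
lms_at <- function(tab, sex, age_months) {
  row <- tab[tab$sex == sex & tab$age_months == age_months, ]
  stopifnot(nrow(row) == 1)
  row
}

# Brute-force Fisher-Jenks oracle: enumerate all contiguous partitions.
brute_jenks_ss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  for (cc in cuts) {
    idx <- c(0, cc, n)
    tot <- sum(vapply(seq_len(k), function(i) ss(x[(idx[i] + 1):idx[i + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}
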