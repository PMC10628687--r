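# Panel construction, CLPM estimation, fit indices.

make_panel <- function(df, vars) {
  structure(df, class = c("clpm_panel", "data.frame"), vars = vars, n_dropped = 0L)
}

test_that("build_panel aggregates unit-block means and standardizes within block", {
  rec <- expand.grid(community = c("u1", "u2", "u3"),
                     wave_year = c(2006, 2011, 2015), rep = 1:2)
  rec$diet <- c(10, 20, 30)[match(rec$community, c("u1", "u2", "u3"))] +
    5 * (rec$wave_year == 2011) + (rec$rep - 1) * 2
  for (v in c("physical_activity", "sleep", "bmi", "blood_pressure")) {
    rec[[v]] <- rec$diet / 2
  }
  pan <- build_panel(rec, min_units = 3L)
  # hand calculation: unit means are base + 1 (rep adds 0 or 2) per block
  b1 <- pan[pan$block == "B1", ]
  expect_equal(b1$diet[order(b1$unit)], as.numeric(scale(c(11, 21, 31))))
  expect_equal(mean(pan$bmi[pan$block == "B2"]), 0, tolerance = 1e-12)
  expect_equal(sd(pan$bmi[pan$block == "B2"]), 1, tolerance = 1e-12)
})

test_that("units missing a block are retained for the transitions they cover", {
  set.seed(5)
  rec <- expand.grid(community = sprintf("u%02d", 1:12),
                     wave_year = c(2006, 2011, 2015))
  for (v in cvh8:::CLPM_VARS) rec[[v]] <- rnorm(nrow(rec), 70, 5)
  rec <- rec[!(rec$community %in% c("u01", "u02") & rec$wave_year == 2015), ]
  rec1 <- rec[rec$community == "u03" & rec$wave_year == 2006, ]
  expect_message(pan <- build_panel(rbind(rec,
    data.frame(community = "solo", wave_year = 2006,
               rec1[cvh8:::CLPM_VARS])), min_units = 10L), "dropped")
  expect_false("solo" %in% pan$unit)
  expect_true(all(c("u01", "u02") %in% pan$unit))
  expect_error(build_panel(rec[rec$community %in% c("u01", "u02"), ], min_units = 10L),
               "unit\\(s\\) retained")
})

test_that("fit indices match direct formula evaluation and clamp correctly", {
  f <- fit_indices(20, 10, 200, 20, 101)
  expect_equal(f$CFI, 1 - 10 / 180)
  expect_equal(f$TLI, (200 / 20 - 20 / 10) / (200 / 20 - 1))
  expect_equal(f$RMSEA, sqrt(10 / (10 * 100)))
  # exact fit
  f <- fit_indices(10, 10, 200, 20, 101)
  expect_equal(f$CFI, 1); expect_equal(f$RMSEA, 0)
  # baseline no worse than model: CFI stays in [0, 1]
  f <- fit_indices(50, 10, 30, 20, 101)
  expect_gte(f$CFI, 0); expect_lte(f$CFI, 1)
  # saturated flag
  f <- fit_indices(0, 0, 200, 20, 101)
  expect_true(f$saturated); expect_equal(f$TLI, 1)
})

test_that("estimates reproduce an analytically constructed covariance exactly", {
  vars <- cvh8:::CLPM_VARS
  p <- length(vars)
  A <- diag(0.6, p); dimnames(A) <- list(vars, vars)
  A["bmi", "diet"] <- 0.19
  A["sleep", "bmi"] <- 0.089
  S11 <- diag(p)
  Psi <- diag(1 - diag(A %*% t(A)))
  Sigma <- rbind(cbind(S11, t(A)), cbind(A, A %*% t(A) + Psi))
  # data whose sample covariance equals Sigma exactly
  set.seed(2)
  n <- 400
  Z <- matrix(rnorm(n * 2 * p), n, 2 * p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(stats::cov(Z))) %*% chol(Sigma)
  colnames(Z) <- c(vars, vars)
  pan <- make_panel(
    data.frame(unit = rep(sprintf("c%03d", 1:n), 2),
               block = rep(c("B1", "B2"), each = n),
               rbind(Z[, 1:p], Z[, p + 1:p])), vars)
  res <- fit_clpm(pan)
  est <- res$paths
  expect_equal(est$estimate[est$from == "diet" & est$to == "bmi"], 0.19, tolerance = 1e-6)
  expect_equal(est$estimate[est$from == "bmi" & est$to == "sleep"], 0.089, tolerance = 1e-6)
  expect_equal(est$estimate[est$from == "diet" & est$to == "diet"], 0.6, tolerance = 1e-6)
  expect_equal(est$estimate[est$from == "sleep" & est$to == "bmi"], 0, tolerance = 1e-6)
})

test_that("a saturated path model attains perfect fit", {
  vars <- cvh8:::CLPM_VARS
  set.seed(9)
  n <- 150
  pan <- make_panel(
    data.frame(unit = rep(sprintf("c%03d", 1:n), 2),
               block = rep(c("B1", "B2"), each = n),
               matrix(rnorm(2 * n * 5), 2 * n, 5, dimnames = list(NULL, vars))),
    vars)
  all_paths <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  res <- fit_clpm(pan, paths = all_paths, residual_cov = "free")
  expect_equal(res$fit$df, 0)
  expect_lt(abs(res$fit$chi_square), 1e-6)
  expect_equal(res$fit$CFI, 1); expect_equal(res$fit$TLI, 1)
  expect_equal(res$fit$RMSEA, 0)
  expect_true(res$fit$saturated)
})

test_that("null cross paths are covered by their confidence intervals", {
  scen <- cvh_scenario("null", clpm_spec = data.frame(
    from = cvh8:::CLPM_VARS, to = cvh8:::CLPM_VARS, coefficient = 0.5))
  cover <- vapply(1:100, function(s) {
    pan <- generate_clpm_panel(scen, n_units = 120, seed = s)
    est <- fit_clpm(pan)$paths
    row <- est[est$from == "diet" & est$to == "bmi" & est$from_block == "B1", ]
    row$ci_lower <= 0 && 0 <= row$ci_upper
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("standardized paths are invariant to affine rescaling of inputs", {
  set.seed(14)
  rec <- expand.grid(community = sprintf("u%02d", 1:30),
                     wave_year = c(2006, 2011, 2015))
  for (v in cvh8:::CLPM_VARS) rec[[v]] <- rnorm(nrow(rec), 70, 8)
  rec2 <- rec
  rec2$diet <- 3 + 10 * rec2$diet
  rec2$bmi <- 100 - 0 + 0.2 * rec2$bmi
  f1 <- fit_clpm(build_panel(rec, min_units = 10L))
  f2 <- fit_clpm(build_panel(rec2, min_units = 10L))
  expect_equal(f1$paths$estimate, f2$paths$estimate, tolerance = 1e-9)
})

test_that("collinear predictors raise an estimation error naming the pair", {
  vars <- cvh8:::CLPM_VARS
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, vars))
  X[, "diet"] <- X[, "bmi"]  # exactly collinear
  Y <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, vars))
  pan <- make_panel(
    data.frame(unit = rep(sprintf("c%03d", 1:n), 2),
               block = rep(c("B1", "B2"), each = n), rbind(X, Y)), vars)
  expect_error(fit_clpm(pan), "collinear")
})
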