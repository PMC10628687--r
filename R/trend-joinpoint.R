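# Joinpoint (segmented linear) regression of annual mean scores: age/sex
# adjusted annual means, continuous piecewise-linear weighted least squares
# with a grid search over candidate break years, and permutation-based
# selection of the number of joinpoints.

#' Construct an annual series
#'
#' @param years calendar years (strictly increasing).
#' @param means mean score per year.
#' @param n sample size per year (used as WLS weight).
#' @param se standard error per year.
#' @param stratum label (e.g. `"rural"`).
#' @return data.frame of class `annual_series`.
#' @export
annual_series <- function(years, means, n = rep(1L, length(years)),
                          se = rep(NA_real_, length(years)), stratum = "all") {
  if (is.unsorted(years, strictly = TRUE)) stopf("years must be strictly increasing")
  if (any(n < 1)) stopf("per-year n must be >= 1")
  structure(data.frame(stratum = stratum, year = years, mean = means, n = n, se = se),
            class = c("annual_series", "data.frame"))
}

#' Age- and sex-adjusted annual mean scores
#'
#' Per stratum, fits a linear model of the score on wave-year indicators plus
#' age and sex, and reports each year's prediction at the pooled covariate
#' reference (overall mean age, sexes balanced 50/50), with model-based
#' standard errors. With a single observed sex the sex term is dropped.
#'
#' @param data scored records (e.g. from [score_records()]) with columns
#'   `wave_year`, `age_years`, `sex` and the score.
#' @param score name of the score column (e.g. `"diet"` or `"overall"`).
#' @param stratum optional `"urban"`/`"rural"` filter applied via the
#'   logical/0-1 `urban` column; `NULL` uses all records.
#' @return an [annual_series()].
#' @export
adjusted_annual_means <- function(data, score, stratum = NULL) {
  data <- as.data.frame(data)
  if (!score %in% names(data)) stopf("no column '%s' in data", score)
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, c("urban", "rural"))
    urb <- if (is.logical(data$urban)) data$urban else data$urban > 0
    data <- data[if (stratum == "urban") urb else !urb, , drop = FALSE]
  }
  df <- data.frame(y = data[[score]], year = data$wave_year,
                   age = data$age_years, sex = as.character(data$sex))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$year)) < 2L) stopf("need >= 2 distinct years")
  df$year <- factor(df$year)
  use_sex <- length(unique(df$sex)) > 1L
  form <- if (use_sex) y ~ 0 + year + age + sex else y ~ 0 + year + age
  fit <- stats::lm(form, data = df)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  years <- as.integer(levels(df$year))
  cn <- names(beta)
  means <- se <- numeric(length(years))
  for (i in seq_along(years)) {
    x <- stats::setNames(numeric(length(beta)), cn)
    x[paste0("year", years[i])] <- 1
    x["age"] <- mean(df$age)
    if (use_sex) x[grep("^sex", cn)] <- 0.5  # balanced-sex reference
    means[i] <- sum(x * beta)
    se[i] <- sqrt(drop(t(x) %*% V %*% x))
  }
  annual_series(years, means, n = as.integer(table(df$year)), se = se,
                stratum = stratum %||% "all")
}

# Candidate joinpoint positions: integer calendar years with at least
# min_side observed years at or below and strictly above. Break years need
# not be survey years (reported breaks typically fall between waves).
candidate_breaks <- function(years, min_side = 2L) {
  grid <- seq(min(years), max(years) - 1L)
  keep <- vapply(grid, function(b) {
    sum(years <= b) >= min_side && sum(years > b) >= min_side
  }, logical(1))
  grid[keep]
}

# All k-combinations of candidates with >= min_gap observed years strictly
# between consecutive breaks. Returns a list of integer vectors.
break_combos <- function(years, k, min_side = 2L, min_gap = 2L) {
  if (k == 0L) return(list(integer(0)))
  cand <- candidate_breaks(years, min_side)
  if (length(cand) < k) return(list())
  combos <- utils::combn(cand, k, simplify = FALSE)
  Filter(function(b) {
    if (length(b) < 2L) return(TRUE)
    all(vapply(seq_len(length(b) - 1L), function(i) {
      sum(years > b[i] & years <= b[i + 1L]) >= min_gap
    }, logical(1)))
  }, combos)
}

# Continuous piecewise-linear design matrix: intercept, (t - t0), hinges.
segmented_design <- function(years, breaks) {
  X <- cbind(1, years - years[1])
  for (b in breaks) X <- cbind(X, pmax(years - b, 0))
  colnames(X) <- c("(Intercept)", "t", if (length(breaks)) paste0("hinge", breaks))
  X
}

# Weighted residual quadratic form Q with y'Qy = weighted SSE of the WLS fit.
sse_qform <- function(X, w) {
  WX <- X * w
  Q <- diag(w) - WX %*% solve(crossprod(X, WX), t(WX))
  (Q + t(Q)) / 2
}

series_weights <- function(series, weights) {
  switch(weights,
         n = as.numeric(series$n),
         inv_var = 1 / series$se^2,
         none = rep(1, nrow(series)))
}

#' Fit a joinpoint model with a fixed number of breaks
#'
#' Continuous piecewise-linear weighted least squares. Break locations are
#' chosen by exhaustive grid search over integer calendar years (at least two
#' observed years on each side of a break and between breaks), minimizing the
#' weighted sum of squared errors. Slope confidence intervals and p-values
#' come from the WLS covariance of the selected model.
#'
#' @param series an [annual_series()].
#' @param k number of joinpoints (>= 0).
#' @param weights `"n"` (per-year sample size, default), `"inv_var"`
#'   (1/se^2), or `"none"`.
#' @param level confidence level for slope intervals.
#' @return object of class `joinpoint_fit`: joinpoints, per-segment slopes
#'   with CIs and p-values, SSE, fitted values.
#' @export
fit_segmented <- function(series, k, weights = c("n", "inv_var", "none"),
                          level = 0.95) {
  weights <- match.arg(weights)
  years <- series$year
  y <- series$mean
  w <- series_weights(series, weights)
  combos <- break_combos(years, k)
  if (length(combos) == 0L) {
    stopf("no feasible placement of %d joinpoint(s) for %d observed years", k, length(years))
  }
  best <- NULL
  best_sse <- Inf
  for (b in combos) {
    X <- segmented_design(years, b)
    fit <- stats::lm.wfit(X, y, w)
    sse <- sum(w * fit$residuals^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- list(breaks = b, X = X, fit = fit)
    }
  }
  joinpoint_fit(series, best$breaks, best$X, best$fit, w, level, weights)
}

# Assemble the fit object: per-segment slopes are cumulative sums of the
# slope and hinge coefficients.
joinpoint_fit <- function(series, breaks, X, fit, w, level, weights) {
  years <- series$year
  y <- series$mean
  n <- length(y)
  p <- ncol(X)
  beta <- fit$coefficients
  res <- fit$residuals
  sse <- sum(w * res^2)
  df <- n - p
  sigma2 <- if (df > 0) sse / df else 0
  XtWX <- crossprod(X, X * w)
  V <- sigma2 * solve(XtWX)
  k <- length(breaks)
  seg_start <- c(min(years), breaks)
  seg_end <- c(breaks, max(years))
  slopes <- lo <- hi <- pv <- numeric(k + 1)
  for (i in seq_len(k + 1)) {
    L <- c(0, 1, as.numeric(seq_len(k) < i))  # slope_i = beta_t + sum of earlier hinges
    slopes[i] <- sum(L * beta)
    se_i <- sqrt(drop(t(L) %*% V %*% L))
    tq <- if (df > 0) stats::qt(1 - (1 - level) / 2, df) else NA_real_
    lo[i] <- slopes[i] - tq * se_i
    hi[i] <- slopes[i] + tq * se_i
    pv[i] <- if (df > 0 && se_i > 0) 2 * stats::pt(-abs(slopes[i] / se_i), df) else NA_real_
  }
  structure(list(
    joinpoints = breaks,
    segments = data.frame(start_year = seg_start, end_year = seg_end,
                          slope = slopes, ci_lower = lo, ci_upper = hi,
                          p_value = pv),
    coefficients = beta, fitted = drop(X %*% beta), residuals = res,
    sse = sse, k = k, n = n, weights = weights, series = series,
    n_perm = NA_integer_, seed = NA_integer_, selection = NULL
  ), class = "joinpoint_fit")
}

#' Predict the fitted joinpoint line at arbitrary years
#'
#' @param object a `joinpoint_fit`.
#' @param years numeric years (may be fractional; the fitted piecewise line
#'   is continuous).
#' @param ... unused.
#' @return fitted score values.
#' @export
predict_joinpoint <- function(object, years, ...) {
  t0 <- min(object$series$year)
  X <- cbind(1, years - t0)
  for (b in object$joinpoints) X <- cbind(X, pmax(years - b, 0))
  drop(X %*% object$coefficients)
}

#' @export
print.joinpoint_fit <- function(x, ...) {
  cat(sprintf("Joinpoint fit: %d joinpoint(s)%s, SSE = %.4g\n", x$k,
              if (x$k) paste0(" at ", paste(x$joinpoints, collapse = ", ")) else "",
              x$sse))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# Minimum weighted SSE over a set of break combinations, evaluated as
# quadratic forms so the same design can be reused across many permuted
# series. `Y` is a matrix with one series per column.
min_sse_over_combos <- function(qforms, Y) {
  sse <- rep(Inf, ncol(Y))
  for (Q in qforms) sse <- pmin(sse, colSums(Y * (Q %*% Y)))
  sse
}

combo_qforms <- function(years, w, combos) {
  lapply(combos, function(b) sse_qform(segmented_design(years, b), w))
}

#' Select the number of joinpoints
#'
#' Sequential permutation tests of k versus k+1 joinpoints (k = 0, 1, ...,
#' `k_max` - 1): residuals of the k-joinpoint fit are permuted and added back
#' to its fitted line, and the observed relative SSE improvement
#' `(SSE_k - SSE_{k+1}) / SSE_{k+1}` is ranked against the permuted ones. The
#' sequence is Bonferroni-corrected at level `alpha / k_max`; the first
#' non-rejection stops the search. `method = "bic"` instead minimizes
#' `n log(SSE/n) + 2 (k+1) log(n)`. Fully reproducible given `seed`.
#'
#' @param series an [annual_series()].
#' @param k_max maximum number of joinpoints to consider.
#' @param n_perm permutations per test (>= 99).
#' @param seed integer seed for the permutation draws.
#' @param alpha family significance level (default 0.05).
#' @param method `"permutation"` (default) or `"bic"`.
#' @param weights WLS weighting, as in [fit_segmented()].
#' @return the selected `joinpoint_fit`, with the selection trace in
#'   `$selection` and `n_perm`/`seed` recorded.
#' @export
select_n_joinpoints <- function(series, k_max = 2L, n_perm = 999L, seed = NULL,
                                alpha = 0.05, method = c("permutation", "bic"),
                                weights = c("n", "inv_var", "none")) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  years <- series$year
  w <- series_weights(series, weights)
  # cap k_max at feasibility
  while (k_max > 0L && length(break_combos(years, k_max)) == 0L) k_max <- k_max - 1L

  if (method == "bic") {
    bic <- vapply(0:k_max, function(k) {
      f <- fit_segmented(series, k, weights)
      n <- length(years)
      n * log(max(f$sse, 1e-12) / n) + 2 * (k + 1) * log(n)
    }, numeric(1))
    k_sel <- which.min(bic) - 1L
    out <- fit_segmented(series, k_sel, weights)
    out$selection <- data.frame(k = 0:k_max, bic = bic)
    return(out)
  }

  if (n_perm < 99L) stopf("n_perm must be >= 99")
  y <- series$mean
  n <- length(y)
  trace <- data.frame(k_null = integer(0), k_alt = integer(0),
                      stat = numeric(0), p_value = numeric(0))
  k <- 0L
  with_seed(seed, {
    while (k < k_max) {
      combos0 <- break_combos(years, k)
      combos1 <- break_combos(years, k + 1L)
      if (length(combos1) == 0L) break
      q0 <- combo_qforms(years, w, combos0)
      q1 <- combo_qforms(years, w, combos1)
      sse0 <- min_sse_over_combos(q0, matrix(y))
      sse1 <- min_sse_over_combos(q1, matrix(y))
      stat_obs <- (sse0 - sse1) / max(sse1, 1e-12)

      # permute (weight-standardized) null-fit residuals
      fit0 <- fit_segmented(series, k, weights)
      e <- fit0$residuals * sqrt(w)
      Y <- vapply(seq_len(n_perm),
                  function(i) fit0$fitted + sample(e) / sqrt(w),
                  numeric(n))
      p0 <- min_sse_over_combos(q0, Y)
      p1 <- min_sse_over_combos(q1, Y)
      stat_perm <- (p0 - p1) / pmax(p1, 1e-12)
      pval <- (1 + sum(stat_perm >= stat_obs - 1e-12)) / (1 + n_perm)
      trace <- rbind(trace, data.frame(k_null = k, k_alt = k + 1L,
                                       stat = stat_obs, p_value = pval))
      if (pval > alpha / k_max) break
      k <- k + 1L
    }
  })
  out <- fit_segmented(series, k, weights)
  out$n_perm <- n_perm
  out$seed <- seed %||% NA_integer_
  out$selection <- trace
  out
}
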