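# Cross-lagged panel models (CLPM) between behaviour and factor scores
# across wave blocks: community-level panel construction, path estimation on
# observed covariance matrices, and maximum-likelihood fit indices.

CLPM_VARS <- c("diet", "physical_activity", "sleep", "bmi", "blood_pressure")

#' Default wave-block map for the cross-lagged panel
#'
#' Three five-year blocks: 2004-2008, 2009-2013, 2014-2018.
#' @return named list of year vectors.
#' @export
clpm_default_blocks <- function() {
  list(B1 = 2004:2008, B2 = 2009:2013, B3 = 2014:2018)
}

#' Default cross-lagged path specification
#'
#' First-order autoregressions for all five variables plus the cross paths
#' diet -> BMI, BMI -> sleep, sleep -> BMI and BMI -> blood pressure, applied
#' across each pair of adjacent blocks.
#'
#' @return data.frame with columns `from`, `to`.
#' @export
clpm_default_paths <- function() {
  rbind(
    data.frame(from = CLPM_VARS, to = CLPM_VARS),
    data.frame(from = c("diet", "bmi", "sleep", "bmi"),
               to = c("bmi", "sleep", "bmi", "blood_pressure"))
  )
}

#' Build a community-level panel from scored records
#'
#' Aggregates scored records to unit (community) means per wave block, keeps
#' units observed in at least `min_blocks` blocks, and standardizes each
#' variable within block (mean 0, sd 1). The number of dropped units is
#' attached as attribute `n_dropped` and reported via message.
#'
#' @param scored scored records with a unit column and `wave_year`.
#' @param vars score columns to carry (default the five CLPM variables).
#' @param block_map named list of year vectors (default
#'   [clpm_default_blocks()]).
#' @param unit_col name of the unit identifier column (default
#'   `"community"`).
#' @param min_blocks minimum blocks per retained unit (default 2).
#' @param min_units minimum retained units (default 10).
#' @return data.frame of class `clpm_panel`: `unit`, `block`, one column per
#'   variable.
#' @export
build_panel <- function(scored, vars = CLPM_VARS, block_map = clpm_default_blocks(),
                        unit_col = "community", min_blocks = 2L, min_units = 10L) {
  scored <- as.data.frame(scored)
  if (!unit_col %in% names(scored)) stopf("no unit column '%s'", unit_col)
  year2block <- rep(names(block_map), lengths(block_map))
  names(year2block) <- unlist(block_map)
  block <- year2block[as.character(scored$wave_year)]
  keep <- !is.na(block)
  scored <- scored[keep, , drop = FALSE]
  block <- block[keep]
  if (nrow(scored) == 0L) stopf("no records fall inside the block map")

  key <- interaction(scored[[unit_col]], block, drop = TRUE)
  agg <- data.frame(unit = tapply(as.character(scored[[unit_col]]), key, `[`, 1),
                    block = tapply(block, key, `[`, 1))
  for (v in vars) agg[[v]] <- as.numeric(tapply(scored[[v]], key, mean, na.rm = TRUE))
  rownames(agg) <- NULL

  nb <- table(agg$unit)
  retained <- names(nb)[nb >= min_blocks]
  n_dropped <- sum(nb < min_blocks)
  agg <- agg[agg$unit %in% retained, , drop = FALSE]
  if (length(retained) < min_units) {
    stopf("only %d unit(s) retained (< %d) after the >=%d-block coverage rule",
          length(retained), min_units, min_blocks)
  }
  if (n_dropped > 0) message(n_dropped, " unit(s) dropped by the block-coverage rule")
  for (v in vars) {
    for (b in unique(agg$block)) {
      i <- agg$block == b
      x <- agg[[v]][i]
      agg[[v]][i] <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    }
  }
  agg <- agg[order(agg$unit, agg$block), , drop = FALSE]
  structure(agg, class = c("clpm_panel", "data.frame"),
            vars = vars, n_dropped = n_dropped)
}

# Long panel -> wide matrix of var.block columns, one row per unit.
panel_wide <- function(panel, vars) {
  blocks <- sort(unique(panel$block))
  units <- unique(panel$unit)
  wide <- matrix(NA_real_, nrow = length(units),
                 ncol = length(vars) * length(blocks),
                 dimnames = list(units, paste(rep(vars, times = length(blocks)),
                                              rep(blocks, each = length(vars)), sep = ".")))
  for (b in blocks) {
    rows <- panel[panel$block == b, , drop = FALSE]
    wide[match(rows$unit, units), paste(vars, b, sep = ".")] <- as.matrix(rows[vars])
  }
  wide
}

#' Structural-equation fit indices from chi-square statistics
#'
#' `CFI = 1 - max(chi_m - df_m, 0) / max(chi_b - df_b, chi_m - df_m, 0)`;
#' `TLI = ((chi_b/df_b) - (chi_m/df_m)) / ((chi_b/df_b) - 1)` (capped at 1);
#' `RMSEA = sqrt(max(chi_m - df_m, 0) / (df_m * (n - 1)))`.
#' A saturated model (`df_m = 0`) is flagged and reported as perfect fit.
#'
#' @param chi_sq_model,df_model model chi-square and degrees of freedom.
#' @param chi_sq_baseline,df_baseline independence-model chi-square and df.
#' @param n sample size (>= 2).
#' @return list with `CFI`, `TLI`, `RMSEA`, `saturated`.
#' @export
fit_indices <- function(chi_sq_model, df_model, chi_sq_baseline, df_baseline, n) {
  stopifnot(df_model >= 0, df_baseline >= 0, n >= 2)
  if (df_model == 0) {
    return(list(CFI = 1, TLI = 1, RMSEA = 0, saturated = TRUE))
  }
  num <- max(chi_sq_model - df_model, 0)
  den <- max(chi_sq_baseline - df_baseline, chi_sq_model - df_model, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- chi_sq_baseline / df_baseline
  tli <- if (abs(rb - 1) < 1e-12) 1 else (rb - chi_sq_model / df_model) / (rb - 1)
  rmsea <- sqrt(max(chi_sq_model - df_model, 0) / (df_model * (n - 1)))
  list(CFI = cfi, TLI = min(tli, 1), RMSEA = rmsea, saturated = FALSE)
}

# Regression of each endogenous variable on its specified lagged predictors,
# computed from a covariance matrix (ML for a recursive path model).
paths_from_cov <- function(S, n, vars, from_block, to_block, paths, level) {
  out <- NULL
  A <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))  # rows = to
  z <- stats::qnorm(1 - (1 - level) / 2)
  for (v in unique(paths$to)) {
    preds <- paths$from[paths$to == v]
    xs <- paste(preds, from_block, sep = ".")
    yv <- paste(v, to_block, sep = ".")
    Sxx <- S[xs, xs, drop = FALSE]
    if (rcond(Sxx) < 1e-10) {
      cn <- stats::cov2cor(Sxx); diag(cn) <- 0
      worst <- which(abs(cn) == max(abs(cn)), arr.ind = TRUE)[1, ]
      stopf("singular predictor covariance in block %s: %s and %s are collinear",
            from_block, xs[worst[1]], xs[worst[2]])
    }
    b <- solve(Sxx, S[xs, yv])
    A[v, preds] <- b
    resid_var <- S[yv, yv] - drop(crossprod(b, S[xs, yv]))
    q <- length(b)
    sigma2 <- resid_var * (n - 1) / max(n - q - 1, 1)
    se <- sqrt(pmax(diag(solve(Sxx)) * sigma2 / (n - 1), 0))
    out <- rbind(out, data.frame(
      from = preds, to = v, from_block = from_block, to_block = to_block,
      type = ifelse(preds == v, "autoregressive", "cross"),
      estimate = b, se = se,
      ci_lower = b - z * se, ci_upper = b + z * se,
      p_value = 2 * stats::pnorm(-abs(b / se)), row.names = NULL))
  }
  list(paths = out, A = A)
}

#' Fit a cross-lagged panel model
#'
#' Path coefficients are estimated per block transition by regression on the
#' transition's observed covariance matrix (maximum likelihood for a
#' recursive path model with lagged-only paths); a unit contributes to every
#' transition for which it has both blocks. Global fit is evaluated on the
#' listwise-complete covariance matrix: the model-implied covariance is built
#' block-recursively from the path matrices and residual (co)variances, and
#' compared with the observed one through the ML discrepancy
#' `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p`, `chi^2 = (n-1) F`, with an
#' independence baseline for CFI/TLI.
#'
#' @param panel a `clpm_panel` from [build_panel()] (variables standardized
#'   within block, so coefficients are standardized).
#' @param paths data.frame `from, to` of lagged paths applied to each
#'   adjacent block pair (default [clpm_default_paths()]).
#' @param residual_cov `"free"` (default; within-block residual covariances
#'   estimated) or `"diagonal"` (uncorrelated residuals).
#' @param level confidence level for Wald intervals.
#' @return list of class `clpm_result`: `paths` (coefficient table), `fit`
#'   (chi_square, df, CFI, TLI, RMSEA), `n` (listwise units), `A` (path
#'   matrices per transition).
#' @export
fit_clpm <- function(panel, paths = clpm_default_paths(),
                     residual_cov = c("free", "diagonal"), level = 0.95) {
  residual_cov <- match.arg(residual_cov)
  vars <- attr(panel, "vars") %||% setdiff(names(panel), c("unit", "block"))
  bad <- setdiff(unique(c(paths$from, paths$to)), vars)
  if (length(bad)) stopf("path variables not in panel: %s", paste(bad, collapse = ", "))
  blocks <- sort(unique(panel$block))
  if (length(blocks) < 2L) stopf("need >= 2 blocks")
  wide <- panel_wide(panel, vars)

  # per-transition estimation on that transition's complete units
  coefs <- NULL
  A_list <- list()
  for (t in seq_len(length(blocks) - 1L)) {
    cols <- c(paste(vars, blocks[t], sep = "."), paste(vars, blocks[t + 1L], sep = "."))
    sub <- wide[stats::complete.cases(wide[, cols]), cols, drop = FALSE]
    if (nrow(sub) < length(vars) + 2L) {
      stopf("too few units (%d) with both blocks %s and %s", nrow(sub),
            blocks[t], blocks[t + 1L])
    }
    est <- paths_from_cov(stats::cov(sub), nrow(sub), vars,
                          blocks[t], blocks[t + 1L], paths, level)
    coefs <- rbind(coefs, est$paths)
    A_list[[t]] <- est$A
  }

  # global fit on listwise-complete units
  complete <- wide[stats::complete.cases(wide), , drop = FALSE]
  n <- nrow(complete)
  fit <- NULL
  if (n >= length(vars) + 2L) {
    S <- stats::cov(complete)
    P <- ncol(S)
    p_b <- length(vars)
    implied <- S[paste(vars, blocks[1], sep = "."), paste(vars, blocks[1], sep = "."),
                 drop = FALSE]  # exogenous block saturated
    Sig <- matrix(0, P, P, dimnames = dimnames(S))
    idx <- function(b) paste(vars, b, sep = ".")
    Sig[idx(blocks[1]), idx(blocks[1])] <- implied
    n_resid <- 0
    for (t in seq_len(length(blocks) - 1L)) {
      A <- A_list[[t]]
      prev <- unlist(lapply(blocks[seq_len(t)], idx))
      cur <- idx(blocks[t])
      nxt <- idx(blocks[t + 1L])
      # residual covariance implied by the transition's own covariance
      St <- stats::cov(wide[stats::complete.cases(wide[, c(cur, nxt)]), c(cur, nxt),
                            drop = FALSE])
      Psi <- St[nxt, nxt] - A %*% St[cur, nxt] - t(St[cur, nxt]) %*% t(A) +
        A %*% St[cur, cur] %*% t(A)
      if (residual_cov == "diagonal") {
        Psi <- diag(diag(Psi), nrow = nrow(Psi))
        n_resid <- n_resid + p_b
      } else {
        n_resid <- n_resid + p_b * (p_b + 1) / 2
      }
      Sig[nxt, prev] <- A %*% Sig[cur, prev]
      Sig[prev, nxt] <- t(Sig[nxt, prev])
      Sig[nxt, nxt] <- A %*% Sig[cur, cur] %*% t(A) + Psi
    }
    n_free <- p_b * (p_b + 1) / 2 + nrow(paths) * (length(blocks) - 1L) + n_resid
    df_m <- P * (P + 1) / 2 - n_free
    F_ml <- max(determinant(Sig, logarithm = TRUE)$modulus -
                  determinant(S, logarithm = TRUE)$modulus +
                  sum(diag(S %*% solve(Sig))) - P, 0)
    chi_m <- (n - 1) * F_ml
    F_b <- max(sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus, 0)
    chi_b <- (n - 1) * F_b
    df_b <- P * (P - 1) / 2
    ind <- fit_indices(chi_m, max(df_m, 0), chi_b, df_b, n)
    fit <- list(chi_square = chi_m, df = df_m, CFI = ind$CFI, TLI = ind$TLI,
                RMSEA = ind$RMSEA, saturated = ind$saturated)
  } else {
    warning("too few listwise-complete units for global fit indices")
  }
  structure(list(paths = coefs, fit = fit, n = n, A = A_list,
                 blocks = blocks, vars = vars),
            class = "clpm_result")
}

#' @export
print.clpm_result <- function(x, ...) {
  cat(sprintf("Cross-lagged panel model: %d blocks, %d listwise units\n",
              length(x$blocks), x$n))
  print(x$paths, row.names = FALSE, digits = 3)
  if (!is.null(x$fit)) {
    cat(sprintf("fit: chi^2 = %.3f, df = %d, CFI = %.3f, TLI = %.3f, RMSEA = %.3f\n",
                x$fit$chi_square, x$fit$df, x$fit$CFI, x$fit$TLI, x$fit$RMSEA))
  }
  invisible(x)
}
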