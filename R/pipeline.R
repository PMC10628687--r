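# Pipeline orchestration: score -> aggregate -> trends -> CLPM, plus the
# Fisher-Jenks classifier used for map-style summaries of provincial scores.

#' Default decade blocks for aggregation
#' @return named list of year vectors.
#' @export
decade_blocks_default <- function() {
  list(`1989-1998` = 1989:1998, `1999-2008` = 1999:2008, `2009-2018` = 2009:2018)
}

#' Aggregate CVH profiles by group
#'
#' Mean, SD and n of the overall, behavior and factor scores per group cell.
#' `"decade"` in `by` groups wave years through `decade_blocks`.
#'
#' @param profiles scored profiles from [score_records()]; excluded records
#'   (fewer observed components than the inclusion minimum) are dropped.
#' @param by grouping columns, e.g. `c("region", "decade")` or
#'   `c("province", "wave_year", "urban")`.
#' @param decade_blocks named list of year vectors (default
#'   [decade_blocks_default()]).
#' @return data.frame with group keys and `<score>_mean`, `<score>_sd`,
#'   `n` columns.
#' @export
aggregate_scores <- function(profiles, by = c("region", "decade"),
                             decade_blocks = decade_blocks_default()) {
  profiles <- as.data.frame(profiles)
  if (nrow(profiles) == 0L) stopf("no profiles to aggregate")
  if ("included" %in% names(profiles)) profiles <- profiles[profiles$included, , drop = FALSE]
  if ("decade" %in% by) {
    year2block <- rep(names(decade_blocks), lengths(decade_blocks))
    names(year2block) <- unlist(decade_blocks)
    profiles$decade <- year2block[as.character(profiles$wave_year)]
  }
  miss <- setdiff(by, names(profiles))
  if (length(miss)) stopf("grouping column(s) not found: %s", paste(miss, collapse = ", "))
  scores <- intersect(c("overall", "behavior_subscore", "factor_subscore"), names(profiles))
  key <- interaction(profiles[by], drop = TRUE, sep = "\r")
  cells <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- stats::setNames(as.data.frame(cells, stringsAsFactors = FALSE), by)
  out$n <- as.integer(table(key))
  for (s in scores) {
    out[[paste0(s, "_mean")]] <- as.numeric(tapply(profiles[[s]], key, mean, na.rm = TRUE))
    sdv <- as.numeric(tapply(profiles[[s]], key, stats::sd, na.rm = TRUE))
    out[[paste0(s, "_sd")]] <- ifelse(is.na(sdv) & out$n == 1L, 0, sdv)
  }
  rownames(out) <- NULL
  out
}

#' Fisher-Jenks natural-breaks classification
#'
#' Exact dynamic-programming optimization of class boundaries minimizing the
#' total within-class sum of squared deviations for one-dimensional data
#' (the "natural breaks" used for choropleth-style score classes).
#'
#' @param values numeric vector.
#' @param n_classes number of classes (>= 2, <= number of distinct values).
#' @return numeric vector of length `n_classes + 1`: the minimum, the upper
#'   value of each class except the last, and the maximum. Class `i` is
#'   `(breaks[i], breaks[i+1]]` (first class closed on the left).
#' @export
jenks_breaks <- function(values, n_classes) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  if (length(unique(x)) < n_classes) {
    stopf("need at least %d distinct values for %d classes", n_classes, n_classes)
  }
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {  # within-class SS of x[i..j]
    m <- j - i + 1
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / m
  }
  # dp[k, j]: minimal total SS partitioning x[1..j] into k classes
  dp <- matrix(Inf, n_classes, n)
  cut_at <- matrix(0L, n_classes, n)
  for (j in seq_len(n)) dp[1, j] <- cost(1, j)
  for (k in 2:n_classes) {
    for (j in k:n) {
      best <- Inf; arg <- 0L
      for (i in k:j) {
        v <- dp[k - 1, i - 1] + cost(i, j)
        if (v < best) { best <- v; arg <- i }
      }
      dp[k, j] <- best
      cut_at[k, j] <- arg
    }
  }
  # backtrack the class start indices
  bounds <- numeric(n_classes + 1)
  bounds[n_classes + 1] <- x[n]
  j <- n
  for (k in n_classes:2) {
    i <- cut_at[k, j]
    bounds[k] <- x[i - 1]
    j <- i - 1L
  }
  bounds[1] <- x[1]
  structure(bounds, within_ss = dp[n_classes, n])
}

#' Read/write participant record CSVs
#'
#' The record CSV uses one row per child-wave observation with the column
#' dictionary documented in the README; missing values are empty fields.
#'
#' @param path CSV path.
#' @return data.frame of records.
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("urban" %in% names(rec) && !is.logical(rec$urban)) {
    rec$urban <- rec$urban %in% c("TRUE", "true", "1", 1, TRUE)
  }
  if ("diabetes_dx" %in% names(rec) && !is.logical(rec$diabetes_dx)) {
    rec$diabetes_dx <- ifelse(is.na(rec$diabetes_dx), NA,
                              rec$diabetes_dx %in% c("TRUE", "true", "1", 1, TRUE))
  }
  if ("secondhand" %in% names(rec) && !is.logical(rec$secondhand)) {
    rec$secondhand <- ifelse(is.na(rec$secondhand), NA,
                             rec$secondhand %in% c("TRUE", "true", "1", 1, TRUE))
  }
  rec
}

#' @rdname read_records
#' @param records data.frame to write.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) records, scores them, writes per-record profiles,
#' grouped aggregates, joinpoint trend fits and the cross-lagged panel model,
#' with a run log recording the seed, configuration checksum and record
#' counts at every filter.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `scenario` (packaged scenario name) or `input` (record CSV path);
#'   `seed`; `out_dir`; `min_components` (default 4); `rubrics`,
#'   `diet_cutoffs`, `region_map`, `references` (optional override paths);
#'   `trends`: list(`scores`, `strata`, `k_max`, `n_perm`);
#'   `aggregate_by` (default region x decade); `clpm`: list(`enabled`,
#'   `unit_col`).
#' @return (invisibly) list with the scored profiles, aggregates, trend fits
#'   and CLPM result, plus output file paths.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stopf("config must name an out_dir")
  seed <- as.integer(config$seed %||% 1L)
  for (f in c("rubrics", "diet_cutoffs", "region_map", "input")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stopf("configured %s file does not exist: %s", f, config[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  refs <- if (!is.null(config$references)) {
    do.call(load_reference_tables, as.list(config$references))
  } else NULL
  cfg <- le8_config(rubrics = config$rubrics, references = refs,
                    diet_cutoffs = config$diet_cutoffs, region_map = config$region_map)

  cfg_hash <- if (!is.null(config_path)) unname(tools::md5sum(config_path)) else {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config, tmp)
    on.exit(unlink(tmp), add = TRUE)
    unname(tools::md5sum(tmp))
  }
  say("pipeline start: seed=%d config_md5=%s", seed, cfg_hash)

  stage <- "input"
  result <- tryCatch({
    records <- if (!is.null(config$input)) {
      read_records(config$input)
    } else {
      scen_name <- config$scenario %||% "demo"
      scen <- cvh_scenarios()[[scen_name]]
      if (is.null(scen)) stopf("unknown packaged scenario '%s'", scen_name)
      generate_cohort(scen, config = cfg, seed = seed)
    }
    say("records read/generated: n=%d", nrow(records))

    stage <- "scoring"
    min_comp <- as.integer(config$min_components %||% 4L)
    profiles <- score_records(records, cfg, min_components = min_comp)
    n_inc <- sum(profiles$included)
    say("scored: n_input=%d n_included=%d n_excluded=%d (>=%d components)",
        nrow(profiles), n_inc, nrow(profiles) - n_inc, min_comp)
    stopifnot(nrow(profiles) == n_inc + sum(!profiles$included))
    scored_path <- file.path(out_dir, "scored.csv")
    write_records(profiles, scored_path)

    stage <- "aggregation"
    by <- unlist(config$aggregate_by %||% c("region", "decade"))
    aggregates <- aggregate_scores(profiles, by = by)
    agg_path <- file.path(out_dir, "aggregates.csv")
    utils::write.csv(aggregates, agg_path, row.names = FALSE)
    say("aggregates: %d cells by %s", nrow(aggregates), paste(by, collapse = " x "))

    stage <- "trends"
    tr_cfg <- config$trends %||% list()
    tr_scores <- unlist(tr_cfg$scores %||% c("diet", "bmi", "sleep"))
    tr_strata <- unlist(tr_cfg$strata %||% c("rural", "urban"))
    k_max <- as.integer(tr_cfg$k_max %||% 2L)
    n_perm <- as.integer(tr_cfg$n_perm %||% 199L)
    trends <- list()
    inc <- profiles[profiles$included, , drop = FALSE]
    for (sc in tr_scores) {
      for (st in tr_strata) {
        series <- adjusted_annual_means(inc, sc, stratum = st)
        fit <- select_n_joinpoints(series, k_max = k_max, n_perm = n_perm,
                                   seed = seed + length(trends))
        trends[[paste(sc, st, sep = ".")]] <- list(
          score = sc, stratum = st, joinpoints = fit$joinpoints,
          segments = fit$segments, sse = fit$sse, n_perm = n_perm)
        say("trend %s/%s: %d joinpoint(s)%s", sc, st, fit$k,
            if (fit$k) paste0(" at ", paste(fit$joinpoints, collapse = ",")) else "")
      }
    }
    trends_path <- file.path(out_dir, "trends.json")
    jsonlite::write_json(trends, trends_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "clpm"
    clpm_res <- NULL
    if (isTRUE(config$clpm$enabled %||% TRUE)) {
      panel <- build_panel(inc, unit_col = config$clpm$unit_col %||% "community")
      say("clpm panel: %d unit-blocks, %d unit(s) dropped by coverage",
          nrow(panel), attr(panel, "n_dropped"))
      clpm_res <- fit_clpm(panel)
      utils::write.csv(clpm_res$paths, file.path(out_dir, "clpm_paths.csv"),
                       row.names = FALSE)
      if (!is.null(clpm_res$fit)) {
        say("clpm fit: chi2=%.3f df=%d CFI=%.3f TLI=%.3f RMSEA=%.3f",
            clpm_res$fit$chi_square, clpm_res$fit$df, clpm_res$fit$CFI,
            clpm_res$fit$TLI, clpm_res$fit$RMSEA)
      }
    }
    list(profiles = profiles, aggregates = aggregates, trends = trends,
         clpm = clpm_res,
         paths = list(scored = scored_path, aggregates = agg_path,
                      trends = trends_path, log = log_path))
  }, error = function(e) {
    log_lines <<- c(log_lines, sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)))
    writeLines(log_lines, log_path)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  say("pipeline complete")
  writeLines(log_lines, log_path)
  invisible(result)
}
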