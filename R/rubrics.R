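# Scoring rubrics as data. Every component's threshold->points mapping lives
# in a YAML file (packaged default: extdata/rubrics.yaml) so that rubric
# values can be changed without touching code.

# Turn a YAML band list into a validated band table. Bands are left-closed
# [lower_i, lower_{i+1}) on the metric, ordered by lower; the last band is
# unbounded above.
as_band_table <- function(x, component = "component") {
  if (is.null(x) || length(x) == 0L) stopf("%s: empty band list", component)
  lower <- vapply(x, function(b) as.numeric(b$lower), numeric(1))
  points <- vapply(x, function(b) as.numeric(b$points), numeric(1))
  if (is.unsorted(lower, strictly = TRUE)) {
    stopf("%s: band lower bounds must be strictly increasing", component)
  }
  if (any(points < 0 | points > 100)) stopf("%s: points must be in [0, 100]", component)
  structure(data.frame(lower = lower, points = points), class = c("band_table", "data.frame"))
}

# Left-closed band lookup, vectorized. Values below the first lower bound are
# an error (bands must be exhaustive on the metric's domain).
band_points <- function(x, bands) {
  idx <- findInterval(x, bands$lower)
  if (any(idx == 0L, na.rm = TRUE)) {
    stopf("value %g below the first rubric band (%g)", x[which(idx == 0L)[1]], bands$lower[1])
  }
  bands$points[idx]
}

#' Load a scoring rubric from YAML
#'
#' Reads the configurable threshold-to-points rubric for all eight
#' cardiovascular-health components. See the packaged
#' `extdata/rubrics.yaml` for the documented schema and the default pediatric
#' point bands.
#'
#' @param path YAML rubric file; default is the packaged rubric.
#' @return a named list of class `le8_rubrics`, one element per component.
#' @export
load_rubrics <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% cvh8_extdata("rubrics.yaml"))
  need <- c("diet", "physical_activity", "nicotine", "sleep",
            "bmi", "lipids", "glucose", "blood_pressure")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stopf("rubric file missing components: %s", paste(missing, collapse = ", "))

  r <- list()
  r$diet <- list(points = as.numeric(raw$diet$points))
  if (length(r$diet$points) != 5L) stopf("diet rubric must map 5 quintile bands")
  r$physical_activity <- list(bands = as_band_table(raw$physical_activity$bands, "physical_activity"))
  cats <- raw$nicotine$categories
  r$nicotine <- list(
    categories = stats::setNames(vapply(cats, as.numeric, numeric(1)), names(cats)),
    secondhand_penalty = as.numeric(raw$nicotine$secondhand_penalty)
  )
  rec <- raw$sleep$recommended_hours
  r$sleep <- list(
    recommended = data.frame(
      age_min = vapply(rec, function(b) as.numeric(b$age_min), numeric(1)),
      age_max = vapply(rec, function(b) as.numeric(b$age_max), numeric(1)),
      hours = vapply(rec, function(b) as.numeric(b$hours), numeric(1))
    ),
    bands = as_band_table(raw$sleep$bands, "sleep")
  )
  r$bmi <- list(
    percentile_bands = as_band_table(raw$bmi$percentile_bands, "bmi percentile"),
    ratio_bands = as_band_table(raw$bmi$ratio_bands, "bmi ratio")
  )
  r$lipids <- list(bands = as_band_table(raw$lipids$bands, "lipids"))
  r$glucose <- list(
    diabetes_fpg = as.numeric(raw$glucose$diabetes_fpg),
    nondiabetic_hba1c = as.numeric(raw$glucose$nondiabetic_hba1c %||% c(5.7, 6.5)),
    fpg_bands = as_band_table(raw$glucose$fpg_bands, "glucose fpg"),
    hba1c_bands = as_band_table(raw$glucose$hba1c_bands, "glucose hba1c")
  )
  r$blood_pressure <- list(
    adult_age = as.numeric(raw$blood_pressure$adult_age),
    youth_percentiles = as.numeric(raw$blood_pressure$youth_percentiles),
    stage2_offset_mmhg = as.numeric(raw$blood_pressure$stage2_offset_mmhg),
    adult_sbp = as.numeric(raw$blood_pressure$adult_sbp),
    adult_dbp = as.numeric(raw$blood_pressure$adult_dbp),
    points = as.numeric(raw$blood_pressure$points)
  )
  for (comp in c("physical_activity")) {
    if (r[[comp]]$bands$lower[1] > 0) stopf("%s bands must start at 0", comp)
  }
  class(r) <- "le8_rubrics"
  r
}

#' Load population diet-adherence cutoffs
#'
#' Reads per-food-group quintile cutoffs and the adherence-total quintile
#' cutoffs used by the DASH-style diet score. The packaged default is a
#' synthetic stand-in for cutoffs estimated on an analysis population;
#' [estimate_diet_cutoffs()] derives them from data.
#'
#' @param path YAML cutoff file; default is the packaged file.
#' @return list of class `diet_cutoffs` with elements `groups` (named list of
#'   `direction`, `cutoffs`, `range`) and `adherence_cutoffs` (length 4).
#' @export
load_diet_cutoffs <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% cvh8_extdata("diet_cutoffs.yaml"))
  groups <- lapply(raw$groups, function(g) {
    g$cutoffs <- as.numeric(g$cutoffs)
    g$range <- as.numeric(g$range %||% c(0, 2 * max(g$cutoffs)))
    if (length(g$cutoffs) != 4L || is.unsorted(g$cutoffs, strictly = TRUE)) {
      stopf("diet cutoffs must be 4 strictly increasing values per group")
    }
    if (!g$direction %in% c("higher", "lower")) stopf("direction must be higher/lower")
    g
  })
  ac <- as.numeric(raw$adherence_cutoffs)
  if (length(ac) != 4L || is.unsorted(ac, strictly = TRUE)) {
    stopf("adherence_cutoffs must be 4 strictly increasing values")
  }
  structure(list(groups = groups, adherence_cutoffs = ac), class = "diet_cutoffs")
}

#' Estimate diet cutoffs from an analysis population
#'
#' Computes per-group intake quintile cutoffs and adherence-total quintile
#' cutoffs from observed records, keeping each group's configured direction.
#'
#' @param intakes data.frame with one column per food group (g/day), rows =
#'   individuals of the analysis population.
#' @param directions named character vector, `"higher"` or `"lower"` per
#'   group; defaults to the packaged directions for known groups.
#' @return a `diet_cutoffs` object.
#' @export
estimate_diet_cutoffs <- function(intakes, directions = NULL) {
  default <- load_diet_cutoffs()
  groups <- list()
  for (g in names(intakes)) {
    dir <- directions[[g]] %||% default$groups[[g]]$direction %||% "higher"
    x <- intakes[[g]][!is.na(intakes[[g]])]
    q <- unname(stats::quantile(x, c(.2, .4, .6, .8), type = 7))
    if (any(diff(q) <= 0)) q <- q + seq(0, 3) * 1e-9  # untie degenerate quantiles
    groups[[g]] <- list(direction = dir, cutoffs = q, range = range(x))
  }
  cuts <- structure(list(groups = groups, adherence_cutoffs = c(1, 2, 3, 4)),
                    class = "diet_cutoffs")
  adh <- diet_adherence(intakes, cuts)
  ac <- unname(stats::quantile(adh, c(.2, .4, .6, .8), type = 7))
  if (any(diff(ac) <= 0)) ac <- ac + seq(0, 3) * 1e-6
  cuts$adherence_cutoffs <- ac
  cuts
}

#' Load the province-to-region mapping
#'
#' Six-region grouping (North, Northeast, East, Central, Southwest, Northwest
#' China) of the 15 survey provinces, per Chinese administrative-division
#' codes.
#'
#' @param path CSV with columns `province, region`; default packaged mapping.
#' @return data.frame `province, region`.
#' @export
load_region_map <- function(path = NULL) {
  tab <- utils::read.csv(path %||% cvh8_extdata("chns_region_map.csv"),
                         stringsAsFactors = FALSE)
  if (!all(c("province", "region") %in% names(tab))) {
    stopf("region map must have columns province, region")
  }
  tab
}

#' Assemble the full scoring configuration
#'
#' Bundles rubrics, growth/blood-pressure references, diet cutoffs and the
#' region mapping, all overridable by file path.
#'
#' @param rubrics,diet_cutoffs,region_map file paths (NULL = packaged default).
#' @param references list as from [load_reference_tables()], or NULL for the
#'   packaged defaults.
#' @return list of class `le8_config`.
#' @export
le8_config <- function(rubrics = NULL, references = NULL,
                       diet_cutoffs = NULL, region_map = NULL) {
  structure(list(
    rubrics = if (inherits(rubrics, "le8_rubrics")) rubrics else load_rubrics(rubrics),
    references = references %||% load_reference_tables(),
    diet_cutoffs = if (inherits(diet_cutoffs, "diet_cutoffs")) diet_cutoffs else load_diet_cutoffs(diet_cutoffs),
    region_map = if (is.data.frame(region_map)) region_map else load_region_map(region_map)
  ), class = "le8_config")
}
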