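#' Michelson contrast sensitivity from a percent threshold
#'
#' A contrast threshold measured in percent is read as the Michelson
#' contrast `(Lmax - Lmin)/(Lmax + Lmin) = threshold/100` of the
#' grating at threshold; contrast sensitivity is its reciprocal, so
#' 100% contrast gives sensitivity 1 and 50% gives 2. The apparatus'
#' exact percent-to-Michelson calibration can be substituted via
#' `convert`.
#'
#' @param thresholdPercent contrast threshold(s), percent in (0, 100]
#' @param convert function mapping percent to Michelson contrast in
#'   (0, 1]; default `percent/100`
#' @return contrast sensitivity (dimensionless, >= 1), vectorized
#' @examples
#' michelsonSensitivity(c(100, 50, 28.6))  # 1, 2, ~3.5
#' @export
michelsonSensitivity <- function(thresholdPercent,
                                 convert = function(p) p / 100) {
  if (any(!is.finite(thresholdPercent)) ||
      any(thresholdPercent <= 0 | thresholdPercent > 100))
    stop("thresholds must lie in (0, 100] percent")
  1 / convert(thresholdPercent)
}

#' Per-animal spatial-frequency improvement
#'
#' Percent change of the spatial-frequency threshold from day 0 to day
#' 7, `100 * (day7 - day0)/day0`, computed per animal (group summaries
#' should average these per-animal percentages, which carries an SEM
#' across animals; the ratio of group means is generally different).
#'
#' @param day0,day7 per-animal thresholds, cyc/deg (equal length)
#' @return per-animal percent improvements
#' @examples
#' sfImprovement(0.37, 0.46)  # 24.3% for this animal
#' @export
sfImprovement <- function(day0, day7) {
  if (length(day0) != length(day7)) stop("day0 and day7 must pair up")
  if (any(is.na(day0)) || any(is.na(day7))) stop("missing day values")
  if (any(day0 <= 0)) stop("day-0 thresholds must be positive")
  100 * (day7 - day0) / day0
}

#' Group spatial-frequency improvement from a behavior table
#'
#' Extracts each animal's day-0 and day-7 `sf_threshold`, computes the
#' per-animal percent improvement and returns the per-animal values
#' with the group mean and SEM.
#'
#' @param table a behavior table (see [simulateBehaviorCohort()])
#' @param group group label to summarize
#' @return list(perAnimal, mean, sem, n)
#' @export
mdImprovement <- function(table, group) {
  sub <- table[table$group == group & table$measure == "sf_threshold", ]
  if (!nrow(sub)) stop("no sf_threshold rows for group '", group, "'")
  d0 <- sub[sub$day == 0, ]
  d7 <- sub[sub$day == 7, ]
  d7 <- d7[match(d0$animal_id, d7$animal_id), ]
  if (any(is.na(d7$value))) stop("missing day-7 values")
  pct <- sfImprovement(d0$value, d7$value)
  list(perAnimal = stats::setNames(pct, d0$animal_id),
       mean = mean(pct), sem = sem(pct), n = length(pct))
}

#' Cohort summary: mean and SEM per cell
#'
#' Group mean and SEM (sd/sqrt(n)) of every group x day x measure x
#' spatial-frequency cell of a behavior table. Singleton cells get an
#' NA SEM and a warning.
#'
#' @param table a behavior table
#' @return data.frame with group, day, measure, spatial_frequency, n,
#'   mean, sem
#' @export
cohortSummary <- function(table) {
  need <- c("animal_id", "group", "day", "measure", "spatial_frequency", "value")
  if (!all(need %in% names(table))) stop("malformed behavior table")
  key <- interaction(table$group, table$day, table$measure,
                     ifelse(is.na(table$spatial_frequency), "na",
                            format(table$spatial_frequency)), drop = TRUE)
  parts <- split(table, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(group = p$group[1], day = p$day[1], measure = p$measure[1],
               spatial_frequency = p$spatial_frequency[1],
               n = nrow(p), mean = mean(p$value),
               sem = if (nrow(p) > 1) sem(p$value) else NA_real_)
  }))
  if (any(out$n == 1))
    warning("singleton cells: SEM undefined (NA)")
  rownames(out) <- NULL
  out[order(out$group, out$measure, out$day, out$spatial_frequency,
            na.last = FALSE), ]
}

#' Contrast sensitivity curve for one day
#'
#' Converts each animal's contrast thresholds to Michelson sensitivities
#' and summarizes mean +/- SEM per group and spatial frequency on the
#' given day, matching the layout in which sensitivity tables are
#' reported (rows = spatial frequency, one block per group).
#'
#' @param table a behavior table
#' @param day test day (default 7)
#' @param convert percent-to-Michelson conversion, see
#'   [michelsonSensitivity()]
#' @return data.frame with group, spatial_frequency, n, sensitivity
#'   (mean), sem
#' @export
sensitivityCurve <- function(table, day = 7, convert = function(p) p / 100) {
  sub <- table[table$measure == "contrast_threshold" & table$day == day, ]
  if (!nrow(sub)) stop("no contrast_threshold rows on day ", day)
  sub$sens <- michelsonSensitivity(sub$value, convert)
  key <- interaction(sub$group, format(sub$spatial_frequency), drop = TRUE)
  out <- do.call(rbind, lapply(split(sub, key), function(p) {
    data.frame(group = p$group[1], spatial_frequency = p$spatial_frequency[1],
               n = nrow(p), sensitivity = mean(p$sens),
               sem = if (nrow(p) > 1) sem(p$sens) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$group, out$spatial_frequency), ]
}
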