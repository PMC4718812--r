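# The six grating spatial frequencies (cyc/deg) at which contrast
# thresholds are measured in the optomotor setup.

#' Standard optomotor spatial-frequency grid
#'
#' The six spatial frequencies (cyc/deg) at which contrast thresholds
#' are measured: 0.031, 0.064, 0.092, 0.103, 0.192, 0.272.
#'
#' @return numeric vector of six spatial frequencies
#' @export
optomotorFrequencies <- function() c(0.031, 0.064, 0.092, 0.103, 0.192, 0.272)

#' Specification of a simulated behavioral cohort
#'
#' Defines the groups of a virtual optomotor experiment. Each group is
#' a list with `label`, `nAnimals` (>= 2), `md` (logical: monocularly
#' deprived, i.e. thresholds ramp from day 0 to day 7; otherwise flat),
#' `day0Sf`/`day7Sf` (spatial-frequency thresholds, cyc/deg) and
#' `csDay0`/`csDay7` (contrast sensitivities at the six standard
#' spatial frequencies). Measurement noise is additive Gaussian with sd
#' `noiseSd` on each recorded value.
#'
#' @param groups list of group definitions (see Details)
#' @param noiseSd per-measurement noise sd
#' @param seed RNG seed
#' @return an object of class `behavior_cohort_spec`
#' @export
behaviorCohortSpec <- function(groups, noiseSd = 0, seed = 1L) {
  if (!length(groups)) stop("empty group list")
  sfGrid <- optomotorFrequencies()
  for (g in groups) {
    stopifnot(is.character(g$label), g$nAnimals >= 2,
              is.logical(g$md), g$day0Sf > 0, g$day7Sf > 0)
    if (length(g$csDay0) != 6L)
      stop("csDay0 must give sensitivities at the six standard frequencies")
    if (length(g$csDay7) != 6L)
      stop("csDay7 must give sensitivities at the six standard frequencies")
    if (any(g$csDay0 < 1) || any(g$csDay7 < 1))
      stop("contrast sensitivities must be >= 1")
  }
  structure(list(groups = groups, noiseSd = noiseSd,
                 seed = as.integer(seed), sfGrid = sfGrid),
            class = "behavior_cohort_spec")
}

#' Simulate an optomotor behavioral cohort
#'
#' Generates a long-format behavior table: one row per animal, day
#' (0-7) and measure. Spatial-frequency thresholds (`sf_threshold`,
#' cyc/deg) and contrast thresholds (`contrast_threshold`, percent, one
#' per standard spatial frequency) of deprived groups ramp linearly
#' from their day-0 to their day-7 values (monotone interpolation);
#' non-deprived groups stay flat. Contrast trajectories are
#' interpolated on the sensitivity scale and stored as the equivalent
#' percent threshold (100/sensitivity). Additive Gaussian measurement
#' noise; fully reproducible under the spec seed.
#'
#' @param spec a [behaviorCohortSpec()]
#' @return data.frame with columns animal_id, group, day, measure,
#'   spatial_frequency, value
#' @export
simulateBehaviorCohort <- function(spec) {
  stopifnot(inherits(spec, "behavior_cohort_spec"))
  days <- 0:7
  rows <- list()
  animalCounter <- 0L
  for (g in spec$groups) {
    for (a in seq_len(g$nAnimals)) {
      animalCounter <- animalCounter + 1L
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", g$label), a)
      w <- if (g$md) days / 7 else rep(0, length(days))
      sf <- g$day0Sf + (g$day7Sf - g$day0Sf) * w
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, group = g$label, day = days,
        measure = "sf_threshold", spatial_frequency = NA_real_,
        value = sf, stringsAsFactors = FALSE)
      for (k in seq_along(spec$sfGrid)) {
        sens <- g$csDay0[k] + (g$csDay7[k] - g$csDay0[k]) * w
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, group = g$label, day = days,
          measure = "contrast_threshold",
          spatial_frequency = spec$sfGrid[k],
          value = 100 / sens, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (spec$noiseSd > 0) {
    tab$value <- withSeed(spec$seed,
      tab$value + stats::rnorm(nrow(tab), sd = spec$noiseSd))
    tab$value <- pmax(tab$value, 1e-6)
    isCt <- tab$measure == "contrast_threshold"
    tab$value[isCt] <- pmin(tab$value[isCt], 100)
  }
  tab
}

#' Preset cohort: healthy adult mice, inhibitor vs vehicle
#'
#' Four groups matching the healthy-brain optomotor design: vehicle
#' controls without MD (n=6, flat 0.37 cyc/deg), vehicle + 7-day MD
#' (n=5, 0.37 -> 0.46 cyc/deg with the corresponding contrast-
#' sensitivity gains), inhibitor-treated without MD (n=5, flat) and
#' inhibitor + MD (n=5, 0.37 -> 0.38: improvement blocked). Contrast
#' sensitivities per spatial frequency follow the published group
#' means.
#'
#' @param noiseSd per-measurement noise sd
#' @param seed RNG seed
#' @return a [behaviorCohortSpec()]
#' @export
cohortPresetHealthy <- function(noiseSd = 0, seed = 1L) {
  behaviorCohortSpec(list(
    list(label = "control", nAnimals = 6L, md = FALSE,
         day0Sf = 0.37, day7Sf = 0.37,
         csDay0 = c(3.6, 12.7, 11.7, 10.3, 6.9, 3.5),
         csDay7 = c(3.6, 12.7, 11.7, 10.5, 7.0, 3.5)),
    list(label = "control+MD", nAnimals = 5L, md = TRUE,
         day0Sf = 0.37, day7Sf = 0.46,
         csDay0 = c(3.5, 11.6, 10.7, 10.0, 7.0, 3.5),
         csDay7 = c(5.1, 26.9, 23.3, 21.8, 13.5, 4.9)),
    list(label = "GM6001", nAnimals = 5L, md = FALSE,
         day0Sf = 0.37, day7Sf = 0.37,
         csDay0 = c(3.5, 11.8, 10.9, 10.2, 6.9, 3.5),
         csDay7 = c(3.5, 11.8, 11.0, 10.3, 7.0, 3.5)),
    list(label = "GM6001+MD", nAnimals = 5L, md = TRUE,
         day0Sf = 0.37, day7Sf = 0.38,
         csDay0 = c(3.5, 12.0, 11.3, 10.6, 6.8, 3.5),
         csDay7 = c(3.6, 12.6, 12.0, 11.3, 7.5, 3.8))
  ), noiseSd = noiseSd, seed = seed)
}

#' Preset cohort: stroke-lesioned mice, inhibitor vs vehicle
#'
#' Four groups matching the post-stroke optomotor design: lesioned
#' vehicle controls with and without MD (improvement lost, flat 0.38
#' cyc/deg) and lesioned inhibitor-treated mice with MD (rescued,
#' 0.38 -> 0.45 cyc/deg, n=14 pooled) or without.
#'
#' @inheritParams cohortPresetHealthy
#' @return a [behaviorCohortSpec()]
#' @export
cohortPresetStroke <- function(noiseSd = 0, seed = 1L) {
  behaviorCohortSpec(list(
    list(label = "PT+vehicle", nAnimals = 4L, md = FALSE,
         day0Sf = 0.38, day7Sf = 0.38,
         csDay0 = c(3.5, 11.4, 10.5, 9.8, 6.9, 3.5),
         csDay7 = c(3.5, 11.4, 10.5, 9.9, 6.9, 3.5)),
    list(label = "PT+MD+vehicle", nAnimals = 4L, md = TRUE,
         day0Sf = 0.38, day7Sf = 0.38,
         csDay0 = c(3.5, 11.8, 10.7, 10.0, 6.7, 3.4),
         csDay7 = c(3.5, 12.1, 11.4, 10.6, 7.0, 3.5)),
    list(label = "PT+GM6001", nAnimals = 4L, md = FALSE,
         day0Sf = 0.38, day7Sf = 0.38,
         csDay0 = c(3.5, 11.4, 10.5, 9.9, 6.7, 3.5),
         csDay7 = c(3.5, 11.5, 10.5, 9.9, 6.8, 3.5)),
    list(label = "PT+MD+GM6001", nAnimals = 14L, md = TRUE,
         day0Sf = 0.38, day7Sf = 0.45,
         csDay0 = c(3.5, 11.8, 11.0, 10.0, 6.5, 3.5),
         csDay7 = c(5.0, 25.2, 21.9, 19.7, 12.8, 4.9))
  ), noiseSd = noiseSd, seed = seed)
}
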