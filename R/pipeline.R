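#' Pipeline configuration
#'
#' One nested configuration object holding every analysis constant, all
#' defaulting to the standard protocol values: acquisition (30 Hz
#' binned to 7.5 Hz, 0.125 Hz stimulus, 70 deg cycle extent, binocular
#' stimulus spanning -5 to +15 deg azimuth), analysis (5x5 uniform
#' kernel, 30%-of-peak responsive threshold, 1e-4 block inclusion,
#' blocks of 4 runs, scatter area of 20,000 pixels at 512x512), and
#' simulation settings (scene, noise, cohort, seed). Round-trips
#' losslessly through YAML via [writePipelineConfig()].
#'
#' @param acquisition,analysis,simulation named lists overriding
#'   individual defaults
#' @return a nested list of class `odi_pipeline_config`
#' @export
pipelineConfig <- function(acquisition = list(), analysis = list(),
                           simulation = list()) {
  acq <- utils::modifyList(list(
    acquisition_rate = 30, binned_rate = 7.5, stim_frequency = 0.125,
    cycle_extent_deg = 70, binocular_span_deg = c(-5, 15)), acquisition)
  ana <- utils::modifyList(list(
    kernel = 5L, mask_fraction = 0.30, inclusion_threshold = 1e-4,
    block_size = 4L, scatter_area_pixels = 20000L,
    scatter_ref_shape = c(512L, 512L)), analysis)
  sim <- utils::modifyList(list(
    image_size = c(64L, 64L), n_cycles = 4L, n_runs = 4L,
    contra_peak = 2e-4, v1_fraction = 0.25, noise_sd = 4e-5, seed = 1L,
    groups = list(list(label = "control", n_animals = 2L, target_odi = 0.25),
                  list(label = "MD", n_animals = 2L, target_odi = 0.05))),
    simulation)
  structure(list(acquisition = acq, analysis = ana, simulation = sim),
            class = "odi_pipeline_config")
}

#' @rdname pipelineConfig
#' @param config a pipeline config
#' @param path YAML file path
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pipelineConfig(acquisition = raw$acquisition, analysis = raw$analysis,
                 simulation = raw$simulation)
}

.configAcq <- function(config) {
  acquisitionConfig(
    acquisitionRate = config$acquisition$acquisition_rate,
    binnedRate = config$acquisition$binned_rate,
    stimFrequency = config$acquisition$stim_frequency,
    nCycles = config$simulation$n_cycles,
    imageSize = config$simulation$image_size)
}

#' Simulate an imaging session to disk
#'
#' Creates one directory per animal under `outdir` (grouped per the
#' config's simulation groups), each holding the rendered runs as
#' multi-page TIFF stacks with YAML sidecars plus the scene-truth
#' sidecars, and writes the simulated behavioral cohort CSV and the
#' effective config YAML at the session root. Deterministic under the
#' config seed.
#'
#' @param config a [pipelineConfig()]
#' @param outdir session directory (created if missing)
#' @return invisibly, the session directory
#' @export
simulateSession <- function(config = pipelineConfig(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  acq <- .configAcq(config)
  sim <- config$simulation
  seed0 <- sim$seed
  aIdx <- 0L
  for (g in sim$groups) {
    scene <- makeOdScene(g$target_odi, contraPeak = sim$contra_peak,
                         shape = sim$image_size, v1Fraction = sim$v1_fraction,
                         extentDeg = config$acquisition$cycle_extent_deg)
    for (a in seq_len(g$n_animals)) {
      aIdx <- aIdx + 1L
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", g$label), a)
      adir <- file.path(outdir, id)
      dir.create(adir, showWarnings = FALSE)
      writeSceneTruth(scene, file.path(adir, "scene"))
      yaml::write_yaml(list(animal_id = id, group = g$label,
                            target_odi = g$target_odi),
                       file.path(adir, "animal.yml"))
      for (eye in c("contra", "ipsi")) for (r in seq_len(sim$n_runs)) {
        nm <- noiseModel(gaussianSd = sim$noise_sd,
                         seed = seed0 + 10000L * aIdx +
                           1000L * (eye == "ipsi") + r)
        st <- renderMovie(scene, eye, acq, nm,
                          runId = sprintf("%s_%s_%02d", id, eye, r))
        writeFrameStack(st, file.path(adir, sprintf("run_%s_%02d.tif", eye, r)))
      }
    }
  }
  beh <- simulateBehaviorCohort(cohortPresetHealthy(noiseSd = 0.005,
                                                    seed = seed0))
  writeBehaviorTable(beh, file.path(outdir, "behavior.csv"))
  writePipelineConfig(config, file.path(outdir, "config.yml"))
  invisible(outdir)
}

.sessionAnimals <- function(sessionDir) {
  dirs <- list.dirs(sessionDir, recursive = FALSE)
  dirs[file.exists(file.path(dirs, "animal.yml"))]
}

.animalRunMaps <- function(adir, config) {
  factor <- as.integer(round(config$acquisition$acquisition_rate /
                               config$acquisition$binned_rate))
  readEye <- function(eye) {
    files <- sort(list.files(adir, sprintf("^run_%s_\\d+\\.tif$", eye),
                             full.names = TRUE))
    lapply(files, function(f) {
      st <- readFrameStack(f)
      if (factor > 1L) st <- binFrames(st, factor)
      extractComponent(st)
    })
  }
  list(contra = readEye("contra"), ipsi = readEye("ipsi"))
}

#' Compute magnitude and retinotopy maps for a session
#'
#' For every animal and run: extracts the stimulus-frequency component,
#' writes the magnitude map (TIFF + grayscale PNG) and the retinotopy
#' map (TIFF + polar PNG with hue = visual-field position, lightness =
#' magnitude).
#'
#' @param sessionDir a directory written by [simulateSession()]
#' @return invisibly, a data.frame of per-run mean display magnitudes
#' @export
sessionMaps <- function(sessionDir) {
  config <- readPipelineConfig(file.path(sessionDir, "config.yml"))
  rows <- list()
  for (adir in .sessionAnimals(sessionDir)) {
    cmaps <- .animalRunMaps(adir, config)
    for (eye in names(cmaps)) for (r in seq_along(cmaps[[eye]])) {
      cm <- cmaps[[eye]][[r]]
      mag <- toMagnitude(cm)
      ret <- toRetinotopy(cm, config$acquisition$cycle_extent_deg)
      base <- file.path(adir, sprintf("map_%s_%02d", eye, r))
      writeMapTiff(mag@values, paste0(base, "_mag.tif"),
                   meta = list(eye = eye, kind = "magnitude"))
      writeMapTiff(ret@positions, paste0(base, "_ret.tif"),
                   meta = list(eye = eye, kind = "retinotopy"))
      renderMagnitudePng(mag, paste0(base, "_mag.png"))
      renderPolarPng(ret, mag, paste0(base, "_polar.png"))
      rows[[length(rows) + 1L]] <- data.frame(
        animal = basename(adir), eye = eye, run = r,
        mean_activation = mean(displayMagnitude(mag)))
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(sessionDir, "activation.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Score ocular dominance for a session
#'
#' Runs the full scoring chain per animal (bin, extract, block
#' assembly, smooth, threshold, inclusion, pixel ODI, block and animal
#' means), writes per-block and per-animal CSVs and an OD color-map PNG
#' per animal. Fails with an error if no animal is scorable.
#'
#' @param sessionDir a session directory
#' @return invisibly, the per-animal data.frame
#' @export
sessionOdi <- function(sessionDir) {
  config <- readPipelineConfig(file.path(sessionDir, "config.yml"))
  ana <- config$analysis
  blockRows <- list(); animalRows <- list()
  for (adir in .sessionAnimals(sessionDir)) {
    info <- yaml::read_yaml(file.path(adir, "animal.yml"))
    cmaps <- .animalRunMaps(adir, config)
    contra <- lapply(cmaps$contra, toMagnitude)
    ipsi <- lapply(cmaps$ipsi, toMagnitude)
    blocks <- lapply(makeRunBlocks(contra, ipsi, ana$block_size), blockOdi,
                     k = ana$kernel, frac = ana$mask_fraction,
                     inclusionThreshold = ana$inclusion_threshold)
    summ <- animalSummary(blocks, animalId = info$animal_id,
                          group = info$group)
    for (b in seq_along(blocks))
      blockRows[[length(blockRows) + 1L]] <- data.frame(
        animal_id = info$animal_id, group = info$group, block = b,
        included = isTRUE(blocks[[b]]@included),
        block_odi = blocks[[b]]@blockOdi)
    animalRows[[length(animalRows) + 1L]] <- data.frame(
      animal_id = info$animal_id, group = info$group,
      n_blocks = length(summ@blockOdis), odi = summ@odi)
    if (summ@scorable) {
      sc <- smoothUniform(blocks[[1]]@contraMap, ana$kernel)
      si <- smoothUniform(blocks[[1]]@ipsiMap, ana$kernel)
      om <- odiMap(sc, si, responsiveMask(si, ana$mask_fraction))
      renderOdMapPng(om, file.path(adir, "od_map.png"))
    }
  }
  blockTab <- do.call(rbind, blockRows)
  animalTab <- do.call(rbind, animalRows)
  utils::write.csv(blockTab, file.path(sessionDir, "odi_blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(animalTab, file.path(sessionDir, "odi_animals.csv"),
                   row.names = FALSE)
  if (all(is.na(animalTab$odi))) stop("no scorable animals in session")
  invisible(animalTab)
}

#' Group statistics report for a session
#'
#' Compares per-animal ODIs across groups (t-test for two groups,
#' Bonferroni-corrected one-way ANOVA otherwise) and runs the
#' repeated-measures ANOVA on the session's behavioral
#' spatial-frequency time course. Writes a results CSV and a
#' human-readable star-annotated text report.
#'
#' @param sessionDir a session directory holding `odi_animals.csv`
#'   (run [sessionOdi()] first) and `behavior.csv`
#' @return invisibly, the combined results data.frame
#' @export
sessionReport <- function(sessionDir) {
  animalTab <- utils::read.csv(file.path(sessionDir, "odi_animals.csv"))
  animalTab <- animalTab[!is.na(animalTab$odi), ]
  groups <- split(animalTab$odi, animalTab$group)
  if (length(groups) < 2) stop("need at least two scorable groups")
  odiRes <- if (length(groups) == 2)
    twoTailedT(groups[[1]], groups[[2]], labels = names(groups))
  else onewayAnovaBonferroni(groups)
  res <- statsTable(odiRes)
  behPath <- file.path(sessionDir, "behavior.csv")
  if (file.exists(behPath)) {
    beh <- readBehaviorTable(behPath)
    sf <- beh[beh$measure == "sf_threshold", ]
    rm <- rmTwowayAnovaBonferroni(data.frame(
      subject = sf$animal_id, group = sf$group, day = sf$day,
      value = sf$value))
    res <- rbind(res, statsTable(rm))
  }
  utils::write.csv(res, file.path(sessionDir, "stats.csv"),
                   row.names = FALSE)
  lines <- c("Group statistics report", "=======================", "",
             sprintf("Animals per group: %s",
                     paste(sprintf("%s n=%d", names(groups),
                                   vapply(groups, length, 1L)),
                           collapse = ", ")), "",
             sprintf("%-14s %-28s p=%.4g adj=%.4g %s", res$test,
                     res$comparison, res$p.value, res$p.adjusted, res$stars))
  writeLines(lines, file.path(sessionDir, "report.txt"))
  invisible(res)
}
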