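# File formats: frame stacks and maps as multi-page TIFF with a YAML
# sidecar, behavior tables as CSV, renderings as PNG.
#
# TIFF samples are stored rescaled to [0, 1] (the storage convention of
# the writer); the affine offset/scale needed to restore physical
# fractional-reflectance values lives in the sidecar, so round-trips
# are lossless up to the 32-bit sample quantisation.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path), ".yml")

.scaleTo01 <- function(x) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  list(data = (x - lo) / scale, offset = lo, scale = scale)
}

#' Write / read a frame stack
#'
#' `writeFrameStack()` stores a [FrameStack-class] as a multi-page
#' 32-bit TIFF plus a YAML sidecar (same basename, `.yml`) holding the
#' acquisition metadata and the affine rescaling applied for storage;
#' `readFrameStack()` restores the stack.
#'
#' @param stack a [FrameStack-class]
#' @param path TIFF file path
#' @return `writeFrameStack()` the path invisibly; `readFrameStack()` a
#'   [FrameStack-class]
#' @export
writeFrameStack <- function(stack, path) {
  d <- dim(stack@data)
  sc <- .scaleTo01(stack@data)
  pages <- lapply(seq_len(d[1]), function(t) matrix(sc$data[t, , ], d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(type = "frame_stack", frames = d[1], rows = d[2], cols = d[3],
               frame_rate = stack@frameRate, stim_frequency = stack@stimFrequency,
               eye = stack@eye, run_id = stack@runId,
               offset = sc$offset, scale = sc$scale)
  yaml::write_yaml(meta, .sidecarPath(path), precision = 17L)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  meta <- yaml::read_yaml(.sidecarPath(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), meta$rows, meta$cols))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  arr <- arr * meta$scale + meta$offset
  new("FrameStack", data = arr, frameRate = meta$frame_rate,
      stimFrequency = meta$stim_frequency, eye = meta$eye,
      runId = meta$run_id)
}

#' Write / read a pixel map
#'
#' Stores a single matrix (magnitude, retinotopy or ODI values) as a
#' one-page 32-bit TIFF with a YAML sidecar carrying the rescaling and
#' a free-form metadata list.
#'
#' @param values numeric matrix
#' @param path TIFF path
#' @param meta named list of extra metadata for the sidecar
#' @return the path invisibly / the matrix with attribute "meta"
#' @export
writeMapTiff <- function(values, path, meta = list()) {
  sc <- .scaleTo01(values)
  tiff::writeTIFF(sc$data, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(c(list(type = "map", rows = nrow(values),
                          cols = ncol(values), offset = sc$offset,
                          scale = sc$scale), meta),
                   .sidecarPath(path), precision = 17L)
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path) {
  meta <- yaml::read_yaml(.sidecarPath(path))
  m <- tiff::readTIFF(path) * meta$scale + meta$offset
  attr(m, "meta") <- meta
  m
}

#' Write / read ground-truth scene sidecars
#'
#' Scene truth is stored as a YAML header (shape, cycle extent) plus
#' one TSV per map (mask, position, contra and ipsi amplitude) sharing
#' the basename — plain-text and diffable.
#'
#' @param scene a [GroundTruthScene-class]
#' @param basename path prefix for the sidecar files
#' @return `writeSceneTruth()` the basename invisibly;
#'   `readSceneTruth()` a [GroundTruthScene-class]
#' @export
writeSceneTruth <- function(scene, basename) {
  shape <- sceneShape(scene)
  yaml::write_yaml(list(type = "scene_truth", rows = shape[1],
                        cols = shape[2], extent_deg = scene@extentDeg),
                   paste0(basename, "_truth.yml"), precision = 17L)
  wtsv <- function(m, tag)
    utils::write.table(m, paste0(basename, "_", tag, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  wtsv(scene@v1Mask * 1L, "mask")
  wtsv(scene@phaseTruth, "phase")
  wtsv(scene@ampContra, "ampContra")
  wtsv(scene@ampIpsi, "ampIpsi")
  invisible(basename)
}

#' @rdname writeSceneTruth
#' @export
readSceneTruth <- function(basename) {
  meta <- yaml::read_yaml(paste0(basename, "_truth.yml"))
  rtsv <- function(tag)
    as.matrix(utils::read.table(paste0(basename, "_", tag, ".tsv"),
                                sep = "\t", header = FALSE))
  mk <- function(m) { dimnames(m) <- NULL; m }
  new("GroundTruthScene",
      v1Mask = mk(rtsv("mask")) > 0,
      phaseTruth = mk(rtsv("phase")),
      ampContra = mk(rtsv("ampContra")),
      ampIpsi = mk(rtsv("ampIpsi")),
      extentDeg = meta$extent_deg)
}

#' Write / read a behavior table as CSV
#'
#' Comma separator, dot decimal, header row; columns animal_id, group,
#' day, measure, spatial_frequency, value.
#'
#' @param table a behavior table data.frame
#' @param path CSV path
#' @return the path invisibly / the data.frame
#' @export
writeBehaviorTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBehaviorTable
#' @export
readBehaviorTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.writeRgbPng <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Render a grayscale activation image
#'
#' Darker = stronger response (the display convention for activity
#' patches), annotated only via the returned mean; values are scaled
#' to the map's peak.
#'
#' @param mag a [MagnitudeMap-class]
#' @param path PNG path
#' @return invisibly, the mean display magnitude (x 1e-4 units)
#' @export
renderMagnitudePng <- function(mag, path) {
  v <- mag@values
  g <- 1 - v / max(v, 1e-12)
  .writeRgbPng(g, path)
  invisible(mean(displayMagnitude(mag)))
}

#' Render a polar retinotopy map
#'
#' Hue encodes visual-field position over the stimulus cycle, lightness
#' encodes response magnitude — the standard polar-map display.
#'
#' @param retino a [RetinotopyMap-class]
#' @param mag a [MagnitudeMap-class] of the same shape
#' @param path PNG path
#' @return the path invisibly
#' @export
renderPolarPng <- function(retino, mag, path) {
  h <- retino@positions / retino@cycleExtent
  vmax <- max(mag@values, 1e-12)
  v <- pmin(mag@values / vmax, 1)
  cols <- grDevices::hsv(h = pmin(h, 0.999), s = 1, v = v)
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, dim = c(nrow(h), ncol(h), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, ], nrow(h), ncol(h))
  .writeRgbPng(arr, path)
}

#' Render a 2-D ocular dominance map
#'
#' Warm colors (red) mark contralateral, cold colors (blue) ipsilateral
#' dominance; pixels off the responsive mask are gray.
#'
#' @param odi an [OdiMap-class]
#' @param path PNG path
#' @return the path invisibly
#' @export
renderOdMapPng <- function(odi, path) {
  v <- odi@values
  arr <- array(0.5, dim = c(nrow(v), ncol(v), 3))   # gray background
  m <- odi@mask & !is.na(v)
  x <- (v[m] + 1) / 2                               # 0 = ipsi, 1 = contra
  arr[, , 1][m] <- x
  arr[, , 2][m] <- 1 - abs(v[m])
  arr[, , 3][m] <- 1 - x
  .writeRgbPng(arr, path)
}
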