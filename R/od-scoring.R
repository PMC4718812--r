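#' Uniform-kernel smoothing of a magnitude map
#'
#' Low-pass filters a response magnitude map with a k x k uniform (box)
#' kernel to reduce pixel shot noise; the default 5x5 kernel is the
#' standard choice. Borders are handled by reflection so edge
#' magnitudes are not biased toward zero.
#'
#' @param map a [MagnitudeMap-class] or numeric matrix
#' @param k odd kernel width in pixels (k = 1 is the identity)
#' @return same type as `map`, smoothed
#' @export
smoothUniform <- function(map, k = 5L) {
  k <- as.integer(k)
  if (length(k) != 1L || k < 1L || k %% 2L == 0L)
    stop("kernel width k must be an odd integer >= 1")
  if (is(map, "MagnitudeMap"))
    new("MagnitudeMap", values = boxMeanReflect(map@values, k), eye = map@eye)
  else
    boxMeanReflect(as.matrix(map), k)
}

#' Responsive-pixel mask by fractional peak threshold
#'
#' Keeps pixels whose (already smoothed) response magnitude reaches at
#' least `frac` of the map's peak — the standard 30%-of-peak rule for
#' eliminating background noise.
#'
#' @param map a [MagnitudeMap-class] or numeric matrix (smooth first;
#'   this function does not smooth)
#' @param frac threshold fraction of the peak, in (0, 1)
#' @return logical matrix mask
#' @export
responsiveMask <- function(map, frac = 0.30) {
  v <- if (is(map, "MagnitudeMap")) map@values else as.matrix(map)
  scalarNumber(frac, "frac")
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  peak <- max(v)
  if (peak <= 0) stop("no responsive pixels: map has no positive peak")
  v >= frac * peak
}

#' Per-pixel ocular dominance index map
#'
#' ODI = (C - I)/(C + I) on the responsive mask, where C and I are the
#' contralateral- and ipsilateral-eye response magnitudes of each pixel.
#' Negative values mark ipsilateral, positive contralateral dominance.
#' Masked pixels with C + I = 0 are dropped from the mask (count
#' reported via `message()`).
#'
#' @param contra,ipsi [MagnitudeMap-class] objects (or matrices) of the
#'   same shape
#' @param mask logical matrix of responsive pixels
#' @return an [OdiMap-class]
#' @export
odiMap <- function(contra, ipsi, mask) {
  C <- if (is(contra, "MagnitudeMap")) contra@values else as.matrix(contra)
  I <- if (is(ipsi, "MagnitudeMap")) ipsi@values else as.matrix(ipsi)
  if (!identical(dim(C), dim(I)) || !identical(dim(C), dim(mask)))
    stop("contra, ipsi and mask must share one shape")
  mask <- mask & TRUE
  denom <- C + I
  bad <- mask & denom <= 0
  if (any(bad)) {
    message(sum(bad), " masked pixel(s) with zero summed response dropped")
    mask <- mask & !bad
  }
  vals <- matrix(NA_real_, nrow(C), ncol(C))
  vals[mask] <- (C[mask] - I[mask]) / denom[mask]
  new("OdiMap", values = vals, mask = mask)
}

#' @rdname accessors
setMethod("meanOdi", "OdiMap", function(object) {
  if (!any(object@mask)) stop("empty responsive mask")
  mean(object@values[object@mask])
})

#' Assemble run blocks from per-run magnitude maps
#'
#' Groups consecutive runs (acquisition order) into blocks of
#' `blockSize` and averages each eye's magnitude maps within a block;
#' a trailing partial block is dropped with a warning.
#'
#' @param contraMaps,ipsiMaps lists of [MagnitudeMap-class], one per
#'   run, in acquisition order
#' @param blockSize runs per block (default 4)
#' @return list of unscored [RunBlock-class] objects
#' @export
makeRunBlocks <- function(contraMaps, ipsiMaps, blockSize = 4L) {
  blockSize <- as.integer(blockSize)
  if (blockSize < 1L) stop("blockSize must be >= 1")
  n <- length(contraMaps)
  if (length(ipsiMaps) != n) stop("need one ipsi map per contra map")
  nBlocks <- n %/% blockSize
  if (nBlocks < 1L) stop("fewer runs than one block")
  if (n %% blockSize)
    warning(sprintf("dropping %d trailing run(s) not filling a block",
                    n %% blockSize))
  avg <- function(maps) {
    vals <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
    new("MagnitudeMap", values = vals, eye = maps[[1]]@eye)
  }
  lapply(seq_len(nBlocks), function(b) {
    idx <- (b - 1L) * blockSize + seq_len(blockSize)
    new("RunBlock", contraMap = avg(contraMaps[idx]),
        ipsiMap = avg(ipsiMaps[idx]), nRuns = blockSize,
        included = NA, blockOdi = NA_real_)
  })
}

#' Score a run block
#'
#' Applies the full per-block scoring chain: both eyes' averaged maps
#' are smoothed with the uniform kernel, each eye's responsive mask is
#' taken at `frac` of its smoothed peak, and the block is included only
#' if both eyes' mean magnitude over their own responsive mask reaches
#' `inclusionThreshold` (default 1e-4 fractional reflectance). For
#' included blocks the ODI mask is derived from the ipsilateral map
#' (`maskFrom = "ipsi"`, the literal rule; `"both"` intersects the two
#' eyes' masks, `"contra"` uses the contralateral map) and the block
#' ODI is the mean pixel ODI over that mask.
#'
#' @param block a [RunBlock-class] from [makeRunBlocks()]
#' @param k uniform kernel width (pixels)
#' @param frac responsive threshold fraction of peak
#' @param inclusionThreshold minimum mean responsive magnitude per eye
#' @param maskFrom which eye's map defines the ODI mask
#' @return the scored [RunBlock-class] (exclusion is a valid outcome:
#'   `included` FALSE, `blockOdi` NA)
#' @export
blockOdi <- function(block, k = 5L, frac = 0.30, inclusionThreshold = 1e-4,
                     maskFrom = c("ipsi", "both", "contra")) {
  maskFrom <- match.arg(maskFrom)
  sc <- smoothUniform(block@contraMap, k)
  si <- smoothUniform(block@ipsiMap, k)
  mc <- responsiveMask(sc, frac)
  mi <- responsiveMask(si, frac)
  magC <- mean(sc@values[mc])
  magI <- mean(si@values[mi])
  # relative epsilon so the "at least" rule is robust to filter round-off
  thr <- inclusionThreshold * (1 - 1e-9)
  block@included <- magC >= thr && magI >= thr
  if (!block@included) {
    message(sprintf(
      "block excluded: mean responsive magnitude contra %.2g, ipsi %.2g (< %.2g)",
      magC, magI, inclusionThreshold))
    block@blockOdi <- NA_real_
    return(block)
  }
  mask <- switch(maskFrom, ipsi = mi, contra = mc, both = mi & mc)
  block@blockOdi <- meanOdi(odiMap(sc, si, mask))
  block
}

#' Per-animal ODI summary
#'
#' Averages the included blocks' ODIs (unweighted); an animal with no
#' included block is flagged unscorable.
#'
#' @param blocks list of scored [RunBlock-class] objects
#' @param animalId,group labels
#' @return an [AnimalOdiSummary-class]
#' @export
animalSummary <- function(blocks, animalId = "animal", group = "group") {
  scored <- vapply(blocks, function(b) isTRUE(b@included), logical(1))
  odis <- vapply(blocks[scored], function(b) b@blockOdi, numeric(1))
  if (!length(odis)) {
    message(sprintf("animal '%s' unscorable: no included blocks", animalId))
    return(new("AnimalOdiSummary", animalId = animalId, group = group,
               blockOdis = numeric(0), odi = NA_real_, scorable = FALSE))
  }
  new("AnimalOdiSummary", animalId = animalId, group = group,
      blockOdis = odis, odi = mean(odis), scorable = TRUE)
}

#' Simulate and score one animal end to end
#'
#' Renders `nRuns` noisy movies per eye from a ground-truth scene,
#' temporally bins to the configured binned rate, extracts the
#' stimulus-frequency component per run, assembles the runs into
#' blocks, scores each block (smooth, threshold, inclusion, pixel ODI)
#' and returns the animal summary. This is the parameter-recovery
#' driver used to check the scoring chain against designed ODIs.
#'
#' @param scene a [GroundTruthScene-class] (e.g. [makeOdScene()])
#' @param acq an [AcquisitionConfig-class]
#' @param noiseSd per pixel-frame Gaussian noise sd (fractional
#'   reflectance)
#' @param nRuns runs per eye
#' @param blockSize runs per block
#' @param seed base seed; each run/eye derives its own stream
#' @param animalId,group labels for the summary
#' @param ... further arguments to [blockOdi()]
#' @return an [AnimalOdiSummary-class]
#' @export
simulateOdAnimal <- function(scene, acq = acquisitionConfig(), noiseSd = 0,
                             nRuns = 4L, blockSize = 4L, seed = 1L,
                             animalId = "animal", group = "group", ...) {
  factor <- as.integer(round(acq@acquisitionRate / acq@binnedRate))
  oneEye <- function(eye, offset) {
    lapply(seq_len(nRuns), function(r) {
      nm <- noiseModel(gaussianSd = noiseSd, seed = seed + offset + r)
      st <- renderMovie(scene, eye, acq, nm,
                        runId = sprintf("%s_%s_run%d", animalId, eye, r))
      if (factor > 1L) st <- binFrames(st, factor)
      toMagnitude(extractComponent(st))
    })
  }
  contra <- oneEye("contra", 0L)
  ipsi <- oneEye("ipsi", 1000L)
  blocks <- lapply(makeRunBlocks(contra, ipsi, blockSize), blockOdi, ...)
  animalSummary(blocks, animalId = animalId, group = group)
}
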