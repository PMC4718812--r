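#' Accessors for odimaps objects
#'
#' Small accessor family: `mapValues()` returns the pixel matrix of a
#' map object, `responseCoef()` the complex coefficient matrix,
#' `stackData()` the raw frame array, `eyeLabel()` the stimulated eye,
#' `odiTruth()` a scene's ground-truth ODI map, `sceneShape()` its
#' pixel dimensions, `meanOdi()` the mean ODI over responsive pixels,
#' `scatterValue()` the scalar scatter index, `isIncluded()` a run
#' block's inclusion flag, and `statsTable()` the result table of a
#' [StatsResult-class].
#'
#' @param object an odimaps S4 object
#' @return see the individual generic's description
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("responseCoef", function(object) standardGeneric("responseCoef"))
#' @rdname accessors
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("stimFrequency", function(object) standardGeneric("stimFrequency"))
#' @rdname accessors
#' @export
setGeneric("eyeLabel", function(object) standardGeneric("eyeLabel"))
#' @rdname accessors
#' @export
setGeneric("odiTruth", function(object) standardGeneric("odiTruth"))
#' @rdname accessors
#' @export
setGeneric("sceneShape", function(object) standardGeneric("sceneShape"))
#' @rdname accessors
#' @export
setGeneric("meanOdi", function(object) standardGeneric("meanOdi"))
#' @rdname accessors
#' @export
setGeneric("scatterValue", function(object) standardGeneric("scatterValue"))
#' @rdname accessors
#' @export
setGeneric("isIncluded", function(object) standardGeneric("isIncluded"))
#' @rdname accessors
#' @export
setGeneric("statsTable", function(object) standardGeneric("statsTable"))

#' Number of frames in one run
#'
#' @param object an [AcquisitionConfig-class]
#' @param binned if TRUE, count after temporal binning
#' @return integer frame count: `nCycles * rate / stimFrequency`
#' @export
setGeneric("framesPerRun", function(object, binned = FALSE)
  standardGeneric("framesPerRun"))

#' @rdname accessors
setMethod("mapValues", "MagnitudeMap", function(object) object@values)
#' @rdname accessors
setMethod("mapValues", "RetinotopyMap", function(object) object@positions)
#' @rdname accessors
setMethod("mapValues", "OdiMap", function(object) object@values)
#' @rdname accessors
setMethod("responseCoef", "ComplexResponseMap", function(object) object@coef)
#' @rdname accessors
setMethod("stackData", "FrameStack", function(object) object@data)
#' @rdname accessors
setMethod("frameRate", "FrameStack", function(object) object@frameRate)
#' @rdname accessors
setMethod("stimFrequency", "FrameStack", function(object) object@stimFrequency)
#' @rdname accessors
setMethod("stimFrequency", "ComplexResponseMap", function(object) object@stimFrequency)
#' @rdname accessors
setMethod("stimFrequency", "AcquisitionConfig", function(object) object@stimFrequency)
#' @rdname accessors
setMethod("eyeLabel", "FrameStack", function(object) object@eye)
#' @rdname accessors
setMethod("eyeLabel", "ComplexResponseMap", function(object) object@eye)
#' @rdname accessors
setMethod("eyeLabel", "MagnitudeMap", function(object) object@eye)

#' @rdname accessors
setMethod("odiTruth", "GroundTruthScene", function(object) {
  s <- object@ampContra + object@ampIpsi
  out <- matrix(NA_real_, nrow(s), ncol(s))
  ok <- s > 0
  out[ok] <- (object@ampContra[ok] - object@ampIpsi[ok]) / s[ok]
  out
})
#' @rdname accessors
setMethod("sceneShape", "GroundTruthScene", function(object) dim(object@v1Mask))

#' @rdname accessors
setMethod("scatterValue", "ScatterResult", function(object) object@scatter)
#' @rdname accessors
setMethod("isIncluded", "RunBlock", function(object) object@included)
#' @rdname accessors
setMethod("statsTable", "StatsResult", function(object) object@results)

setMethod("framesPerRun", "AcquisitionConfig", function(object, binned = FALSE) {
  rate <- if (binned) object@binnedRate else object@acquisitionRate
  as.integer(round(object@nCycles * rate / object@stimFrequency))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig:", object@acquisitionRate, "Hz acquisition,",
      object@binnedRate, "Hz binned; stimulus", object@stimFrequency, "Hz;",
      object@nCycles, "cycles;",
      paste(object@imageSize, collapse = "x"), "px\n")
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack '%s' (%s eye): %d frames of %dx%d at %g Hz, stimulus %g Hz\n",
              object@runId, object@eye, d[1], d[2], d[3],
              object@frameRate, object@stimFrequency))
})

setMethod("show", "GroundTruthScene", function(object) {
  d <- dim(object@v1Mask)
  cat(sprintf("GroundTruthScene %dx%d px, %d responsive px, cycle extent %g deg\n",
              d[1], d[2], sum(object@v1Mask), object@extentDeg))
  m <- odiTruth(object)
  if (any(object@v1Mask))
    cat(sprintf("  mean ground-truth ODI in mask: %.4f\n",
                mean(m[object@v1Mask], na.rm = TRUE)))
})

setMethod("show", "ComplexResponseMap", function(object) {
  cat(sprintf("ComplexResponseMap (%s eye) %dx%d at %g Hz; peak magnitude %.3g\n",
              object@eye, nrow(object@coef), ncol(object@coef),
              object@stimFrequency, max(Mod(object@coef))))
})

setMethod("show", "MagnitudeMap", function(object) {
  cat(sprintf("MagnitudeMap (%s eye) %dx%d; mean %.2f, peak %.2f (x1e-4)\n",
              object@eye, nrow(object@values), ncol(object@values),
              mean(object@values) * 1e4, max(object@values) * 1e4))
})

setMethod("show", "RetinotopyMap", function(object) {
  cat(sprintf("RetinotopyMap %dx%d, cycle extent %g deg, range [%.2f, %.2f] deg\n",
              nrow(object@positions), ncol(object@positions),
              object@cycleExtent, min(object@positions), max(object@positions)))
})

setMethod("show", "OdiMap", function(object) {
  n <- sum(object@mask)
  cat(sprintf("OdiMap %dx%d, %d responsive px", nrow(object@values),
              ncol(object@values), n))
  if (n > 0) cat(sprintf(", mean ODI %.4f", mean(object@values[object@mask], na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "RunBlock", function(object) {
  cat(sprintf("RunBlock of %d runs: %s", object@nRuns,
              if (isTRUE(object@included)) "included" else "excluded"))
  if (!is.na(object@blockOdi)) cat(sprintf(", block ODI %.4f", object@blockOdi))
  cat("\n")
})

setMethod("show", "AnimalOdiSummary", function(object) {
  cat(sprintf("Animal '%s' (%s): %d included block(s)", object@animalId,
              object@group, length(object@blockOdis)))
  if (object@scorable) cat(sprintf(", ODI %.4f", object@odi))
  else cat(", unscorable")
  cat("\n")
})

setMethod("show", "ScatterResult", function(object) {
  cat(sprintf("ScatterResult: scatter %.4f deg over %d pixels\n",
              object@scatter, object@nUsed))
})

setMethod("show", "StatsResult", function(object) {
  cat(object@method, "\n")
  df <- object@results
  df$p.value <- signif(df$p.value, 4)
  df$p.adjusted <- signif(df$p.adjusted, 4)
  df$statistic <- signif(df$statistic, 4)
  print(df, row.names = FALSE)
  if (length(object@notes)) cat("notes:", paste(object@notes, collapse = "; "), "\n")
})
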