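#' @import methods
NULL

#' Acquisition configuration for a periodic-stimulus imaging run
#'
#' Holds the timing and geometry of one intrinsic-signal acquisition:
#' camera frame rate, the rate after temporal binning, the temporal
#' frequency of the periodic visual stimulus, the number of stimulus
#' cycles recorded per run, and the image size in pixels.
#'
#' Validity requires that the binned rate divides the acquisition rate
#' and that the binned rate is an integer multiple of the stimulation
#' frequency, so that a run always contains a whole number of frames
#' per stimulus cycle.
#'
#' @slot acquisitionRate camera frame rate, frames/s
#' @slot binnedRate frame rate after temporal binning, frames/s
#' @slot stimFrequency stimulus temporal frequency, Hz
#' @slot nCycles number of stimulus cycles per run
#' @slot imageSize integer vector (rows, cols) in pixels
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    acquisitionRate = "numeric",
    binnedRate      = "numeric",
    stimFrequency   = "numeric",
    nCycles         = "integer",
    imageSize       = "integer"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msgs <- character()
  if (object@acquisitionRate <= 0 || object@binnedRate <= 0)
    msgs <- c(msgs, "frame rates must be positive")
  if (object@stimFrequency <= 0)
    msgs <- c(msgs, "stimFrequency must be positive")
  if (!isTRUE(all.equal(object@acquisitionRate %% object@binnedRate, 0)) &&
      !isTRUE(all.equal(object@acquisitionRate %% object@binnedRate, object@binnedRate)))
    msgs <- c(msgs, "binnedRate must divide acquisitionRate")
  fpc <- object@binnedRate / object@stimFrequency
  if (abs(fpc - round(fpc)) > 1e-9)
    msgs <- c(msgs, "binnedRate/stimFrequency must be an integer (whole frames per cycle)")
  if (length(object@nCycles) != 1L || object@nCycles < 1L)
    msgs <- c(msgs, "nCycles must be a single integer >= 1")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L))
    msgs <- c(msgs, "imageSize must be two positive integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AcquisitionConfig
#'
#' Defaults follow the standard mouse intrinsic-signal protocol: frames
#' acquired at 30 Hz and temporally binned to 7.5 Hz, a drifting-bar
#' stimulus at 0.125 Hz, and a scaled-down 64x64 test geometry
#' (512x512 full-scale acquisition is supported the same way).
#'
#' @param acquisitionRate camera frame rate (frames/s)
#' @param binnedRate post-binning frame rate (frames/s)
#' @param stimFrequency stimulus frequency (Hz)
#' @param nCycles stimulus cycles per run
#' @param imageSize (rows, cols) in pixels
#' @return an [AcquisitionConfig-class] object
#' @examples
#' acq <- acquisitionConfig()
#' framesPerRun(acq)   # 960 at 30 Hz for 4 cycles of 0.125 Hz
#' @export
acquisitionConfig <- function(acquisitionRate = 30, binnedRate = 7.5,
                              stimFrequency = 0.125, nCycles = 4L,
                              imageSize = c(64L, 64L)) {
  new("AcquisitionConfig",
      acquisitionRate = as.numeric(acquisitionRate),
      binnedRate      = as.numeric(binnedRate),
      stimFrequency   = as.numeric(stimFrequency),
      nCycles         = as.integer(nCycles),
      imageSize       = as.integer(imageSize))
}

#' Noise model for simulated reflectance movies
#'
#' Additive i.i.d. Gaussian noise per pixel and frame (emulating shot
#' noise) plus an optional slow global sinusoid at a non-stimulus
#' frequency (emulating hemodynamic/illumination drift). The seed makes
#' rendering fully reproducible.
#'
#' @slot gaussianSd standard deviation, fractional reflectance units
#' @slot driftAmp amplitude of the slow sinusoid, fractional reflectance
#' @slot driftFrequency frequency of the drift sinusoid, Hz
#' @slot seed integer RNG seed
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(gaussianSd = "numeric", driftAmp = "numeric",
                 driftFrequency = "numeric", seed = "integer")
)

setValidity("NoiseModel", function(object) {
  msgs <- character()
  if (object@gaussianSd < 0) msgs <- c(msgs, "gaussianSd must be >= 0")
  if (object@driftAmp < 0) msgs <- c(msgs, "driftAmp must be >= 0")
  if (object@driftFrequency <= 0) msgs <- c(msgs, "driftFrequency must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NoiseModel-class
#' @param gaussianSd,driftAmp,driftFrequency,seed see slot descriptions
#' @return a [NoiseModel-class] object
#' @export
noiseModel <- function(gaussianSd = 0, driftAmp = 0, driftFrequency = 0.02,
                       seed = 1L) {
  new("NoiseModel", gaussianSd = as.numeric(gaussianSd),
      driftAmp = as.numeric(driftAmp),
      driftFrequency = as.numeric(driftFrequency), seed = as.integer(seed))
}

#' Ground-truth imaging scene
#'
#' A simulated patch of visual cortex: a boolean mask of responsive
#' cortex (the binocular zone), a per-pixel ground-truth visual-field
#' position (degrees), and per-pixel response amplitude maps for
#' stimulation through the contralateral and ipsilateral eye
#' (fractional reflectance change, typically a few 1e-4).
#'
#' @slot v1Mask logical matrix, responsive cortex
#' @slot phaseTruth numeric matrix, visual-field position in degrees
#' @slot ampContra,ampIpsi numeric matrices, response amplitudes
#' @slot extentDeg degrees of visual field spanned by one stimulus cycle
#' @exportClass GroundTruthScene
setClass("GroundTruthScene",
  representation(v1Mask = "matrix", phaseTruth = "matrix",
                 ampContra = "matrix", ampIpsi = "matrix",
                 extentDeg = "numeric")
)

setValidity("GroundTruthScene", function(object) {
  msgs <- character()
  dm <- dim(object@v1Mask)
  if (!identical(dim(object@phaseTruth), dm) ||
      !identical(dim(object@ampContra), dm) ||
      !identical(dim(object@ampIpsi), dm))
    msgs <- c(msgs, "all scene maps must share one shape")
  if (any(object@ampContra < 0) || any(object@ampIpsi < 0))
    msgs <- c(msgs, "amplitudes must be non-negative")
  if (object@extentDeg <= 0)
    msgs <- c(msgs, "extentDeg must be positive")
  if (any(object@phaseTruth < 0 | object@phaseTruth > object@extentDeg))
    msgs <- c(msgs, "phaseTruth must lie within [0, extentDeg]")
  if (length(msgs)) msgs else TRUE
})

#' One run's reflectance movie
#'
#' A time x rows x cols array of fractional reflectance changes together
#' with its acquisition metadata: frame rate, stimulation frequency, the
#' stimulated eye, and a run identifier.
#'
#' @slot data numeric array, time x rows x cols
#' @slot frameRate frames/s
#' @slot stimFrequency Hz
#' @slot eye "contra" or "ipsi"
#' @slot runId character run label
#' @exportClass FrameStack
setClass("FrameStack",
  representation(data = "array", frameRate = "numeric",
                 stimFrequency = "numeric", eye = "character",
                 runId = "character")
)

setValidity("FrameStack", function(object) {
  msgs <- character()
  if (length(dim(object@data)) != 3L)
    msgs <- c(msgs, "data must be a 3-D array (time x rows x cols)")
  if (!object@eye %in% c("contra", "ipsi"))
    msgs <- c(msgs, "eye must be 'contra' or 'ipsi'")
  if (object@frameRate <= 0 || object@stimFrequency <= 0)
    msgs <- c(msgs, "frameRate and stimFrequency must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Per-pixel complex response at the stimulation frequency
#'
#' The complex Fourier coefficient of each pixel's time course at the
#' stimulus frequency, amplitude-calibrated so a pure sinusoid of
#' amplitude A yields modulus A. Its modulus is the response magnitude
#' (neuronal activation); its argument encodes retinotopy.
#'
#' @slot coef complex matrix
#' @slot stimFrequency Hz
#' @slot eye stimulated eye
#' @exportClass ComplexResponseMap
setClass("ComplexResponseMap",
  representation(coef = "matrix", stimFrequency = "numeric",
                 eye = "character")
)

#' Per-pixel response magnitude map
#'
#' Response magnitudes in fractional reflectance change; the display
#' convention throughout is value x 1e4 (see [displayMagnitude()]).
#'
#' @slot values numeric matrix, >= 0
#' @slot eye stimulated eye
#' @exportClass MagnitudeMap
setClass("MagnitudeMap",
  representation(values = "matrix", eye = "character")
)

setValidity("MagnitudeMap", function(object) {
  if (any(object@values < 0)) "magnitudes must be non-negative" else TRUE
})

#' Per-pixel retinotopic position map
#'
#' Visual-field positions in degrees, derived from response phase; one
#' stimulus cycle spans `cycleExtent` degrees, so positions lie in
#' [0, cycleExtent).
#'
#' @slot positions numeric matrix, degrees
#' @slot cycleExtent degrees per stimulus cycle
#' @exportClass RetinotopyMap
setClass("RetinotopyMap",
  representation(positions = "matrix", cycleExtent = "numeric")
)

setValidity("RetinotopyMap", function(object) {
  if (object@cycleExtent <= 0) return("cycleExtent must be positive")
  if (any(object@positions < 0 | object@positions >= object@cycleExtent))
    return("positions must lie in [0, cycleExtent)")
  TRUE
})

#' Per-pixel ocular dominance index map
#'
#' ODI = (C - I)/(C + I) per responsive pixel, where C and I are the
#' response magnitudes to contralateral and ipsilateral eye stimulation.
#' +1 is fully contralateral, -1 fully ipsilateral. Values are NA off
#' the responsive mask.
#'
#' @slot values numeric matrix, ODI in \[-1, 1\] on mask, NA elsewhere
#' @slot mask logical matrix of responsive pixels used
#' @exportClass OdiMap
setClass("OdiMap",
  representation(values = "matrix", mask = "matrix")
)

setValidity("OdiMap", function(object) {
  v <- object@values[object@mask]
  if (any(!is.na(v) & (v < -1 | v > 1)))
    return("masked ODI values must lie in [-1, 1]")
  TRUE
})

#' A block of averaged imaging runs
#'
#' Magnitude maps averaged over a block of consecutive runs (one block
#' per eye pair, default 4 runs), its inclusion flag under the response
#' magnitude criterion, and the scalar block ODI once scored.
#'
#' @slot contraMap,ipsiMap [MagnitudeMap-class] averaged over the block
#' @slot nRuns number of runs averaged
#' @slot included whether the block passed the inclusion rule
#' @slot blockOdi scalar ODI (NA until scored or if excluded)
#' @exportClass RunBlock
setClass("RunBlock",
  representation(contraMap = "MagnitudeMap", ipsiMap = "MagnitudeMap",
                 nRuns = "integer", included = "logical",
                 blockOdi = "numeric")
)

#' Per-animal ODI summary
#'
#' The included blocks' ODIs (typically 3-5 per animal) and their
#' unweighted mean; `scorable` is FALSE when no block passed inclusion.
#'
#' @slot animalId,group labels
#' @slot blockOdis included blocks' scalar ODIs
#' @slot odi mean of blockOdis (NA if unscorable)
#' @slot scorable at least one included block
#' @exportClass AnimalOdiSummary
setClass("AnimalOdiSummary",
  representation(animalId = "character", group = "character",
                 blockOdis = "numeric", odi = "numeric",
                 scorable = "logical")
)

#' Retinotopic map-quality (scatter) result
#'
#' For each evaluable pixel of the selected responsive area, the
#' difference between its visual-field position and the mean position of
#' its 24 surrounding pixels; the scatter index is the standard
#' deviation of these differences (degrees), small for smooth maps.
#'
#' @slot mask logical matrix of pixels actually evaluated
#' @slot diffs numeric matrix of position differences (NA where skipped)
#' @slot scatter scalar scatter index, degrees
#' @slot nUsed number of pixels entering the index
#' @exportClass ScatterResult
setClass("ScatterResult",
  representation(mask = "matrix", diffs = "matrix", scatter = "numeric",
                 nUsed = "integer")
)

#' Statistical test result set
#'
#' A uniform container for the statistics battery: one row per test or
#' comparison with the statistic, raw and adjusted p-values, and
#' significance stars (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @slot results data.frame with columns test, comparison, statistic,
#'   df, p.value, p.adjusted, adjust.method, stars
#' @slot method description of the procedure
#' @slot notes character vector of caveats/flags
#' @exportClass StatsResult
setClass("StatsResult",
  representation(results = "data.frame", method = "character",
                 notes = "character")
)

setValidity("StatsResult", function(object) {
  p <- object@results$p.value
  pa <- object@results$p.adjusted
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values must lie in [0,1]")
  if (any(!is.na(pa) & (pa < 0 | pa > 1))) return("adjusted p-values must lie in [0,1]")
  ok <- is.na(p) | is.na(pa) | pa >= p - 1e-12
  if (!all(ok)) return("adjusted p must be >= raw p")
  TRUE
})
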