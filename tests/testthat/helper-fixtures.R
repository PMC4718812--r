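# Small in-code fixtures shared across test files.

# A FrameStack built directly from an array (bypassing the renderer).
stackFromArray <- function(arr, frameRate, stimFrequency, eye = "contra") {
  new("FrameStack", data = arr, frameRate = frameRate,
      stimFrequency = stimFrequency, eye = eye, runId = "test")
}

# Single-pixel trace as a T x 1 x 1 stack.
traceStack <- function(x, frameRate, stimFrequency, eye = "contra") {
  stackFromArray(array(x, dim = c(length(x), 1, 1)), frameRate,
                 stimFrequency, eye)
}

# A scene with uniform amplitude over the whole image and a given
# phase matrix (degrees within [0, extent]).
uniformScene <- function(phase, amp = 2e-4, extent = 70) {
  z <- matrix(amp, nrow(phase), ncol(phase))
  new("GroundTruthScene", v1Mask = matrix(TRUE, nrow(phase), ncol(phase)),
      phaseTruth = phase, ampContra = z, ampIpsi = z, extentDeg = extent)
}

# Independent brute-force DFT at the stimulus bin: plain O(T) sum per
# pixel, no DC removal (whole cycles make it irrelevant at this bin).
bruteForceCoef <- function(arr, frameRate, stimFrequency) {
  d <- dim(arr)
  T <- d[1]
  out <- matrix(complex(real = 0, imaginary = 0), d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    s <- 0 + 0i
    for (k in seq_len(T)) {
      t <- (k - 1) / frameRate
      s <- s + arr[k, i, j] * exp(-2i * pi * stimFrequency * t)
    }
    out[i, j] <- 2 * s / T
  }
  out
}

# Circular absolute difference between positions on a cycle.
circDiff <- function(a, b, extent) {
  d <- abs(a - b) %% extent
  pmin(d, extent - d)
}

# RetinotopyMap built directly from a position matrix.
retinoFromPositions <- function(pos, extent = 70) {
  new("RetinotopyMap", positions = pos %% extent, cycleExtent = extent)
}

# Scaled-down acquisition used by recovery tests: rendering directly at
# the binned rate (binning itself is tested separately).
binnedRateAcq <- function(shape = c(64L, 64L), nCycles = 4L) {
  acquisitionConfig(acquisitionRate = 7.5, binnedRate = 7.5,
                    stimFrequency = 0.125, nCycles = nCycles,
                    imageSize = as.integer(shape))
}

# extractComponent for intentionally short (single-cycle) test stacks.
extractQuiet <- function(st) suppressWarnings(extractComponent(st))
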