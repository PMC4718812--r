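#' Linear ground-truth retinotopy
#'
#' Builds a scene whose visual-field position increases linearly along
#' the column axis from 0 degrees at the first column to `extentDeg` at
#' the last, and is constant along rows — the idealised retinotopic
#' gradient a drifting periodic bar produces across cortex. Amplitude
#' maps are left at zero; combine with [makeOdScene()] or set amplitudes
#' directly for a renderable scene.
#'
#' @param extentDeg visual-field extent of one stimulus cycle, degrees
#'   (70 for the standard drifting-bar full-field stimulus)
#' @param shape integer (rows, cols), at least 5x5
#' @return a [GroundTruthScene-class] with the phase ramp, an all-TRUE
#'   mask and zero amplitudes
#' @examples
#' sc <- makeLinearRetinotopy(70, c(64, 64))
#' range(sc@phaseTruth)  # 0 .. 70 degrees
#' @export
makeLinearRetinotopy <- function(extentDeg, shape) {
  scalarNumber(extentDeg, "extentDeg")
  if (extentDeg <= 0) stop("extentDeg must be positive")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 5L))
    stop("shape must be at least 5x5 pixels")
  ramp <- seq(0, extentDeg, length.out = shape[2])
  phase <- matrix(ramp, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  zero <- matrix(0, shape[1], shape[2])
  new("GroundTruthScene",
      v1Mask = matrix(TRUE, shape[1], shape[2]),
      phaseTruth = phase, ampContra = zero, ampIpsi = zero,
      extentDeg = extentDeg)
}

#' Ground-truth ocular dominance scene
#'
#' Builds a scene with a centred rectangular responsive zone (the model
#' binocular V1) occupying about `v1Fraction` of the image, uniform
#' contralateral amplitude `contraPeak` inside it, and the ipsilateral
#' amplitude chosen so the pixelwise ODI (C-I)/(C+I) equals
#' `targetMeanOdi` exactly (uniform maps make the mean exact). Both
#' amplitudes are zero outside the zone. Retinotopy is a linear ramp
#' over `extentDeg`.
#'
#' @param targetMeanOdi designed mean ODI in \[-1, 1\]
#' @param contraPeak contralateral response amplitude, fractional
#'   reflectance change (order 1e-4)
#' @param shape integer (rows, cols)
#' @param v1Fraction areal fraction of the responsive zone
#' @param extentDeg degrees per stimulus cycle for the phase ramp
#' @return a [GroundTruthScene-class]
#' @examples
#' sc <- makeOdScene(0.1875, contraPeak = 1.9e-4)
#' mean(odiTruth(sc)[sc@v1Mask])  # 0.1875: ipsi amplitude is 1.3e-4
#' @export
makeOdScene <- function(targetMeanOdi, contraPeak = 2e-4, shape = c(64L, 64L),
                        v1Fraction = 0.25, extentDeg = 70) {
  scalarNumber(targetMeanOdi, "targetMeanOdi")
  if (abs(targetMeanOdi) > 1)
    stop("targetMeanOdi must lie in [-1, 1]")
  scalarNumber(contraPeak, "contraPeak")
  if (contraPeak <= 0) stop("contraPeak must be positive")
  if (v1Fraction <= 0 || v1Fraction > 1)
    stop("v1Fraction must lie in (0, 1]")
  base <- makeLinearRetinotopy(extentDeg, shape)
  shape <- sceneShape(base)
  side <- sqrt(v1Fraction)
  hr <- max(1L, as.integer(round(shape[1] * side)))
  hc <- max(1L, as.integer(round(shape[2] * side)))
  r0 <- (shape[1] - hr) %/% 2L
  c0 <- (shape[2] - hc) %/% 2L
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[r0 + seq_len(hr), c0 + seq_len(hc)] <- TRUE
  ampC <- matrix(0, shape[1], shape[2])
  ampI <- matrix(0, shape[1], shape[2])
  ampC[mask] <- contraPeak
  # invert ODI = (C - I)/(C + I)  =>  I = C (1 - odi)/(1 + odi)
  ampI[mask] <- contraPeak * (1 - targetMeanOdi) / (1 + targetMeanOdi)
  new("GroundTruthScene", v1Mask = mask, phaseTruth = base@phaseTruth,
      ampContra = ampC, ampIpsi = ampI, extentDeg = extentDeg)
}

#' Render a noisy periodic-stimulus reflectance movie
#'
#' Forward model of the signal the Fourier method assumes: each pixel's
#' trace is `A(x) * cos(2*pi*f*t + theta(x))` where A is the chosen
#' eye's amplitude map, f the stimulation frequency, and
#' `theta(x) = 2*pi * position(x) / extentDeg` maps ground-truth
#' visual-field position onto temporal phase over one stimulus cycle.
#' Additive Gaussian noise and an optional slow drift sinusoid come from
#' the [NoiseModel-class]; rendering is deterministic under its seed.
#'
#' @param scene a [GroundTruthScene-class]
#' @param eye "contra" or "ipsi"
#' @param acq an [AcquisitionConfig-class]
#' @param noise a [NoiseModel-class]
#' @param runId run label stored in the stack
#' @return a [FrameStack-class] at the acquisition frame rate with
#'   `nCycles * acquisitionRate / stimFrequency` frames
#' @examples
#' sc <- makeOdScene(0, contraPeak = 2e-4, shape = c(16, 16))
#' acq <- acquisitionConfig(imageSize = c(16L, 16L), nCycles = 1L)
#' st <- renderMovie(sc, "contra", acq, noiseModel(seed = 7))
#' dim(stackData(st))  # 240 frames of 16x16
#' @export
renderMovie <- function(scene, eye = c("contra", "ipsi"),
                        acq = acquisitionConfig(), noise = noiseModel(),
                        runId = "run1") {
  eye <- match.arg(eye)
  shape <- sceneShape(scene)
  if (!identical(as.integer(acq@imageSize), as.integer(shape)))
    acq@imageSize <- as.integer(shape)
  amp <- if (eye == "contra") scene@ampContra else scene@ampIpsi
  f <- acq@stimFrequency
  nFrames <- framesPerRun(acq)
  t <- (seq_len(nFrames) - 1) / acq@acquisitionRate
  theta <- 2 * pi * scene@phaseTruth / scene@extentDeg
  # cos(wt + theta) = cos(wt)cos(theta) - sin(wt)sin(theta)
  wt <- 2 * pi * f * t
  sig <- outer(cos(wt), as.vector(amp * cos(theta))) -
         outer(sin(wt), as.vector(amp * sin(theta)))
  if (noise@driftAmp > 0) {
    if (abs(noise@driftFrequency - f) < 1e-12)
      stop("drift frequency must differ from the stimulation frequency")
    sig <- sig + noise@driftAmp * sin(2 * pi * noise@driftFrequency * t)
  }
  if (noise@gaussianSd > 0) {
    sig <- sig + withSeed(noise@seed,
      matrix(stats::rnorm(length(sig), sd = noise@gaussianSd), nrow = nFrames))
  }
  dim(sig) <- c(nFrames, shape[1], shape[2])
  new("FrameStack", data = sig, frameRate = acq@acquisitionRate,
      stimFrequency = f, eye = eye, runId = runId)
}
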