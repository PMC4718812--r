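#' Temporal binning of a frame stack
#'
#' Averages every `factor` consecutive frames, dividing the frame rate
#' accordingly (e.g. 30 Hz acquisition binned by 4 to 7.5 Hz). A
#' trailing remainder of fewer than `factor` frames is dropped with a
#' warning.
#'
#' @param stack a [FrameStack-class]
#' @param factor integer binning factor, >= 1
#' @return a [FrameStack-class] with `floor(T/factor)` frames at
#'   `frameRate/factor`
#' @examples
#' sc <- makeOdScene(0, shape = c(16, 16))
#' st <- renderMovie(sc, "contra", acquisitionConfig(imageSize = c(16L, 16L),
#'                                                   nCycles = 1L))
#' binned <- binFrames(st, 4L)  # 240 frames at 30 Hz -> 60 at 7.5 Hz
#' @export
binFrames <- function(stack, factor) {
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("factor must be a single integer >= 1")
  d <- dim(stack@data)
  if (factor > d[1]) stop("binning factor exceeds the frame count")
  if (factor == 1L) return(stack)
  nOut <- d[1] %/% factor
  keep <- nOut * factor
  if (keep < d[1])
    warning(sprintf("dropping %d trailing frame(s) not filling a bin",
                    d[1] - keep))
  m <- matrix(stack@data[seq_len(keep), , , drop = FALSE], nrow = keep)
  dim(m) <- c(factor, nOut, d[2] * d[3])
  out <- colMeans(m)                      # mean over each bin
  dim(out) <- c(nOut, d[2], d[3])
  new("FrameStack", data = out, frameRate = stack@frameRate / factor,
      stimFrequency = stack@stimFrequency, eye = stack@eye,
      runId = stack@runId)
}

#' Extract the complex response at the stimulation frequency
#'
#' Per pixel, computes the amplitude-calibrated Fourier coefficient of
#' the time course at the stimulus frequency f:
#' `coef = (2/T) * sum_k x_k * exp(-2*pi*i*f*t_k)` over the `T`
#' retained frames, after (a) truncating to a whole number of stimulus
#' cycles (incomplete trailing cycles are dropped, keeping f exactly on
#' a DFT bin) and (b) subtracting each pixel's temporal mean (intrinsic
#' baselines dominate raw reflectance; for whole cycles this does not
#' touch the stimulus bin). With this calibration a pure sinusoid
#' `A*cos(2*pi*f*t + phi)` yields `Mod(coef) = A` and
#' `Arg(coef) = +phi` — the sign convention used consistently by
#' [renderMovie()] and [toRetinotopy()].
#'
#' @param stack a [FrameStack-class]; its frame rate must be an integer
#'   multiple of the stimulation frequency, with at least 2 samples per
#'   cycle and at least one full cycle
#' @return a [ComplexResponseMap-class]
#' @export
extractComponent <- function(stack) {
  d <- dim(stack@data)
  fs <- stack@frameRate
  f <- stack@stimFrequency
  spc <- fs / f
  if (abs(spc - round(spc)) > 1e-9)
    stop("frame rate must be an integer multiple of the stimulation frequency")
  spc <- as.integer(round(spc))
  if (spc < 2L)
    stop("stimulation frequency not resolvable: fewer than 2 samples per cycle")
  nCyc <- d[1] %/% spc
  if (nCyc < 1L) stop("need at least one full stimulus cycle")
  if (nCyc < 2L)
    warning("fewer than 2 full stimulus cycles retained")
  T <- nCyc * spc
  m <- if (T == d[1]) stack@data else stack@data[seq_len(T), , , drop = FALSE]
  dim(m) <- c(T, d[2] * d[3])
  w <- 2 * pi * f * (0:(T - 1)) / fs
  cw <- cos(w); sw <- sin(w)
  mu <- colMeans(m)                       # per-pixel DC removal, applied
  re <- crossprod(m, cw) - mu * sum(cw)   # to the projections directly
  im <- crossprod(m, sw) - mu * sum(sw)
  coefs <- (2 / T) * complex(real = re, imaginary = -im)
  dim(coefs) <- c(d[2], d[3])
  new("ComplexResponseMap", coef = coefs, stimFrequency = f,
      eye = stack@eye)
}

#' Response magnitude from a complex response map
#'
#' The modulus of the complex coefficient: the intensity of
#' visually-driven activation, in fractional reflectance change. Use
#' [displayMagnitude()] for the conventional x1e4 display scale.
#'
#' @param cmap a [ComplexResponseMap-class]
#' @return a [MagnitudeMap-class]
#' @export
toMagnitude <- function(cmap) {
  new("MagnitudeMap", values = Mod(cmap@coef), eye = cmap@eye)
}

#' Display-scale response magnitudes
#'
#' Activation is conventionally reported as fractional reflectance
#' change x 1e-4, so e.g. a magnitude of 1.9e-4 displays as 1.9.
#'
#' @param map a [MagnitudeMap-class] or numeric values
#' @return numeric values multiplied by 1e4
#' @export
displayMagnitude <- function(map) {
  v <- if (is(map, "MagnitudeMap")) map@values else map
  v * 1e4
}

#' Retinotopy from response phase
#'
#' Maps each pixel's response phase onto a visual-field position:
#' `position = cycleExtent * (Arg(coef) mod 2*pi) / (2*pi)`, placing
#' positions in `[0, cycleExtent)` degrees.
#'
#' @param cmap a [ComplexResponseMap-class]
#' @param cycleExtent degrees of visual field per stimulus cycle
#' @return a [RetinotopyMap-class]
#' @export
toRetinotopy <- function(cmap, cycleExtent = 70) {
  scalarNumber(cycleExtent, "cycleExtent")
  if (cycleExtent <= 0) stop("cycleExtent must be positive")
  ph <- Arg(cmap@coef) %% (2 * pi)
  pos <- (cycleExtent * ph / (2 * pi)) %% cycleExtent
  new("RetinotopyMap", positions = pos, cycleExtent = cycleExtent)
}
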