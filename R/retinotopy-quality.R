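#' Select the most responsive area
#'
#' Applies the 30%-of-peak threshold to a (smoothed) magnitude map and
#' keeps at most `nPixels` of the surviving pixels, largest magnitude
#' first — the area over which map scatter is computed. The canonical
#' full-scale choice is 20,000 pixels at 512x512; use
#' [scaledAreaPixels()] to keep the same areal fraction at other
#' image sizes.
#'
#' @param map a [MagnitudeMap-class] or numeric matrix
#' @param nPixels maximum number of pixels to keep (>= 25)
#' @param frac threshold fraction of peak
#' @return logical matrix mask
#' @export
selectResponsiveArea <- function(map, nPixels, frac = 0.30) {
  v <- if (is(map, "MagnitudeMap")) map@values else as.matrix(map)
  nPixels <- as.integer(nPixels)
  if (nPixels < 25L) stop("nPixels must be at least 25")
  cand <- responsiveMask(v, frac)
  if (sum(cand) < 25L)
    stop("fewer than 25 pixels pass the responsive threshold")
  mask <- matrix(FALSE, nrow(v), ncol(v))
  idx <- which(cand)
  keep <- idx[order(v[idx], decreasing = TRUE)][seq_len(min(nPixels, length(idx)))]
  mask[keep] <- TRUE
  mask
}

#' Area size scaled to a reference areal fraction
#'
#' Number of pixels at `shape` occupying the same areal fraction as
#' `refPixels` at `refShape` (20,000 of 512x512, about 7.6%; 312 at
#' 64x64).
#'
#' @param shape target (rows, cols)
#' @param refPixels,refShape reference count and shape
#' @return integer pixel count
#' @export
scaledAreaPixels <- function(shape, refPixels = 20000L,
                             refShape = c(512L, 512L)) {
  as.integer(round(refPixels * prod(as.numeric(shape)) /
                     prod(as.numeric(refShape))))
}

#' Retinotopic map scatter index
#'
#' For every pixel of the selected area whose full 5x5 neighbourhood
#' (its 24 surrounding pixels) also lies in the area, computes the
#' difference between the pixel's visual-field position and the mean
#' position of those 24 neighbours; the scatter index is the standard
#' deviation of these differences, in degrees. Smooth, high-quality
#' maps have small scatter. Positions within one cycle are treated as
#' linear; pixels whose neighbourhood straddles the cycle wrap (range
#' wider than half the cycle extent) are skipped, as are pixels without
#' 24 in-mask neighbours — skipped counts are reported via `message()`.
#'
#' @param retino a [RetinotopyMap-class]
#' @param mask logical matrix, the selected responsive area
#' @return a [ScatterResult-class]
#' @export
scatterIndex <- function(retino, mask) {
  P <- retino@positions
  if (!identical(dim(P), dim(mask)))
    stop("retinotopy map and mask must share one shape")
  nr <- nrow(P); nc <- ncol(P)
  if (nr < 5L || nc < 5L) stop("map too small for a 5x5 neighbourhood")
  Pm <- P; Pm[!mask] <- 0
  Nm <- matrix(0, nr, nc); Nm[mask] <- 1
  ri <- 3:(nr - 2); ci <- 3:(nc - 2)
  cnt <- matrix(0, length(ri), length(ci))
  psum <- cnt
  pmin_ <- matrix(Inf, length(ri), length(ci))
  pmax_ <- matrix(-Inf, length(ri), length(ci))
  for (di in -2:2) for (dj in -2:2) {
    blk <- Pm[ri + di, ci + dj]
    nbl <- Nm[ri + di, ci + dj]
    cnt <- cnt + nbl
    psum <- psum + blk
    inP <- ifelse(nbl > 0, blk, NA)
    pmin_ <- pmin(pmin_, inP, na.rm = TRUE)
    pmax_ <- pmax(pmax_, inP, na.rm = TRUE)
  }
  center <- P[ri, ci]
  full <- cnt == 25 & mask[ri, ci]
  wrap <- full & (pmax_ - pmin_) > retino@cycleExtent / 2
  nWrap <- sum(wrap)
  nShort <- sum(mask[ri, ci] & cnt < 25) +
    sum(mask) - sum(mask[ri, ci])        # border pixels can never qualify
  eval_ <- full & !wrap
  if (!any(eval_)) stop("no evaluable pixels for the scatter index")
  if (nShort > 0)
    message(nShort, " pixel(s) skipped: fewer than 24 in-mask neighbours")
  if (nWrap > 0)
    message(nWrap, " pixel(s) skipped: neighbourhood straddles the cycle wrap")
  diffsInner <- center - (psum - center) / 24
  diffsInner[!eval_] <- NA_real_
  diffs <- matrix(NA_real_, nr, nc)
  usedMask <- matrix(FALSE, nr, nc)
  diffs[ri, ci] <- diffsInner
  usedMask[ri, ci] <- eval_
  vals <- diffsInner[eval_]
  new("ScatterResult", mask = usedMask, diffs = diffs,
      scatter = if (length(vals) > 1) stats::sd(vals) else 0,
      nUsed = as.integer(length(vals)))
}
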