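# Preprocessing: CLAHE illumination correction, Otsu thresholding and the
# denoise/blur step used by cell segmentation.

# Map intensities 0..maxVal onto 1..nBins histogram bins.
.binOf <- function(v, maxVal, nBins) {
  pmin(floor(v / ((maxVal + 1) / nBins)) + 1L, nBins)
}

# Mirror-pad a matrix at the bottom/right so dims become (nr, nc).
.mirrorPad <- function(m, nr, nc) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(nr)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(nc)]
  m[ri, ci, drop = FALSE]
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Equalizes the image histogram per contextual region (tile), clipping each
#' tile histogram at `clipLimit` times the tile pixel count per bin and
#' redistributing the excess uniformly, then bilinearly interpolating the
#' per-tile intensity mappings between tile centers. Border tiles are
#' computed on mirrored padding so every pixel has a full contextual region.
#' The operation is deterministic and preserves shape and bit depth.
#'
#' Defaults are the pipeline's standard settings for stained micrographs: a
#' 10 x 10 px contextual region, clip limit 0.02 and 256 bins. The small
#' kernel evens out the brightness of individual mitochondria under uneven
#' illumination. Because CLAHE implementations disagree on whether the
#' "kernel" counts pixels or tiles, `tileGrid = TRUE` switches
#' `kernelSize` to mean a grid of `kernelSize[1] x kernelSize[2]` tiles.
#'
#' The clip limit is normalized: with `clipMode = "reference"` (default)
#' the per-bin ceiling is `max(1, clipLimit * tilePixels / nBins)`, the
#' normalization of Zuiderveld's original routine (also OpenCV's); it
#' bounds the local contrast slope by about `clipLimit * 255` plus the
#' one-count floor, which keeps background-only regions from being
#' stretched across the intensity range. `clipMode = "tileFraction"`
#' uses `clipLimit * tilePixels` (scikit-image's convention); it
#' equalizes much more aggressively and is unsuitable for fields that
#' are mostly empty background.
#'
#' @param img a [RawImage-class].
#' @param kernelSize contextual region size in px `(rows, cols)`; with
#'   `tileGrid = TRUE`, the number of tiles per axis instead.
#' @param clipLimit normalized clip limit in (0, 1]; see Details.
#' @param nBins number of histogram bins (>= 2).
#' @param tileGrid interpret `kernelSize` as a tile-grid size.
#' @param clipMode `"reference"` or `"tileFraction"`; see Details.
#' @return A [RawImage-class] of identical shape and bit depth.
#' @examples
#' img <- rawImage(matrix(rep(0:15, each = 16), 16, 16))
#' eq <- claheCorrect(img, kernelSize = c(8, 8))
#' @export
claheCorrect <- function(img, kernelSize = c(10, 10), clipLimit = 0.02,
                         nBins = 256L, tileGrid = FALSE,
                         clipMode = c("reference", "tileFraction")) {
  clipMode <- match.arg(clipMode)
  stopifnot(is(img, "RawImage"))
  v <- img@pixels
  H <- nrow(v); W <- ncol(v)
  if (length(kernelSize) == 1L) kernelSize <- rep(kernelSize, 2L)
  if (clipLimit <= 0 || clipLimit > 1)
    stop("clipLimit must lie in (0, 1]")
  if (nBins < 2L) stop("nBins must be at least 2")
  if (tileGrid) {
    ntr <- as.integer(kernelSize[1]); ntc <- as.integer(kernelSize[2])
    th <- ceiling(H / ntr); tw <- ceiling(W / ntc)
  } else {
    th <- as.integer(kernelSize[1]); tw <- as.integer(kernelSize[2])
    if (th < 2L || tw < 2L) stop("kernelSize components must be >= 2")
    if (th > H || tw > W)
      stop("CLAHE kernel larger than the image (",
           th, "x", tw, " vs ", H, "x", W, ")")
    ntr <- ceiling(H / th); ntc <- ceiling(W / tw)
  }
  maxVal <- 2^img@bitDepth - 1
  pad <- .mirrorPad(v, ntr * th, ntc * tw)
  nT <- ntr * ntc
  tilePix <- th * tw
  tr <- (row(pad) - 1L) %/% th
  tc <- (col(pad) - 1L) %/% tw
  tid <- tc * ntr + tr + 1L
  bins <- .binOf(pad, maxVal, nBins)
  hist <- matrix(tabulate(bins + (tid - 1L) * nBins, nbins = nT * nBins),
                 nrow = nBins)
  # clip and redistribute the excess uniformly (single pass)
  clipCount <- if (clipMode == "reference")
    max(1, clipLimit * tilePix / nBins)
  else
    max(1, clipLimit * tilePix)
  excess <- colSums(pmax(hist - clipCount, 0))
  hist <- pmin(hist, clipCount)
  hist <- sweep(hist, 2L, excess / nBins, "+")
  cdf <- apply(hist, 2L, cumsum)
  mapping <- round(cdf / tilePix * maxVal)  # nBins x nTiles
  # bilinear interpolation between tile-center mappings
  pr <- row(v); pc <- col(v)
  ty <- (pr - 0.5) / th + 0.5
  tx <- (pc - 0.5) / tw + 0.5
  i0 <- floor(ty); wy <- ty - i0
  j0 <- floor(tx); wx <- tx - j0
  i0c <- pmin(pmax(i0, 1L), ntr); i1c <- pmin(pmax(i0 + 1L, 1L), ntr)
  j0c <- pmin(pmax(j0, 1L), ntc); j1c <- pmin(pmax(j0 + 1L, 1L), ntc)
  b <- .binOf(v, maxVal, nBins)
  gather <- function(ti, tj) {
    mapping[cbind(as.vector(b), as.vector((tj - 1L) * ntr + ti))]
  }
  out <- (1 - wy) * (1 - wx) * gather(i0c, j0c) +
         (1 - wy) * wx       * gather(i0c, j1c) +
         wy       * (1 - wx) * gather(i1c, j0c) +
         wy       * wx       * gather(i1c, j1c)
  out <- matrix(out, H, W)
  rawImage(.quantize(out, img@bitDepth), bitDepth = img@bitDepth,
           channel = img@channel, pixelSize = img@pixelSize,
           sourceId = img@sourceId)
}

# Global Otsu threshold from a histogram of counts over levels 0..L-1.
# Returns the level t* maximizing between-class variance of the split
# {v <= t} / {v > t}; ties broken toward the smallest threshold.
.otsuFromCounts <- function(counts) {
  counts <- as.numeric(counts)   # avoid integer overflow in the moments
  L <- length(counts)
  n <- sum(counts)
  levels <- seq_len(L) - 1
  w0 <- cumsum(counts)
  mu <- cumsum(counts * levels)
  muT <- mu[L]
  w1 <- n - w0
  sigma <- rep(-Inf, L)
  ok <- w0 > 0 & w1 > 0
  sigma[ok] <- (muT * w0[ok] - n * mu[ok])^2 / (w0[ok] * w1[ok])
  if (!any(ok)) return(NA_integer_)
  as.integer(which.max(sigma) - 1L)  # first max = smallest threshold
}

#' Otsu thresholding of a (CLAHE-normalized) image
#'
#' Global mode computes the single threshold maximizing between-class
#' variance over the full-resolution intensity histogram; foreground is
#' every pixel strictly above the threshold. Adaptive mode computes a
#' per-tile Otsu threshold over windows of `window` px (default four times
#' the standard 10-px CLAHE kernel) and bilinearly interpolates the
#' thresholds between tile centers into a per-pixel threshold surface;
#' tiles with no 2-class split fall back to the global threshold. In both
#' modes ties in the Otsu objective break toward the smallest threshold.
#' After CLAHE normalization the global variant is well posed and is the
#' default.
#'
#' With `maxForeground < 1`, the threshold is re-estimated recursively on
#' the upper class while the foreground fraction exceeds the bound.
#' Otsu's objective splits the background of a very sparsely stained
#' field (the foreground class is too light to matter); since
#' mitochondria never cover more than a modest fraction of a field, a
#' bound of about 0.25 restores a meaningful threshold there while
#' leaving ordinary fields untouched. The default (1) disables the
#' recursion, giving the plain single-pass estimator.
#'
#' @param img a [RawImage-class] with at least two distinct intensities.
#' @param mode `"global"` or `"adaptive"`.
#' @param window adaptive window edge length in px.
#' @param maxForeground largest acceptable foreground fraction before the
#'   threshold is re-estimated on the upper class (global mode only).
#' @return A [BinaryMask-class]; the chosen global threshold (or `NA` in
#'   adaptive mode) is attached as attribute `"threshold"` of the mask
#'   pixels' source: use `otsuLevel()` to recover it.
#' @examples
#' img <- rawImage(matrix(c(rep(10L, 100), rep(200L, 100)), 20, 10))
#' mask <- otsuThreshold(img)
#' sum(pixels(mask))  # 100
#' @export
otsuThreshold <- function(img, mode = c("global", "adaptive"),
                          window = NULL, maxForeground = 1) {
  stopifnot(is(img, "RawImage"))
  mode <- match.arg(mode)
  v <- img@pixels
  if (min(v) == max(v))
    stop("degenerate input: constant image has no 2-class Otsu split")
  maxVal <- 2^img@bitDepth - 1
  counts <- tabulate(as.vector(v) + 1L, nbins = maxVal + 1L)
  tGlobal <- .otsuFromCounts(counts)
  if (mode == "global") {
    while (maxForeground < 1 && mean(v > tGlobal) > maxForeground) {
      upper <- v[v > tGlobal]
      t2 <- .otsuFromCounts(tabulate(as.vector(upper) + 1L,
                                     nbins = maxVal + 1L))
      if (is.na(t2) || t2 <= tGlobal) break
      tGlobal <- t2
    }
    mask <- binaryMask(v > tGlobal, sourceId = img@sourceId)
    attr(mask, "threshold") <- tGlobal
    return(mask)
  }
  if (is.null(window)) window <- 40L
  H <- nrow(v); W <- ncol(v)
  th <- min(as.integer(window), H); tw <- min(as.integer(window), W)
  ntr <- ceiling(H / th); ntc <- ceiling(W / tw)
  pad <- .mirrorPad(v, ntr * th, ntc * tw)
  tr <- (row(pad) - 1L) %/% th
  tc <- (col(pad) - 1L) %/% tw
  tid <- tc * ntr + tr + 1L
  tThr <- vapply(seq_len(ntr * ntc), function(t) {
    cnt <- tabulate(pad[tid == t] + 1L, nbins = maxVal + 1L)
    tt <- .otsuFromCounts(cnt)
    if (is.na(tt)) tGlobal else tt
  }, 0L)
  thrM <- matrix(as.numeric(tThr), ntr, ntc)
  pr <- row(v); pc <- col(v)
  ty <- (pr - 0.5) / th + 0.5
  tx <- (pc - 0.5) / tw + 0.5
  i0 <- floor(ty); wy <- ty - i0
  j0 <- floor(tx); wx <- tx - j0
  i0c <- pmin(pmax(i0, 1L), ntr); i1c <- pmin(pmax(i0 + 1L, 1L), ntr)
  j0c <- pmin(pmax(j0, 1L), ntc); j1c <- pmin(pmax(j0 + 1L, 1L), ntc)
  surf <- (1 - wy) * (1 - wx) * thrM[cbind(as.vector(i0c), as.vector(j0c))] +
          (1 - wy) * wx       * thrM[cbind(as.vector(i0c), as.vector(j1c))] +
          wy       * (1 - wx) * thrM[cbind(as.vector(i1c), as.vector(j0c))] +
          wy       * wx       * thrM[cbind(as.vector(i1c), as.vector(j1c))]
  mask <- binaryMask(v > matrix(surf, H, W), sourceId = img@sourceId)
  attr(mask, "threshold") <- NA_integer_
  mask
}

#' Otsu threshold level of a mask
#' @param mask a [BinaryMask-class] produced by [otsuThreshold()].
#' @return The global threshold level, or `NA` for adaptive masks.
#' @export
otsuLevel <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  attr(mask, "threshold")
}

#' Close sub-resolution gaps in a binary mask
#'
#' Morphological closing (dilation then erosion) with a disk of radius
#' `radius`, healing 1-2 px gaps that shot noise cuts into thin
#' thresholded tubules. A closing cannot merge objects farther apart
#' than `2 * radius` px.
#'
#' @param mask a [BinaryMask-class].
#' @param radius closing disk radius in px (0 = no-op).
#' @return A [BinaryMask-class].
#' @export
closeGaps <- function(mask, radius = 1) {
  stopifnot(is(mask, "BinaryMask"))
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L,
                              shape = "disc")
  px <- EBImage::closing(mask@pixels * 1, brush)
  binaryMask(matrix(px > 0, nrow(mask@pixels), ncol(mask@pixels)),
             sourceId = mask@sourceId)
}

#' Remove sub-resolution specks from a binary mask
#'
#' Drops 8-connected foreground components smaller than `minArea` px.
#' At diffraction-limited optics the smallest real object (a punctate
#' blob) thresholds to a footprint of a few dozen pixels, so components
#' of a few pixels are shot-noise specks, not organelles.
#'
#' @param mask a [BinaryMask-class].
#' @param minArea minimum component area in px to keep.
#' @return A [BinaryMask-class].
#' @export
removeSpecks <- function(mask, minArea = 5) {
  stopifnot(is(mask, "BinaryMask"))
  if (minArea <= 1) return(mask)
  lab <- .label8(mask@pixels)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop <- which(areas < minArea)
  if (length(drop)) {
    px <- mask@pixels
    px[lab %in% drop] <- FALSE
    mask <- binaryMask(px, sourceId = mask@sourceId)
  }
  mask
}

# Grayscale morphology with a disk structuring element, as running
# min/max over the disk offsets. Border cells take the extremum of the
# available neighbors only.
.diskOffsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}

.grayErode <- function(m, offsets) {
  out <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets)))
    out <- pmin(out, .shift(m, offsets$dr[i], offsets$dc[i], fill = Inf))
  out
}

.grayDilate <- function(m, offsets) {
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(offsets)))
    out <- pmax(out, .shift(m, offsets$dr[i], offsets$dc[i], fill = -Inf))
  out
}

#' Denoise and blur an intensity image
#'
#' Grayscale morphological opening with a disk of radius `minFeature`
#' suppresses features smaller than the disk; a subsequent Gaussian blur
#' with standard deviation `sigma` smooths pixel intensities. Used to
#' prepare the stain image for cell detection. With `minFeature = 0` and
#' `sigma = 0` the input is returned unchanged.
#'
#' @param img a [RawImage-class].
#' @param minFeature opening disk radius in px (>= 0).
#' @param sigma Gaussian standard deviation in px (>= 0).
#' @return A [RawImage-class] of identical shape and bit depth.
#' @export
denoiseAndBlur <- function(img, minFeature = 2, sigma = 2) {
  stopifnot(is(img, "RawImage"), minFeature >= 0, sigma >= 0)
  if (minFeature == 0 && sigma == 0) return(img)
  m <- img@pixels * 1.0
  if (minFeature > 0) {
    off <- .diskOffsets(minFeature)
    m <- .grayDilate(.grayErode(m, off), off)   # grayscale opening
  }
  if (sigma > 0)
    m <- EBImage::gblur(m, sigma = sigma, boundary = "replicate")
  rawImage(.quantize(m, img@bitDepth), bitDepth = img@bitDepth,
           channel = img@channel, pixelSize = img@pixelSize,
           sourceId = img@sourceId)
}
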