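# Cell segmentation from the stain channel alone (no nuclear or phase
# image needed), skeleton-to-cell assignment, and nucleus counting for
# colony-mode normalization.

# Relabel a label matrix to contiguous 1..K ordered by first row-major pixel.
.relabel <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(list(labels = lab * 0L, areas = integer(0), K = 0L))
  nr <- nrow(lab)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ord <- order(r, cc)
  old <- lab[idx]
  map <- integer(max(old))
  nxt <- 0L
  for (i in ord) {
    o <- old[i]
    if (map[o] == 0L) { nxt <- nxt + 1L; map[o] <- nxt }
  }
  out <- matrix(0L, nr, ncol(lab))
  out[idx] <- map[old]
  list(labels = out, areas = as.integer(tabulate(map[old], nbins = nxt)),
       K = nxt)
}

#' Detect individual cells on the stain image
#'
#' A self-contained equivalent of the classic primary-object detection
#' used in cell-image analysis: the stain image is denoised (grayscale
#' opening) and blurred, thresholded globally by Otsu, holes are filled,
#' and touching cells are declumped by a distance-transform watershed.
#' Objects whose equivalent diameter (diameter of the circle with the same
#' area) falls outside `[minDiameter, maxDiameter]`, or that touch the
#' image border when `excludeBorder = TRUE`, are discarded. Deterministic
#' for fixed inputs.
#'
#' The default diameter window (40-400 px) suits spread fibroblast-like
#' cells imaged at 40x; both bounds are configuration, not measurements.
#'
#' @param img the grayscale mito-stain [RawImage-class] (not a skeleton).
#' @param minDiameter,maxDiameter accepted equivalent-diameter range, px.
#' @param minFeature opening radius for [denoiseAndBlur()], px.
#' @param sigma Gaussian blur sigma for [denoiseAndBlur()], px.
#' @param excludeBorder discard objects touching the image border.
#' @param minContrast minimum brightness difference (intensity units,
#'   after smoothing) between the thresholded objects and the surround;
#'   below it the field is treated as blank.
#' @return A [SegmentationLabels-class]; `K = 0` (with a warning) when no
#'   object survives the size filter.
#' @export
identifyPrimaryObjects <- function(img, minDiameter = 40, maxDiameter = 400,
                                   minFeature = 2, sigma = 6,
                                   excludeBorder = FALSE, minContrast = 8) {
  stopifnot(is(img, "RawImage"),
            minDiameter > 0, maxDiameter > minDiameter)
  sm <- denoiseAndBlur(img, minFeature = minFeature, sigma = sigma)
  v <- pixels(sm)
  empty <- function(msg) {
    warning(msg)
    new("SegmentationLabels",
        labels = matrix(0L, nrow(v), ncol(v)), areas = integer(0), K = 0L)
  }
  if (min(v) == max(v)) return(empty("blank field: no objects detected"))
  mask <- pixels(otsuThreshold(sm, mode = "global", maxForeground = 0.5))
  # a blank noisy field splits into classes of nearly equal brightness;
  # real cells sit well above the surround after smoothing
  if (mean(v[mask]) - mean(v[!mask]) < minContrast)
    return(empty("blank field: no objects detected"))
  mask <- EBImage::fillHull(mask * 1) > 0
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm, tolerance = max(1, minDiameter / 4), ext = 1)
  ws <- matrix(as.integer(ws), nrow(v), ncol(v))
  if (max(ws) == 0L) return(empty("no objects detected"))
  areas <- tabulate(ws[ws > 0], nbins = max(ws))
  eqd <- 2 * sqrt(areas / pi)
  keep <- eqd >= minDiameter & eqd <= maxDiameter
  if (excludeBorder) {
    border <- unique(c(ws[1, ], ws[nrow(ws), ], ws[, 1], ws[, ncol(ws)]))
    keep[border[border > 0]] <- FALSE
  }
  ws[!ws %in% which(keep)] <- 0L
  rl <- .relabel(ws)
  if (rl$K == 0L) return(empty("no objects survive the size filter"))
  new("SegmentationLabels", labels = rl$labels, areas = rl$areas, K = rl$K)
}

#' Split a field skeleton into per-cell skeletons
#'
#' Every skeleton pixel takes the segmentation label under it; pixels on
#' background are attached to the nearest positive label within `maxGap`
#' px (Euclidean, ties to the smaller label), and dropped otherwise. The
#' per-cell pixel counts plus the dropped count always equal the input
#' skeleton pixel count.
#'
#' @param skel field [SkeletonImage-class].
#' @param seg [SegmentationLabels-class] of the same shape.
#' @param maxGap maximum attachment distance in px.
#' @return list with `skeletons` (one full-size [SkeletonImage-class] per
#'   cell) and `dropped` (pixel count discarded by the straddle rule).
#' @export
assignSkeletonToCells <- function(skel, seg, maxGap = 5L) {
  stopifnot(is(skel, "SkeletonImage"), is(seg, "SegmentationLabels"))
  if (!identical(dim(skel@pixels), dim(seg@labels)))
    stop("skeleton and segmentation shapes differ")
  K <- seg@K
  if (K == 0L)
    return(list(skeletons = list(), dropped = sum(skel@pixels)))
  nr <- nrow(skel@pixels)
  idx <- which(skel@pixels)
  lab <- seg@labels[idx]
  orphan <- which(lab == 0L)
  g <- as.integer(ceiling(maxGap))
  for (o in orphan) {
    i <- idx[o]
    r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
    rs <- max(1L, r - g):min(nr, r + g)
    cs <- max(1L, cc - g):min(ncol(skel@pixels), cc + g)
    win <- seg@labels[rs, cs, drop = FALSE]
    pos <- which(win > 0)
    if (!length(pos)) next
    wr <- ((pos - 1L) %% length(rs)) + 1L
    wc <- ((pos - 1L) %/% length(rs)) + 1L
    d2 <- (rs[wr] - r)^2 + (cs[wc] - cc)^2
    ok <- d2 <= maxGap^2
    if (!any(ok)) next
    cand <- win[pos[ok]]
    best <- order(d2[ok], cand)[1L]
    lab[o] <- cand[best]
  }
  skeletons <- vector("list", K)
  for (k in seq_len(K)) {
    m <- matrix(FALSE, nr, ncol(skel@pixels))
    m[idx[lab == k]] <- TRUE
    skeletons[[k]] <- skeletonImage(m, sourceMaskId =
                                      sprintf("%s_cell%d", skel@sourceMaskId, k))
  }
  list(skeletons = skeletons, dropped = sum(lab == 0L))
}

#' Count nuclei in a nuclear-stain image
#'
#' Gaussian blur, global Otsu threshold, hole filling, distance-transform
#' watershed to split touching nuclei, and a count of resulting objects
#' with at least `minNucleusArea` px. Blank images count 0.
#'
#' @param nucImg the nuclear-stain [RawImage-class].
#' @param minNucleusArea minimum object area in px^2.
#' @param sigma Gaussian blur sigma in px.
#' @return Integer nucleus count.
#' @export
countNuclei <- function(nucImg, minNucleusArea = 50, sigma = 3) {
  stopifnot(is(nucImg, "RawImage"))
  v <- pixels(nucImg)
  if (min(v) == max(v)) return(0L)
  sm <- denoiseAndBlur(nucImg, minFeature = 0, sigma = sigma)
  if (min(pixels(sm)) == max(pixels(sm))) return(0L)
  mask <- pixels(otsuThreshold(sm, mode = "global", maxForeground = 0.5))
  mask <- EBImage::fillHull(mask * 1) > 0
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  ws <- matrix(as.integer(ws), nrow(v), ncol(v))
  if (max(ws) == 0L) return(0L)
  areas <- tabulate(ws[ws > 0], nbins = max(ws))
  sum(areas >= minNucleusArea)
}
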