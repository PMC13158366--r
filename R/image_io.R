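# Raster and table I/O. All file-format handling lives here; the rest of
# the pipeline only sees RawImage / SkeletonImage / MorphologyMetrics.

#' Read a raster image into a RawImage
#'
#' Reads a TIFF (baseline, uncompressed or LZW) or PNG raster on its native
#' integer scale; intensities are never rescaled. Multi-channel images are
#' reduced to one plane: with `channelPolicy = "auto"` the plane with the
#' highest mean intensity is taken (for a red mitochondrial stain exported
#' as RGB this is the red plane), with `channelPolicy = "index"` the plane
#' `channelIndex` is taken.
#'
#' @param path file path to a `.tif`/`.tiff` or `.png` image.
#' @param channelPolicy `"auto"` or `"index"`.
#' @param channelIndex plane number when `channelPolicy = "index"`.
#' @param channel channel tag stored on the result (`"mito"`, `"nuclei"`,
#'   `"phase"`).
#' @param pixelSize optional physical pixel size (micrometres per pixel).
#' @return A [RawImage-class] with `bitDepth` inferred from the file.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeRawImage(rawImage(matrix(0:255, 16, 16)), f)
#' img <- readRawImage(f)
#' @export
readRawImage <- function(path, channelPolicy = c("auto", "index"),
                         channelIndex = 1L, channel = "mito",
                         pixelSize = NA_real_) {
  channelPolicy <- match.arg(channelPolicy)
  if (!file.exists(path))
    stop("cannot read image file (no such file): ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e)
                    stop("cannot read image file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
    bits <- attr(x, "bits.per.sample")
    bd <- if (is.null(bits)) NULL else as.integer(bits)
    # multi-sample TIFFs come back normalized to [0,1] even with as.is
    if (is.double(x) && !is.null(bd) && max(x) <= 1 && min(x) >= 0)
      x <- round(x * (2^bd - 1))
  } else if (ext == "png") {
    x <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop("cannot read image file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
    # readPNG returns [0,1]; recover the integer scale from the sample depth
    v255 <- x * 255
    if (max(abs(v255 - round(v255))) < 1e-9) {
      x <- round(v255); bd <- 8L
    } else {
      x <- round(x * 65535); bd <- 16L
    }
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  if (length(dim(x)) > 3L)
    stop("image has more than 3 dimensions after channel resolution: ", path)
  if (length(dim(x)) == 3L) {
    nch <- dim(x)[3]
    if (channelPolicy == "index") {
      if (channelIndex < 1L || channelIndex > nch)
        stop("channelIndex ", channelIndex, " out of range for ", path)
      x <- x[, , channelIndex]
    } else {
      use <- min(nch, 3L)  # ignore an alpha plane
      means <- vapply(seq_len(use), function(k) mean(x[, , k]), 0)
      x <- x[, , which.max(means)]
    }
  }
  if (is.null(bd)) bd <- if (max(x) > 255) 16L else 8L
  rawImage(x, bitDepth = bd, channel = channel, pixelSize = pixelSize,
           sourceId = basename(path))
}

#' Write a RawImage to disk
#'
#' Writes a single-plane TIFF or PNG on the image's native integer scale;
#' reading the file back with [readRawImage()] is pixel-identical.
#'
#' @param img a [RawImage-class].
#' @param path destination `.tif`/`.tiff` or `.png` path.
#' @return Invisibly, `path`.
#' @export
writeRawImage <- function(img, path) {
  stopifnot(is(img, "RawImage"))
  if (!dir.exists(dirname(path)))
    stop("cannot write image, directory does not exist: ", dirname(path))
  mx <- 2^img@bitDepth - 1
  m <- img@pixels / mx
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = img@bitDepth)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  invisible(path)
}

#' Write a skeleton as a binary 8-bit TIFF
#'
#' Foreground (skeleton) pixels are written as 255, background as 0.
#'
#' @param skel a [SkeletonImage-class].
#' @param path destination `.tif` path.
#' @return Invisibly, `path`.
#' @export
writeSkeletonImage <- function(skel, path) {
  stopifnot(is(skel, "SkeletonImage"))
  if (!dir.exists(dirname(path)))
    stop("cannot write skeleton, directory does not exist: ", dirname(path))
  tiff::writeTIFF((skel@pixels * 1) , path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary skeleton TIFF back into a SkeletonImage
#'
#' @param path a `.tif` written by [writeSkeletonImage()] (any nonzero
#'   pixel is foreground).
#' @return A [SkeletonImage-class].
#' @export
readSkeletonImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read skeleton file (no such file): ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  skeletonImage(x > 0, sourceMaskId = basename(path))
}

#' Write a morphology metrics table as CSV
#'
#' One row per analysis unit: `unit_id` first, then the 18 morphology
#' parameters in fixed table order, then the normalizer columns. Undefined
#' (NA) parameters are written as empty cells, never as 0.
#'
#' @param records list of [MorphologyMetrics-class] (or a single record).
#' @param path destination `.csv` path.
#' @return Invisibly, `path`.
#' @seealso [readMetricsTable()]
#' @export
writeMetricsTable <- function(records, path) {
  df <- metricsToDataFrame(records)
  if (nrow(df) == 0L)
    warning("writing a header-only metrics table (no records)")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a morphology metrics table written by writeMetricsTable
#'
#' @param path the `.csv` path.
#' @return data.frame with empty cells restored as NA.
#' @export
readMetricsTable <- function(path) {
  read.csv(path, check.names = FALSE,
           na.strings = "", stringsAsFactors = FALSE)
}
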