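# The 18 morphology parameters per analysis unit, their normalization, and
# the batch driver.

#' Compute the 18 morphology parameters from a skeleton graph
#'
#' Definitions (counts refer to connected skeleton components by class;
#' lengths are geodesic skeleton lengths):
#' \itemize{
#'   \item `skeleton_area`: total skeleton pixel count (times `pixelSize^2`
#'     when a physical pixel size is known).
#'   \item class counts and `*_pct`: share of component count per class,
#'     in percent (a length-weighted variant is available via
#'     `percentBasis = "length"`).
#'   \item `punctate_length`, `rod_length`, `network_length`: summed
#'     lengths per class (network length sums branch lengths).
#'   \item `mean_rod_length` = `rod_length / rod_count`.
#'   \item `total_network_branch_count`: branches summed over networks;
#'     `mean_network_branch_count` divides by `network_count`;
#'     `mean_network_branch_length` = `network_length /
#'     total_network_branch_count`; `mean_network_length` =
#'     `network_length / network_count`.
#'   \item `all_branch_count` = `punctate_count + rod_count +
#'     total_network_branch_count`; `mean_length_all_branches` divides the
#'     combined length of all classes by it.
#'   \item `mean_network_and_rod_length` = `(network_length + rod_length) /
#'     (network_count + rod_count)`.
#' }
#' Any mean with a zero denominator is `NA` (missing), never 0.
#'
#' @param graph a [SkeletonGraph-class].
#' @param unitId identifier stored on the record.
#' @param pixelSize physical pixel size in micrometres per pixel; when
#'   given, lengths are reported in micrometres and the skeleton area in
#'   square micrometres, otherwise in pixels.
#' @param percentBasis `"count"` (default) or `"length"`: denominator
#'   convention for the class percentages.
#' @return A [MorphologyMetrics-class].
#' @examples
#' m <- matrix(FALSE, 6, 12); m[3, 3:10] <- TRUE
#' met <- computeMetrics(buildGraph(skeletonImage(m)), unitId = "rod")
#' metricValues(met)[["mean_rod_length"]]  # 7
#' @export
computeMetrics <- function(graph, unitId = "", pixelSize = NA_real_,
                           percentBasis = c("count", "length")) {
  stopifnot(is(graph, "SkeletonGraph"))
  percentBasis <- match.arg(percentBasis)
  cs <- componentCensus(graph)
  scale <- if (is.na(pixelSize)) 1 else pixelSize
  nTot <- cs$punctateCount + cs$rodCount + cs$networkCount
  pl <- cs$punctateLength * scale
  rl <- cs$rodLength * scale
  nl <- cs$networkLength * scale
  if (percentBasis == "count") {
    den <- nTot
    num <- c(cs$punctateCount, cs$rodCount, cs$networkCount)
  } else {
    den <- pl + rl + nl
    num <- c(pl, rl, nl)
  }
  pct <- if (den > 0) num / den * 100 else rep(NA_real_, 3L)
  tnbc <- cs$totalNetworkBranchCount
  abc <- cs$punctateCount + cs$rodCount + tnbc
  v <- c(
    skeleton_area = graph@nPixels * scale^2,
    punctate_count = cs$punctateCount,
    rod_count = cs$rodCount,
    network_count = cs$networkCount,
    punctate_pct = pct[1], rod_pct = pct[2], network_pct = pct[3],
    punctate_length = pl, rod_length = rl, network_length = nl,
    mean_rod_length = if (cs$rodCount > 0) rl / cs$rodCount else NA_real_,
    total_network_branch_count = tnbc,
    mean_network_branch_count =
      if (cs$networkCount > 0) tnbc / cs$networkCount else NA_real_,
    mean_network_branch_length = if (tnbc > 0) nl / tnbc else NA_real_,
    mean_network_length =
      if (cs$networkCount > 0) nl / cs$networkCount else NA_real_,
    all_branch_count = abc,
    mean_length_all_branches =
      if (abc > 0) (pl + rl + nl) / abc else NA_real_,
    mean_network_and_rod_length =
      if (cs$networkCount + cs$rodCount > 0)
        (nl + rl) / (cs$networkCount + cs$rodCount) else NA_real_
  )
  new("MorphologyMetrics", values = v, unitId = as.character(unitId),
      normalizerKind = "none", normalizerValue = NA_real_)
}

#' Normalize extensive morphology parameters
#'
#' Divides the extensive parameters (skeleton area, the three class counts,
#' the three class length totals, total network branch count, all branch
#' count) by a positive normalizer: the cell surface area for segmented
#' single cells, or the nucleus count of the analyzed area for aggregate
#' colony fields. Intensive parameters (percentages and means) are
#' unchanged.
#'
#' @param m a [MorphologyMetrics-class].
#' @param kind `"cell_area"` or `"nuclei_count"`.
#' @param value positive normalizer.
#' @return A [MorphologyMetrics-class] with the normalizer recorded.
#' @export
normalizeMetrics <- function(m, kind = c("cell_area", "nuclei_count"),
                             value) {
  stopifnot(is(m, "MorphologyMetrics"))
  kind <- match.arg(kind)
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value <= 0)
    stop("normalizer value must be a positive number")
  v <- m@values
  ext <- .extensiveParameterNames()
  v[ext] <- v[ext] / value
  new("MorphologyMetrics", values = v, unitId = m@unitId,
      normalizerKind = kind, normalizerValue = as.numeric(value))
}

#' Default pipeline configuration
#'
#' Returns the full set of tunable pipeline parameters with their default
#' values; pass overrides as named arguments. Keys follow the
#' `stage.parameter` convention.
#'
#' @param ... overrides, e.g. `defaultConfig("clahe.clip" = 0.05)`.
#' @return Named list of configuration values.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    clahe.enabled = TRUE,
    clahe.kernel = c(10, 10),
    clahe.clip = 0.02,
    clahe.bins = 256L,
    clahe.tile_grid = FALSE,
    clahe.clip_mode = "reference",
    threshold.mode = "global",
    threshold.window = 40L,
    threshold.min_object = 5,
    threshold.max_foreground = 0.15,
    threshold.close_radius = 1,
    denoise.min_feature = 2,
    denoise.sigma = 2,
    skeleton.prune_spurs = 0L,
    graph.punctate_max = 5,
    graph.spur_length = 3,
    metrics.percent_basis = "count",
    segment.min_diameter = 40,
    segment.max_diameter = 400,
    segment.exclude_border = FALSE,
    segment.max_gap = 5L,
    segment.blur_sigma = 6,
    segment.min_feature = 2,
    nuclei.min_area = 50,
    nuclei.blur_sigma = 3
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Run the aggregate morphology pipeline on one image
#'
#' CLAHE illumination correction, Otsu thresholding, Zhang-Suen thinning
#' and skeleton-graph construction, returning the skeleton, the graph and
#' the (unnormalized) morphology parameters of the whole field.
#'
#' @param img a [RawImage-class] (mitochondrial stain channel).
#' @param config configuration list from [defaultConfig()].
#' @param unitId identifier for the metrics record (defaults to the image
#'   source id).
#' @return list with elements `mask` ([BinaryMask-class]), `skeleton`
#'   ([SkeletonImage-class]), `graph` ([SkeletonGraph-class]) and
#'   `metrics` ([MorphologyMetrics-class]).
#' @examples
#' gen <- generateScene(sceneSpec(nPunctates = 3, nRods = 2,
#'                                nNetworks = 1, rngSeed = 4))
#' res <- analyzeImage(gen$image)
#' metricValues(res$metrics)[["rod_count"]]
#' @export
analyzeImage <- function(img, config = defaultConfig(),
                         unitId = sourceId(img)) {
  stopifnot(is(img, "RawImage"))
  work <- img
  if (isTRUE(config$clahe.enabled))
    work <- claheCorrect(work, kernelSize = config$clahe.kernel,
                         clipLimit = config$clahe.clip,
                         nBins = config$clahe.bins,
                         tileGrid = config$clahe.tile_grid,
                         clipMode = config$clahe.clip_mode)
  mask <- otsuThreshold(work, mode = config$threshold.mode,
                        window = config$threshold.window,
                        maxForeground = config$threshold.max_foreground)
  mask <- closeGaps(mask, radius = config$threshold.close_radius)
  mask <- removeSpecks(mask, minArea = config$threshold.min_object)
  skel <- zhangSuenThin(mask, pruneSpurs = config$skeleton.prune_spurs)
  graph <- buildGraph(skel, punctateMax = config$graph.punctate_max,
                      spurLength = config$graph.spur_length)
  metrics <- computeMetrics(graph, unitId = unitId,
                            pixelSize = pixelSize(img),
                            percentBasis = config$metrics.percent_basis)
  list(mask = mask, skeleton = skel, graph = graph, metrics = metrics)
}

#' Run the segmented (per-cell) morphology pipeline on one image
#'
#' Detects spatially separated cells on the stain image, thins the whole
#' field once, splits the field skeleton into per-cell skeletons by the
#' segmentation labels (skeleton pixels on background are attached to the
#' nearest cell within `segment.max_gap` px, otherwise dropped), and
#' computes one metrics record per cell, normalized by the cell surface
#' area in px^2 (or um^2 when the pixel size is known).
#'
#' @param img a [RawImage-class].
#' @param config configuration list from [defaultConfig()].
#' @param unitId base identifier; cell records get `unitId_cellK`.
#' @return list with `segmentation` ([SegmentationLabels-class]),
#'   `skeleton` (whole-field [SkeletonImage-class]), `cellSkeletons`
#'   (list of per-cell skeletons), `droppedPixels` (straddle-rule drops)
#'   and `metrics` (list of normalized [MorphologyMetrics-class]).
#' @export
analyzeImageSegmented <- function(img, config = defaultConfig(),
                                  unitId = sourceId(img)) {
  stopifnot(is(img, "RawImage"))
  seg <- identifyPrimaryObjects(
    img, minDiameter = config$segment.min_diameter,
    maxDiameter = config$segment.max_diameter,
    minFeature = config$segment.min_feature,
    sigma = config$segment.blur_sigma,
    excludeBorder = config$segment.exclude_border)
  agg <- analyzeImage(img, config = config, unitId = unitId)
  parts <- assignSkeletonToCells(agg$skeleton, seg,
                                 maxGap = config$segment.max_gap)
  px2 <- if (is.na(pixelSize(img))) 1 else pixelSize(img)^2
  mets <- vector("list", nCells(seg))
  for (k in seq_len(nCells(seg))) {
    g <- buildGraph(parts$skeletons[[k]],
                    punctateMax = config$graph.punctate_max,
                    spurLength = config$graph.spur_length)
    m <- computeMetrics(g, unitId = sprintf("%s_cell%d", unitId, k),
                        pixelSize = pixelSize(img),
                        percentBasis = config$metrics.percent_basis)
    mets[[k]] <- normalizeMetrics(m, "cell_area", cellAreas(seg)[k] * px2)
  }
  list(segmentation = seg, skeleton = agg$skeleton,
       cellSkeletons = parts$skeletons, droppedPixels = parts$dropped,
       metrics = mets)
}

#' Batch morphology analysis over a directory of images
#'
#' Runs the pipeline over every TIFF/PNG in `root`. In `"segmented"` mode
#' each detected cell yields one record normalized by its surface area; in
#' `"aggregate"` mode each field yields one record, normalized by the
#' nucleus count when a matching nuclear-stain image is present (a file of
#' the same name with suffix `nucleiSuffix` before the extension),
#' otherwise left unnormalized. Unreadable files are skipped with a
#' warning.
#'
#' @param root directory of images.
#' @param mode `"aggregate"` or `"segmented"` (fixed per batch).
#' @param config configuration list from [defaultConfig()].
#' @param nucleiSuffix suffix identifying nuclear-channel companions
#'   (those files are not analyzed as fields themselves).
#' @return list of [MorphologyMetrics-class] records with stable unit ids
#'   (file name, plus cell index in segmented mode).
#' @export
analyzeBatch <- function(root, mode = c("aggregate", "segmented"),
                         config = defaultConfig(),
                         nucleiSuffix = "_nuclei") {
  mode <- match.arg(mode)
  if (!dir.exists(root)) stop("root directory does not exist: ", root)
  files <- sort(list.files(root, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE, full.names = TRUE))
  isNuc <- grepl(paste0(nucleiSuffix, "\\.(tif|tiff|png)$"), files,
                 ignore.case = TRUE)
  nucFiles <- files[isNuc]
  files <- files[!isNuc]
  if (!length(files)) {
    warning("no images found under ", root)
    return(list())
  }
  records <- list()
  for (f in files) {
    img <- tryCatch(readRawImage(f), error = function(e) {
      warning("skipping unreadable file ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    if (mode == "segmented") {
      res <- analyzeImageSegmented(img, config = config)
      records <- c(records, res$metrics)
    } else {
      res <- analyzeImage(img, config = config)
      m <- res$metrics
      nucPath <- file.path(dirname(f), paste0(
        tools::file_path_sans_ext(basename(f)), nucleiSuffix, ".",
        tools::file_ext(f)))
      if (nucPath %in% nucFiles) {
        nuc <- readRawImage(nucPath, channel = "nuclei")
        cnt <- countNuclei(nuc, minNucleusArea = config$nuclei.min_area,
                           sigma = config$nuclei.blur_sigma)
        if (cnt > 0) m <- normalizeMetrics(m, "nuclei_count", cnt)
      }
      records <- c(records, list(m))
    }
  }
  records
}
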