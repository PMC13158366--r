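#' @import methods
#' @importFrom stats rnorm rpois runif setNames aov anova t.test TukeyHSD sd
#' @importFrom utils write.csv read.csv
NULL

# Central S4 containers. Pixel grids are stored as R matrices in (row, col)
# order; the user-facing coordinate convention is 0-based with pixel centers
# at integer coordinates, matching the rest of the pipeline's documentation.

#' RawImage: a single-channel intensity grid
#'
#' Holds one plane of a fluorescence micrograph as integers on the native
#' camera scale. Intensities are never rescaled at read time; all contrast
#' handling is done explicitly by [claheCorrect()].
#'
#' @slot pixels integer matrix of intensities, `(row, col)` layout.
#' @slot bitDepth 8 or 16; intensities lie in `[0, 2^bitDepth - 1]`.
#' @slot channel one of `"mito"`, `"nuclei"`, `"phase"`.
#' @slot pixelSize physical size of one pixel in micrometres, or `NA` when
#'   unknown (all lengths are then reported in pixels).
#' @slot sourceId file name or synthetic seed tag.
#'
#' @exportClass RawImage
setClass("RawImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    channel = "character",
    pixelSize = "numeric",
    sourceId = "character"
  ),
  prototype(
    bitDepth = 8L, channel = "mito", pixelSize = NA_real_, sourceId = ""
  )
)

setValidity("RawImage", function(object) {
  p <- object@pixels
  msgs <- character(0)
  if (nrow(p) < 2L || ncol(p) < 2L)
    msgs <- c(msgs, "pixel grid must have at least 2 rows and 2 columns")
  if (!object@bitDepth %in% c(8L, 16L))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (any(is.na(p)))
    msgs <- c(msgs, "pixels must not contain NA")
  else {
    mx <- 2^object@bitDepth - 1
    if (min(p) < 0 || max(p) > mx)
      msgs <- c(msgs, sprintf("intensities must lie in [0, %d]", mx))
  }
  if (!is.na(object@pixelSize) && object@pixelSize <= 0)
    msgs <- c(msgs, "pixelSize must be > 0 when given")
  if (!object@channel %in% c("mito", "nuclei", "phase"))
    msgs <- c(msgs, "channel must be one of 'mito', 'nuclei', 'phase'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RawImage
#'
#' @param pixels numeric or integer matrix of non-negative intensities.
#' @param bitDepth 8 or 16.
#' @param channel channel tag, one of `"mito"`, `"nuclei"`, `"phase"`.
#' @param pixelSize optional pixel size in micrometres per pixel.
#' @param sourceId provenance tag (file name or seed label).
#' @return A [RawImage-class] object.
#' @examples
#' img <- rawImage(matrix(0:24, 5, 5))
#' bitDepth(img)
#' @export
rawImage <- function(pixels, bitDepth = NULL, channel = "mito",
                     pixelSize = NA_real_, sourceId = "") {
  stopifnot(is.matrix(pixels))
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  if (is.null(bitDepth))
    bitDepth <- if (max(pixels, 0L, na.rm = TRUE) > 255L) 16L else 8L
  new("RawImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      channel = channel, pixelSize = as.numeric(pixelSize),
      sourceId = as.character(sourceId))
}

#' BinaryMask: a boolean foreground mask
#'
#' Intermediate of the thresholding stage; shape matches its source image.
#'
#' @slot pixels logical matrix.
#' @slot sourceId provenance tag.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", sourceId = "character"),
  prototype(sourceId = "")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (any(is.na(object@pixels))) return("pixels must not contain NA")
  TRUE
})

#' Construct a BinaryMask
#' @param pixels logical (or 0/1) matrix.
#' @param sourceId provenance tag.
#' @return A [BinaryMask-class] object.
#' @export
binaryMask <- function(pixels, sourceId = "") {
  stopifnot(is.matrix(pixels))
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  new("BinaryMask", pixels = m, sourceId = as.character(sourceId))
}

#' SkeletonImage: a one-pixel-wide binary skeleton
#'
#' Output of Zhang-Suen thinning; foreground is a subset of the source mask
#' and contains no fully set 2x2 block.
#'
#' @slot pixels logical matrix.
#' @slot sourceMaskId provenance tag of the mask it was thinned from.
#' @exportClass SkeletonImage
setClass("SkeletonImage",
  representation(pixels = "matrix", sourceMaskId = "character"),
  prototype(sourceMaskId = "")
)

setValidity("SkeletonImage", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (any(is.na(object@pixels))) return("pixels must not contain NA")
  TRUE
})

#' Construct a SkeletonImage
#' @param pixels logical (or 0/1) matrix; should satisfy the 1-pixel-width
#'   contract (no fully set 2x2 block). Violations are caught by
#'   [buildGraph()].
#' @param sourceMaskId provenance tag.
#' @return A [SkeletonImage-class] object.
#' @export
skeletonImage <- function(pixels, sourceMaskId = "") {
  stopifnot(is.matrix(pixels))
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  new("SkeletonImage", pixels = m, sourceMaskId = as.character(sourceMaskId))
}

#' SegmentationLabels: per-cell label image
#'
#' @slot labels integer matrix; 0 = background, 1..K = cells.
#' @slot areas integer vector of per-label pixel counts.
#' @slot K number of cells.
#' @exportClass SegmentationLabels
setClass("SegmentationLabels",
  representation(labels = "matrix", areas = "integer", K = "integer")
)

setValidity("SegmentationLabels", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be an integer matrix")
  K <- object@K
  u <- sort(unique(as.integer(l[l > 0])))
  if (length(u) && !identical(u, seq_len(K)))
    return("labels must be contiguous 1..K")
  if (length(u) == 0L && K != 0L)
    return("K must be 0 for an empty segmentation")
  if (length(object@areas) != K)
    return("areas must have one entry per label")
  if (K > 0L) {
    tab <- tabulate(as.integer(l[l > 0]), nbins = K)
    if (!identical(as.integer(tab), object@areas))
      return("areas must equal per-label pixel counts")
  }
  TRUE
})

#' SkeletonGraph: branches and nodes of a skeleton, per connected component
#'
#' Each component carries its pixel count, junction-cluster and endpoint
#' counts, traced branches with geodesic lengths (1 per axial step, sqrt(2)
#' per diagonal step) and a morphological class: `punctate` (no junctions,
#' at most `punctateMax` pixels), `rod` (no junctions, larger) or `network`
#' (at least one junction cluster; node-free closed loops are networks with
#' a single cycle branch, by convention).
#'
#' @slot components list; one entry per 8-connected component with elements
#'   `pixelCount`, `class`, `junctionCount`, `endpointCount`,
#'   `branchLengths`, `branchPixels`, `totalLength`.
#' @slot punctateMax punctate/rod size boundary in skeleton pixels.
#' @slot nPixels total skeleton foreground count.
#' @slot sourceId provenance tag.
#' @exportClass SkeletonGraph
setClass("SkeletonGraph",
  representation(
    components = "list",
    punctateMax = "numeric",
    nPixels = "integer",
    sourceId = "character"
  ),
  prototype(punctateMax = 3, nPixels = 0L, sourceId = "")
)

setValidity("SkeletonGraph", function(object) {
  if (length(object@components)) {
    tot <- sum(vapply(object@components, function(co) co$pixelCount, 0))
    if (tot != object@nPixels)
      return("component pixel counts must sum to nPixels")
    cls <- vapply(object@components, function(co) co$class, "")
    if (!all(cls %in% c("punctate", "rod", "network")))
      return("component class must be punctate, rod or network")
  }
  TRUE
})

#' MorphologyMetrics: the 18-parameter morphology record for one unit
#'
#' One record per analysis unit (a segmented cell, or a whole field in
#' aggregate mode). Mean-type parameters with a zero denominator are stored
#' as `NA` (missing), never 0. See [morphologyParameterNames()] for the
#' fixed column order used in tables.
#'
#' @slot values named numeric vector of the 18 parameters.
#' @slot unitId stable identifier (file name plus cell index).
#' @slot normalizerKind `"none"`, `"cell_area"` or `"nuclei_count"`.
#' @slot normalizerValue the divisor applied to extensive parameters
#'   (`NA` when `normalizerKind == "none"`).
#' @exportClass MorphologyMetrics
setClass("MorphologyMetrics",
  representation(
    values = "numeric",
    unitId = "character",
    normalizerKind = "character",
    normalizerValue = "numeric"
  ),
  prototype(normalizerKind = "none", normalizerValue = NA_real_)
)

#' Names of the 18 morphology parameters, in table order
#'
#' @return Character vector of parameter names (snake_case), in the fixed
#'   order used by [writeMetricsTable()].
#' @export
morphologyParameterNames <- function() {
  c("skeleton_area",
    "punctate_count", "rod_count", "network_count",
    "punctate_pct", "rod_pct", "network_pct",
    "punctate_length", "rod_length", "network_length",
    "mean_rod_length",
    "total_network_branch_count", "mean_network_branch_count",
    "mean_network_branch_length", "mean_network_length",
    "all_branch_count", "mean_length_all_branches",
    "mean_network_and_rod_length")
}

.extensiveParameterNames <- function() {
  c("skeleton_area", "punctate_count", "rod_count", "network_count",
    "punctate_length", "rod_length", "network_length",
    "total_network_branch_count", "all_branch_count")
}

setValidity("MorphologyMetrics", function(object) {
  want <- morphologyParameterNames()
  if (!identical(names(object@values), want))
    return("values must carry the 18 morphology parameters in table order")
  if (any(object@values < 0, na.rm = TRUE))
    return("parameters must be non-negative")
  if (!object@normalizerKind %in% c("none", "cell_area", "nuclei_count"))
    return("normalizerKind must be none, cell_area or nuclei_count")
  TRUE
})

#' GroupComparison: group descriptives plus a t-test or ANOVA with Tukey HSD
#'
#' @slot metricName the compared parameter.
#' @slot groupStats data.frame with columns `group`, `n`, `mean`, `sd`
#'   (SD uses the n-1 denominator).
#' @slot test `"t_test"` or `"anova"`.
#' @slot statistic t or F statistic.
#' @slot pValue two-sided p-value.
#' @slot tukey data.frame of pairwise Tukey HSD results (`pair`,
#'   `mean_diff`, `p_adj`), empty for two groups.
#' @slot alpha significance level (strict inequality).
#' @slot significant `pValue < alpha`.
#' @slot degenerate TRUE when all groups had zero within-group variance with
#'   unequal means (p reported as 0).
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    metricName = "character",
    groupStats = "data.frame",
    test = "character",
    statistic = "numeric",
    pValue = "numeric",
    tukey = "data.frame",
    alpha = "numeric",
    significant = "logical",
    degenerate = "logical"
  )
)

setValidity("GroupComparison", function(object) {
  if (!object@test %in% c("t_test", "anova"))
    return("test must be t_test or anova")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  if (!identical(object@significant, object@pValue < object@alpha))
    return("significant must equal pValue < alpha")
  TRUE
})

#' SceneSpec: parameters of one synthetic micrograph
#'
#' Defines the object inventory and optics of a generated field: punctates
#' are single PSF spots, rods are gently curved 2-px-wide strokes, networks
#' are star-shaped trees rooted at a junction. Strokes are blurred with a
#' Gaussian PSF, modulated by a planar illumination gradient, and corrupted
#' with shot (Poisson) or Gaussian read noise before quantization.
#'
#' @slot imageShape integer `(rows, cols)`.
#' @slot nPunctates,nRods,nNetworks object counts to sample.
#' @slot rodLengthRange rod geometric length range in px.
#' @slot branchesPerNetworkRange branches per network (integer range).
#' @slot branchLengthRange network branch length range in px.
#' @slot psfSigma Gaussian PSF standard deviation in px.
#' @slot backgroundLevel camera background offset (intensity units).
#' @slot foregroundLevel stroke amplitude above background.
#' @slot noiseModel `"poisson"` or `"gaussian"`.
#' @slot noiseSd Gaussian read-noise SD (used when `noiseModel="gaussian"`).
#' @slot illuminationAmplitude amplitude `a` of the multiplicative field
#'   `1 + a * g` with `g` a planar gradient in `[0, 1]`.
#' @slot minSeparation minimum boundary-to-boundary object separation in px;
#'   keep it at least `6 * psfSigma` so objects stay distinct after blur.
#' @slot bitDepth output bit depth (8 or 16).
#' @slot rngSeed integer seed; fixes the scene bitwise.
#' @slot objects explicit object inventory (as produced by
#'   [fccpTransform()]); empty list means "sample from the counts above".
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    imageShape = "integer",
    nPunctates = "integer",
    nRods = "integer",
    rodLengthRange = "numeric",
    nNetworks = "integer",
    branchesPerNetworkRange = "integer",
    branchLengthRange = "numeric",
    psfSigma = "numeric",
    backgroundLevel = "numeric",
    foregroundLevel = "numeric",
    noiseModel = "character",
    noiseSd = "numeric",
    illuminationAmplitude = "numeric",
    minSeparation = "numeric",
    bitDepth = "integer",
    rngSeed = "integer",
    objects = "list"
  )
)

setValidity("SceneSpec", function(object) {
  msgs <- character(0)
  if (any(object@imageShape < 32L))
    msgs <- c(msgs, "imageShape must be at least 32x32")
  if (object@rodLengthRange[1] <= 0 || diff(object@rodLengthRange) < 0)
    msgs <- c(msgs, "rodLengthRange must be positive and ordered")
  if (object@branchLengthRange[1] <= 0 || diff(object@branchLengthRange) < 0)
    msgs <- c(msgs, "branchLengthRange must be positive and ordered")
  if (!object@noiseModel %in% c("poisson", "gaussian", "none"))
    msgs <- c(msgs, "noiseModel must be poisson, gaussian or none")
  if (object@minSeparation < 2 * (3 * object@psfSigma) - 1e-9)
    msgs <- c(msgs,
      "minSeparation must be at least 6*psfSigma to keep objects distinct")
  if (!object@bitDepth %in% c(8L, 16L))
    msgs <- c(msgs, "bitDepth must be 8 or 16")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults emulate the study conditions the pipeline targets: sparse bright
#' curvilinear structures (a few dozen objects) on a dark background at 8-bit
#' depth, diffraction-limited blur of about 1.5 px, shot-noise-limited
#' detection and a mild planar illumination gradient.
#'
#' @param imageShape `(rows, cols)` of the field.
#' @param nPunctates,nRods,nNetworks object counts.
#' @param rodLengthRange,branchLengthRange length ranges in px.
#' @param branchesPerNetworkRange integer range of branches per network.
#' @param psfSigma PSF standard deviation in px.
#' @param backgroundLevel,foregroundLevel background offset and stroke
#'   amplitude in intensity units.
#' @param noiseModel `"poisson"` (shot noise), `"gaussian"` or `"none"`.
#' @param noiseSd read-noise SD for the Gaussian model.
#' @param illuminationAmplitude amplitude of the planar gradient field.
#' @param minSeparation minimum object separation in px.
#' @param bitDepth 8 or 16.
#' @param rngSeed integer seed.
#' @param objects explicit inventory; leave empty to sample.
#' @return A [SceneSpec-class] object.
#' @examples
#' sc <- sceneSpec(nPunctates = 5, nRods = 3, nNetworks = 1, rngSeed = 7)
#' gen <- generateScene(sc)
#' @export
sceneSpec <- function(imageShape = c(288L, 288L),
                      nPunctates = 10L, nRods = 10L, nNetworks = 3L,
                      rodLengthRange = c(20, 60),
                      branchesPerNetworkRange = c(3L, 5L),
                      branchLengthRange = c(15, 40),
                      psfSigma = 1.5,
                      backgroundLevel = 20, foregroundLevel = 180,
                      noiseModel = "poisson", noiseSd = 8,
                      illuminationAmplitude = 0.5,
                      minSeparation = 15,
                      bitDepth = 8L, rngSeed = 1L,
                      objects = list()) {
  new("SceneSpec",
      imageShape = as.integer(imageShape),
      nPunctates = as.integer(nPunctates), nRods = as.integer(nRods),
      nNetworks = as.integer(nNetworks),
      rodLengthRange = as.numeric(rodLengthRange),
      branchesPerNetworkRange = as.integer(branchesPerNetworkRange),
      branchLengthRange = as.numeric(branchLengthRange),
      psfSigma = as.numeric(psfSigma),
      backgroundLevel = as.numeric(backgroundLevel),
      foregroundLevel = as.numeric(foregroundLevel),
      noiseModel = noiseModel, noiseSd = as.numeric(noiseSd),
      illuminationAmplitude = as.numeric(illuminationAmplitude),
      minSeparation = as.numeric(minSeparation),
      bitDepth = as.integer(bitDepth), rngSeed = as.integer(rngSeed),
      objects = objects)
}

#' SyntheticGroundTruth: exact inventory of a generated field
#'
#' @slot objects list of per-object records with elements `class`
#'   (`"punctate"`, `"rod"`, `"network"`), `polylines` (list of n-by-2
#'   `(row, col)` coordinate matrices, one per branch), `length` (geometric
#'   length in px; 0 for punctates), `branchCount`, `center`, and `cell`
#'   (owning cell index, 0 for single-cell scenes).
#' @slot nNuclei true nucleus count (multi-cell fields), 0 otherwise.
#' @slot cellCenters K-by-2 matrix of cell centers (multi-cell fields).
#' @slot cellRadius cell disk radius in px (multi-cell fields).
#' @slot imageShape `(rows, cols)`.
#' @slot sourceSpec the [SceneSpec-class] the field was generated from
#'   (used by [fccpTransform()] to derive a perturbed spec).
#' @exportClass SyntheticGroundTruth
setClass("SyntheticGroundTruth",
  representation(
    objects = "list",
    nNuclei = "integer",
    cellCenters = "matrix",
    cellRadius = "numeric",
    imageShape = "integer",
    sourceSpec = "ANY"
  ),
  prototype(nNuclei = 0L, cellCenters = matrix(0, 0, 2),
            cellRadius = NA_real_, sourceSpec = NULL)
)

#' True per-class object counts of a synthetic field
#' @param truth a [SyntheticGroundTruth-class].
#' @return Named integer vector with `punctate`, `rod`, `network` counts.
#' @export
truthCounts <- function(truth) {
  stopifnot(is(truth, "SyntheticGroundTruth"))
  cls <- vapply(truth@objects, function(o) o$class, "")
  c(punctate = sum(cls == "punctate"), rod = sum(cls == "rod"),
    network = sum(cls == "network"))
}
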