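# Synthetic micrograph generator with exact ground truth. Scenes carry the
# statistical structure the pipeline assumes: sparse bright curvilinear
# objects on a dark background, diffraction-limited blur, shot noise and a
# planar illumination gradient.

.polylineLength <- function(P) {
  if (nrow(P) < 2L) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

# Sample a polyline at ~`step` px spacing (includes both endpoints).
.samplePolyline <- function(P, step = 0.3) {
  if (nrow(P) < 2L) return(P)
  out <- list(P[1, , drop = FALSE])
  for (i in seq_len(nrow(P) - 1L)) {
    a <- P[i, ]; b <- P[i + 1L, ]
    d <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(d / step))
    t <- seq_len(k) / k
    out[[i + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                           a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Object templates: geometry relative to the object's own center.

.makePunctate <- function() {
  list(class = "punctate", polylines = list(matrix(0, 1, 2)),
       length = 0, branchCount = 1L, radius = 1.5)
}

# Gently curved rod of geometric length ~L (quadratic Bezier).
.makeRod <- function(L) {
  th <- runif(1, 0, pi)
  u <- c(cos(th), sin(th))
  v <- c(-u[2], u[1])
  bend <- runif(1, 0, 0.08) * L * sample(c(-1, 1), 1)
  p0 <- -u * L / 2; p2 <- u * L / 2; p1 <- v * bend
  t <- seq(0, 1, length.out = 25L)
  P <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  len <- .polylineLength(P)
  list(class = "rod", polylines = list(P), length = len,
       branchCount = 1L, radius = max(sqrt(rowSums(P^2))) + 1)
}

# Star tree: k straight branches from a central junction.
.makeNetwork <- function(k, lenRange) {
  base <- runif(1, 0, 2 * pi)
  ang <- base + 2 * pi * (seq_len(k) - 1L) / k +
    runif(k, -pi / (4 * k), pi / (4 * k))
  lens <- runif(k, lenRange[1], lenRange[2])
  polys <- lapply(seq_len(k), function(i) {
    rbind(c(0, 0), lens[i] * c(cos(ang[i]), sin(ang[i])))
  })
  list(class = "network", polylines = polys, length = sum(lens),
       branchCount = as.integer(k),
       radius = max(lens) + 1)
}

# Coarse point sampling of an object's strokes, for separation checks.
.objectPoints <- function(polylines) {
  do.call(rbind, lapply(polylines, .samplePolyline, step = 1.5))
}

# Place object templates by rejection sampling. Separation is measured
# boundary-to-boundary between stroke point clouds (plus the 1-px stroke
# half-width on each side), which lets thin elongated objects pack far
# more densely than a circumscribed-disk rule would. `fixed` objects
# already have absolute polylines and only contribute exclusion zones.
# Returns absolute-geometry object records.
.placeObjects <- function(templates, fixed, shape, minSep, margin,
                          center = NULL, maxR = NULL) {
  sep <- minSep + 2  # account for the 2-px stroke width
  placedPts <- do.call(rbind, c(list(matrix(0, 0, 2)),
                                lapply(fixed, function(o)
                                  .objectPoints(o$polylines))))
  out <- fixed
  # the hard floor below which objects are no longer guaranteed distinct
  # after PSF blur and thresholding
  sepFloor <- min(sep, 9 + 2)
  for (tp in templates) {
    relPts <- .objectPoints(tp$polylines)
    ok <- FALSE
    trySep <- sep
    for (try in seq_len(4500L)) {
      # crowded fields: relax separation gradually, never below the floor
      if (try == 1501L) trySep <- max(sepFloor, 0.8 * sep)
      if (try == 3001L) trySep <- sepFloor
      if (is.null(center)) {
        ctr <- c(runif(1, margin + 1, shape[1] - margin - 1),
                 runif(1, margin + 1, shape[2] - margin - 1))
      } else {
        rr <- runif(1, 0, max(0.1, maxR))
        aa <- runif(1, 0, 2 * pi)
        ctr <- center + rr * c(cos(aa), sin(aa))
      }
      pts <- sweep(relPts, 2L, ctr, "+")
      if (min(pts[, 1]) < margin + 1 || min(pts[, 2]) < margin + 1 ||
          max(pts[, 1]) > shape[1] - margin ||
          max(pts[, 2]) > shape[2] - margin) next
      if (!is.null(center)) {
        d2c <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
        if (max(d2c) > maxR) next
      }
      if (nrow(placedPts)) {
        d2 <- outer(pts[, 1], placedPts[, 1], "-")^2 +
              outer(pts[, 2], placedPts[, 2], "-")^2
        if (min(d2) < trySep^2) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("object placement failed; use a larger image or fewer objects")
    obj <- tp
    obj$polylines <- lapply(tp$polylines, function(P)
      sweep(P, 2L, ctr, "+"))
    obj$center <- ctr
    obj$radius <- tp$radius
    obj$cell <- if (is.null(tp$cell)) 0L else tp$cell
    out <- c(out, list(obj))
    placedPts <- rbind(placedPts, pts)
  }
  out
}

# Stamp all object polylines onto a 0/1 canvas. Tubules (rods, network
# branches) are drawn at 2-px stroke width; punctates get a 3x3 stamp so
# that, as for a real compact organelle, their peak brightness after PSF
# blur is comparable to a tubule cross-section rather than far below it.
.renderCanvas <- function(objects, shape) {
  stroke <- matrix(0, shape[1], shape[2])
  dot <- matrix(0, shape[1], shape[2])
  strokeOff <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))    # 2x2 = 2-px stroke
  dotOff <- as.matrix(expand.grid(-1:1, -1:1))        # 3x3 blob
  for (o in objects) {
    isDot <- o$class == "punctate"
    off <- if (isDot) dotOff else strokeOff
    for (P in o$polylines) {
      S <- .samplePolyline(P, 0.3)
      pr <- round(S[, 1]); pc <- round(S[, 2])
      for (k in seq_len(nrow(off))) {
        r <- pr + off[k, 1]; cc <- pc + off[k, 2]
        keep <- r >= 1 & r <= shape[1] & cc >= 1 & cc <= shape[2]
        if (isDot) dot[cbind(r[keep], cc[keep])] <- 1
        else stroke[cbind(r[keep], cc[keep])] <- 1
      }
    }
  }
  list(stroke = stroke, dot = dot)
}

# Optics + noise: PSF blur, amplitude scaling, illumination, noise, ADC.
# Tubule strokes and punctate blobs are blurred and peak-normalized
# separately so both classes reach the same peak brightness, as compact
# and tubular organelles carrying the same dye do.
.imageFromCanvas <- function(canvas, spec, extraBackground = 0,
                             sourceId = "synthetic") {
  shape <- dim(canvas$stroke)
  layer <- function(m) {
    if (max(m) == 0) return(m)
    bl <- EBImage::gblur(m, sigma = spec@psfSigma, boundary = "replicate")
    bl / max(bl)
  }
  signal <- spec@foregroundLevel *
    matrix(pmin(1, layer(canvas$stroke) + layer(canvas$dot)),
           shape[1], shape[2])
  g <- (row(signal) + col(signal) - 2) / (shape[1] + shape[2] - 2)
  field <- 1 + spec@illuminationAmplitude * g
  base <- (spec@backgroundLevel + extraBackground + signal) * field
  noisy <- switch(spec@noiseModel,
    poisson = matrix(rpois(length(base), pmax(base, 0)), shape[1]),
    gaussian = base + rnorm(length(base), sd = spec@noiseSd),
    none = base)
  rawImage(.quantize(noisy, spec@bitDepth), bitDepth = spec@bitDepth,
           channel = "mito", sourceId = sourceId)
}

# Sample the object inventory called for by a SceneSpec (templates only).
.sampleTemplates <- function(spec) {
  tmpl <- list()
  ks <- seq(spec@branchesPerNetworkRange[1],
            spec@branchesPerNetworkRange[2])
  for (i in seq_len(spec@nNetworks)) {
    k <- ks[sample.int(length(ks), 1L)]
    tmpl <- c(tmpl, list(.makeNetwork(k, spec@branchLengthRange)))
  }
  for (i in seq_len(spec@nRods))
    tmpl <- c(tmpl, list(.makeRod(runif(1, spec@rodLengthRange[1],
                                        spec@rodLengthRange[2]))))
  for (i in seq_len(spec@nPunctates))
    tmpl <- c(tmpl, list(.makePunctate()))
  tmpl
}

#' Generate a synthetic micrograph with exact ground truth
#'
#' Samples the object inventory called for by the scene parameters (or renders the
#' spec's explicit inventory, re-placing any objects marked for
#' relocation), stamps all strokes at 2-px width, applies Gaussian PSF
#' blur, a multiplicative planar illumination field, the configured noise
#' model and quantization. Fully reproducible: the same `rngSeed` yields a
#' bit-identical image.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `image` ([RawImage-class]) and `truth`
#'   ([SyntheticGroundTruth-class]).
#' @examples
#' gen <- generateScene(sceneSpec(nPunctates = 4, nRods = 2,
#'                                nNetworks = 1, rngSeed = 11))
#' truthCounts(gen$truth)
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  set.seed(spec@rngSeed)
  shape <- spec@imageShape
  margin <- 3 * spec@psfSigma + 2
  if (length(spec@objects)) {
    fixed <- Filter(function(o) !isTRUE(o$needsPlacement), spec@objects)
    todo <- Filter(function(o) isTRUE(o$needsPlacement), spec@objects)
    todo <- lapply(todo, function(o) { o$needsPlacement <- NULL; o })
    objects <- .placeObjects(todo, fixed, shape, spec@minSeparation, margin)
  } else {
    tmpl <- .sampleTemplates(spec)
    objects <- .placeObjects(tmpl, list(), shape, spec@minSeparation,
                             margin)
  }
  canvas <- .renderCanvas(objects, shape)
  img <- .imageFromCanvas(canvas, spec,
                          sourceId = sprintf("synth_seed%d", spec@rngSeed))
  truth <- new("SyntheticGroundTruth", objects = objects,
               nNuclei = 0L, imageShape = shape, sourceSpec = spec)
  list(image = img, truth = truth)
}

#' Uncoupler-style fragmentation transform of a synthetic field
#'
#' Models the stress response of mitochondria to an uncoupler such as
#' FCCP, which collapses membrane potential and rapidly fragments the
#' network: a `fragmentation` fraction of rods is split into punctate
#' pairs (triples for rods of 30 px or more) placed along the former rod,
#' and each network loses a matching fraction of its branches (always
#' keeping at least three, so it remains a network); detached branches
#' become free rods of the same length, relocated into empty space at
#' render time. Rod-to-punctate splitting discards the rod's tubule
#' length by construction (a punctate is a dot); branch detachment
#' conserves length exactly.
#'
#' @param truth a [SyntheticGroundTruth-class] from [generateScene()].
#' @param fragmentation fraction in `[0, 1]`; 0 returns the original spec.
#' @return A derived [SceneSpec-class] with an explicit object inventory;
#'   pass it to [generateScene()] (optionally with a new seed) to render
#'   the fragmented field.
#' @export
fccpTransform <- function(truth, fragmentation) {
  stopifnot(is(truth, "SyntheticGroundTruth"),
            fragmentation >= 0, fragmentation <= 1)
  spec <- truth@sourceSpec
  if (is.null(spec))
    stop("truth does not carry its generating SceneSpec")
  if (fragmentation == 0) return(spec)
  newObjects <- list()
  rodSeen <- 0L
  rodIdx <- which(vapply(truth@objects, function(o) o$class, "") == "rod")
  nSplit <- round(fragmentation * length(rodIdx))
  for (i in seq_along(truth@objects)) {
    o <- truth@objects[[i]]
    if (o$class == "rod") {
      rodSeen <- rodSeen + 1L
      if (rodSeen <= nSplit) {
        # split into punctates pinned along the former rod
        P <- .samplePolyline(o$polylines[[1]], 0.3)
        fr <- if (o$length >= 30) c(0.10, 0.50, 0.90) else c(0.12, 0.88)
        at <- pmax(1L, round(fr * nrow(P)))
        for (a in at) {
          p <- .makePunctate()
          p$polylines <- list(P[a, , drop = FALSE])
          p$center <- P[a, ]
          p$cell <- o$cell
          newObjects <- c(newObjects, list(p))
        }
        next
      }
    } else if (o$class == "network") {
      k <- length(o$polylines)
      m <- min(floor(fragmentation * k), max(0L, k - 3L))
      if (m > 0L) {
        detach <- seq.int(k - m + 1L, k)
        for (d in detach) {
          P <- o$polylines[[d]]
          ctr <- colMeans(P)
          rod <- list(class = "rod",
                      polylines = list(sweep(P, 2L, ctr, "-")),
                      length = .polylineLength(P),
                      branchCount = 1L,
                      radius = max(sqrt(rowSums(
                        sweep(P, 2L, ctr, "-")^2))) + 1,
                      cell = o$cell, needsPlacement = TRUE)
          newObjects <- c(newObjects, list(rod))
        }
        o$polylines <- o$polylines[-detach]
        o$length <- sum(vapply(o$polylines, .polylineLength, 0))
        o$branchCount <- as.integer(k - m)
        o$radius <- max(vapply(o$polylines, function(P)
          max(sqrt(rowSums(sweep(P, 2L, o$center, "-")^2))), 0)) + 1
      }
    }
    newObjects <- c(newObjects, list(o))
  }
  cls <- vapply(newObjects, function(o) o$class, "")
  spec@objects <- newObjects
  spec@nPunctates <- sum(cls == "punctate")
  spec@nRods <- sum(cls == "rod")
  spec@nNetworks <- sum(cls == "network")
  spec
}

#' Generate a multi-cell field, optionally with a nuclei channel
#'
#' Cells are disjoint disks of elevated background laid out on a jittered
#' grid with at least `gap` px between disk boundaries; each disk contains
#' its own sampled scene objects. The optional nuclei channel renders one
#' blurred bright disk per cell, as a Hoechst-stained nucleus would
#' appear.
#'
#' @param nCells number of cells.
#' @param cellSpec [SceneSpec-class] describing the per-cell object
#'   inventory and the optics (its `imageShape` is ignored).
#' @param cellRadius cell disk radius in px.
#' @param gap minimum boundary gap between cells in px.
#' @param withNuclei render the nuclear channel too.
#' @param cellLift background elevation inside a cell disk (intensity
#'   units).
#' @param rngSeed integer seed for the whole field.
#' @return list with `image` ([RawImage-class]), `nuclei`
#'   ([RawImage-class] or NULL) and `truth`
#'   ([SyntheticGroundTruth-class]).
#' @export
generateMulticellField <- function(nCells, cellSpec = sceneSpec(),
                                   cellRadius = 55, gap = 40,
                                   withNuclei = FALSE, cellLift = 15,
                                   rngSeed = 1L) {
  stopifnot(is(cellSpec, "SceneSpec"), nCells >= 0)
  set.seed(as.integer(rngSeed))
  side <- max(1L, ceiling(sqrt(nCells)))
  pitch <- 2 * cellRadius + gap
  dimPx <- as.integer(side * pitch + gap)
  shape <- c(dimPx, dimPx)
  centers <- matrix(0, 0, 2)
  if (nCells > 0) {
    grid <- expand.grid(r = seq_len(side), c = seq_len(side))
    grid <- grid[seq_len(nCells), , drop = FALSE]
    jit <- matrix(runif(2 * nCells, -gap / 4, gap / 4), ncol = 2)
    centers <- cbind(gap + cellRadius + (grid$r - 1) * pitch,
                     gap + cellRadius + (grid$c - 1) * pitch) + jit
  }
  margin <- 3 * cellSpec@psfSigma + 2
  objects <- list()
  for (k in seq_len(nCells)) {
    tmpl <- .sampleTemplates(cellSpec)
    tmpl <- lapply(tmpl, function(o) { o$cell <- as.integer(k); o })
    objects <- c(objects,
                 .placeObjects(tmpl, list(), shape, cellSpec@minSeparation,
                               margin, center = centers[k, ],
                               maxR = cellRadius - margin))
  }
  canvas <- .renderCanvas(objects, shape)
  extra <- matrix(0, shape[1], shape[2])
  for (k in seq_len(nCells)) {
    d2 <- (row(extra) - centers[k, 1])^2 + (col(extra) - centers[k, 2])^2
    extra[d2 <= cellRadius^2] <- cellLift
  }
  img <- .imageFromCanvas(canvas, cellSpec, extraBackground = extra,
                          sourceId = sprintf("synthfield_seed%d", rngSeed))
  nuc <- NULL
  if (withNuclei) {
    nr <- max(6, cellRadius * 0.25)
    nucCanvas <- matrix(0, shape[1], shape[2])
    for (k in seq_len(nCells)) {
      d2 <- (row(nucCanvas) - centers[k, 1])^2 +
            (col(nucCanvas) - centers[k, 2])^2
      nucCanvas[d2 <= nr^2] <- 1
    }
    base <- cellSpec@backgroundLevel + cellSpec@foregroundLevel *
      (if (nCells > 0) EBImage::gblur(nucCanvas, sigma = 2,
                                      boundary = "replicate") else nucCanvas)
    noisy <- switch(cellSpec@noiseModel,
      poisson = matrix(rpois(length(base), pmax(base, 0)), shape[1]),
      gaussian = base + rnorm(length(base), sd = cellSpec@noiseSd),
      none = base)
    nuc <- rawImage(.quantize(noisy, cellSpec@bitDepth),
                    bitDepth = cellSpec@bitDepth, channel = "nuclei",
                    sourceId = sprintf("synthfield_seed%d_nuclei", rngSeed))
  }
  fieldSpec <- cellSpec
  fieldSpec@imageShape <- shape
  truth <- new("SyntheticGroundTruth", objects = objects,
               nNuclei = as.integer(nCells), cellCenters = centers,
               cellRadius = cellRadius, imageShape = shape,
               sourceSpec = fieldSpec)
  list(image = img, nuclei = nuc, truth = truth)
}
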