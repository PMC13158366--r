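# Skeleton graph: endpoints, junction clusters and traced branches per
# 8-connected component. This is the substrate for every morphology
# parameter downstream.

#' Build the branch graph of a skeleton
#'
#' Labels 8-connected components, computes the skeleton-neighbor degree of
#' every pixel, merges mutually 8-adjacent pixels of degree >= 3 into
#' junction clusters (thinning leaves small junction "thick spots" that
#' would otherwise multiply branch counts), and traces branches between
#' nodes (endpoints and junction clusters). Branch length accumulates 1 per
#' axial step and sqrt(2) per diagonal step. Isolated single pixels are
#' branches of length 0; node-free closed loops are a single cycle branch.
#'
#' Two graph-level cleanups correct artifacts of thinning thick, jagged
#' strokes before classification. First, terminal branches of at most
#' `spurLength` px hanging off a cluster with three or more incident
#' branch ends are removed (boundary spurs, not structure; set
#' `spurLength = 0` to keep them). Second, clusters left with fewer than
#' three incident branch ends are dissolved: staircase corners of a
#' digitized line produce mid-path pixels of degree 3, but a topological
#' junction needs at least three incident branches, so the adjoining
#' branches are merged, adding the geodesic across the cluster's pixels.
#'
#' Components are then classified as `network` (>= 1 surviving junction
#' cluster, or a closed loop), `rod` (no junction, more than
#' `punctateMax` pixels) or `punctate` (no junction, at most
#' `punctateMax` pixels). The default boundary of 3 px marks objects with
#' no meaningful length that render as dots at typical 40x magnification;
#' it is configurable because the punctate/rod size boundary is a
#' convention, not a measurement.
#'
#' Enumeration order is fixed by row-major `(row, col)` scan order, so the
#' result is deterministic.
#'
#' @param skel a [SkeletonImage-class] (or logical matrix) satisfying the
#'   1-px-width contract.
#' @param punctateMax punctate/rod boundary in skeleton pixels.
#' @param spurLength maximum length (px) of terminal branches discarded
#'   as thinning spurs at junctions; 0 disables spur removal.
#' @return A [SkeletonGraph-class].
#' @examples
#' m <- matrix(FALSE, 5, 12); m[3, 3:10] <- TRUE
#' g <- buildGraph(skeletonImage(m))
#' componentCensus(g)$rodCount  # 1
#' @export
buildGraph <- function(skel, punctateMax = 5, spurLength = 3) {
  if (is(skel, "SkeletonImage")) {
    mask <- skel@pixels
    src <- skel@sourceMaskId
  } else if (is.matrix(skel) && is.logical(skel)) {
    mask <- skel
    src <- ""
  } else {
    stop("skel must be a SkeletonImage or a logical matrix")
  }
  bad <- .find2x2(mask)
  if (!is.null(bad))
    stop(sprintf(
      "skeleton integrity error: fully set 2x2 block at pixel (%d, %d)",
      bad["row"], bad["col"]))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L)
    return(new("SkeletonGraph", components = list(),
               punctateMax = punctateMax, nPixels = 0L, sourceId = src))
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ord <- order(r, cc)                    # row-major scan order
  idx <- idx[ord]; r <- r[ord]; cc <- cc[ord]
  fg <- integer(nr * nc)
  fg[idx] <- seq_len(n)
  # adjacency lists (ids sorted, hence row-major deterministic)
  pi <- integer(0); pj <- integer(0)
  for (k in seq_len(8L)) {
    r2 <- r + .N8[k, 1]; c2 <- cc + .N8[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[nb]
    pi <- c(pi, which(ok)[keep])
    pj <- c(pj, fg[nb[keep]])
  }
  adj <- vector("list", n)
  if (length(pi)) {
    sp <- split(pj, pi)
    adj[as.integer(names(sp))] <- lapply(sp, sort)
  }
  deg <- lengths(adj)
  compLab <- .label8(mask)
  compOf <- compLab[idx]
  nComp <- max(compOf)
  # junction clusters: connected sets of degree>=3 pixels
  isJct <- deg >= 3L
  clusterOf <- integer(n)
  nodeOf <- integer(n)
  nNodes <- 0L
  if (any(isJct)) {
    jm <- matrix(FALSE, nr, nc)
    jm[idx[isJct]] <- TRUE
    jlab <- .label8(jm)
    clusterOf[isJct] <- jlab[idx[isJct]]
    nClust <- max(clusterOf)
    nodeOf[isJct] <- clusterOf[isJct]
    nNodes <- nClust
  }
  isEnd <- deg <= 1L
  if (any(isEnd)) {
    nodeOf[isEnd] <- nNodes + seq_len(sum(isEnd))
    nNodes <- nNodes + sum(isEnd)
  }
  nClust <- max(clusterOf, 0L)
  clusterPixels <- if (nClust > 0L)
    split(which(clusterOf > 0L), clusterOf[clusterOf > 0L]) else list()
  s2 <- sqrt(2)
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) {
    if (a < b) paste0(a, ".", b) else paste0(b, ".", a)
  }
  brComp <- integer(0); brLen <- numeric(0); brPix <- integer(0)
  brFrom <- integer(0); brTo <- integer(0)
  brFromPix <- integer(0); brToPix <- integer(0)
  nodePixels <- which(nodeOf > 0L)        # already in row-major order
  for (s in nodePixels) {
    for (m1 in adj[[s]]) {
      if (nodeOf[m1] > 0L && nodeOf[m1] == nodeOf[s]) next  # intra-cluster
      k <- ekey(s, m1)
      if (!is.null(used[[k]])) next
      used[[k]] <- TRUE
      len <- if (r[s] != r[m1] && cc[s] != cc[m1]) s2 else 1
      npx <- 2L
      prev <- s; cur <- m1
      while (nodeOf[cur] == 0L) {
        nbrs <- adj[[cur]]
        nxt <- if (nbrs[1L] == prev) nbrs[2L] else nbrs[1L]
        used[[ekey(cur, nxt)]] <- TRUE
        len <- len + if (r[cur] != r[nxt] && cc[cur] != cc[nxt]) s2 else 1
        npx <- npx + 1L
        prev <- cur; cur <- nxt
      }
      brComp <- c(brComp, compOf[s])
      brLen <- c(brLen, len)
      brPix <- c(brPix, npx)
      brFrom <- c(brFrom, nodeOf[s])
      brTo <- c(brTo, nodeOf[cur])
      brFromPix <- c(brFromPix, s)
      brToPix <- c(brToPix, cur)
    }
  }
  # Dissolve degenerate junction clusters. Thinning staircase corners
  # leave clusters of degree>=3 pixels in the middle of a simple path
  # (2 incident branch ends) or at a thick line tip (<= 1 incident end);
  # topologically these are not junctions. Merge or absorb their branches,
  # adding the geodesic across the cluster pixels.
  clusterAlive <- rep(TRUE, nClust)
  if (nClust > 0L) {
    geodesic <- function(pix, from, to) {
      # BFS shortest path over a tiny pixel set with 1/sqrt(2) steps
      if (from == to) return(0)
      dist <- setNames(rep(Inf, length(pix)), pix)
      dist[as.character(from)] <- 0
      queue <- from
      while (length(queue)) {
        curp <- queue[1L]; queue <- queue[-1L]
        for (nb in intersect(adj[[curp]], pix)) {
          step <- if (r[curp] != r[nb] && cc[curp] != cc[nb]) s2 else 1
          nd <- dist[as.character(curp)] + step
          if (nd < dist[as.character(nb)]) {
            dist[as.character(nb)] <- nd
            queue <- c(queue, nb)
          }
        }
      }
      d <- dist[as.character(to)]
      if (is.finite(d)) d else 0
    }
    spanFrom <- function(pix, from) {
      if (length(pix) <= 1L) return(0)
      max(vapply(pix, function(p) geodesic(pix, from, p), 0))
    }
    nextNode <- nNodes
    alive <- rep(TRUE, length(brLen))
    repeat {
      changed <- FALSE
      # graph-level spur removal: a terminal branch of at most spurLength
      # hanging off a cluster that has >= 3 incident ends is a thinning
      # artifact of the thick stroke boundary, not structure
      if (spurLength > 0) {
        for (cl in seq_len(nClust)) {
          if (!clusterAlive[cl]) next
          inc <- which(alive & (brFrom == cl | brTo == cl))
          nEnds <- sum(brFrom[inc] == cl) + sum(brTo[inc] == cl)
          if (nEnds < 3L) next
          for (b in inc) {
            if (nEnds < 3L) break
            if (brFrom[b] == cl && brTo[b] == cl) {
              # tiny self-loop = thinning triangle, not a real ring
              if (brLen[b] <= 2 * spurLength) {
                alive[b] <- FALSE
                nEnds <- nEnds - 2L
                changed <- TRUE
              }
              next
            }
            other <- if (brFrom[b] == cl) brTo[b] else brFrom[b]
            if (other > nClust && brLen[b] <= spurLength) {
              alive[b] <- FALSE
              nEnds <- nEnds - 1L
              changed <- TRUE
            }
          }
        }
      }
      for (cl in seq_len(nClust)) {
        if (!clusterAlive[cl]) next
        inc <- which(alive & (brFrom == cl | brTo == cl))
        nEnds <- sum(brFrom[inc] == cl) + sum(brTo[inc] == cl)
        if (nEnds == 2L && length(inc) == 2L) {
          b1 <- inc[1L]; b2 <- inc[2L]
          p1 <- if (brFrom[b1] == cl) brFromPix[b1] else brToPix[b1]
          p2 <- if (brFrom[b2] == cl) brFromPix[b2] else brToPix[b2]
          delta <- geodesic(clusterPixels[[cl]], p1, p2)
          farN2 <- if (brFrom[b2] == cl) brTo[b2] else brFrom[b2]
          farP2 <- if (brFrom[b2] == cl) brToPix[b2] else brFromPix[b2]
          brLen[b1] <- brLen[b1] + delta + brLen[b2]
          brPix[b1] <- brPix[b1] + brPix[b2] +
            length(clusterPixels[[cl]]) - 2L
          if (brFrom[b1] == cl) {
            brFrom[b1] <- farN2; brFromPix[b1] <- farP2
          } else {
            brTo[b1] <- farN2; brToPix[b1] <- farP2
          }
          alive[b2] <- FALSE
          clusterAlive[cl] <- FALSE
          changed <- TRUE
        } else if (nEnds == 1L) {
          b1 <- inc[1L]
          p1 <- if (brFrom[b1] == cl) brFromPix[b1] else brToPix[b1]
          delta <- spanFrom(clusterPixels[[cl]], p1)
          brLen[b1] <- brLen[b1] + delta
          brPix[b1] <- brPix[b1] + length(clusterPixels[[cl]]) - 1L
          nextNode <- nextNode + 1L
          if (brFrom[b1] == cl) brFrom[b1] <- nextNode
          else brTo[b1] <- nextNode
          clusterAlive[cl] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    keep <- alive
    brComp <- brComp[keep]; brLen <- brLen[keep]; brPix <- brPix[keep]
    brFrom <- brFrom[keep]; brTo <- brTo[keep]
    brFromPix <- brFromPix[keep]; brToPix <- brToPix[keep]
  }
  clustComp <- if (nClust > 0L)
    vapply(clusterPixels, function(p) compOf[p[1L]], 0L) else integer(0)
  comps <- vector("list", nComp)
  for (ci in seq_len(nComp)) {
    inComp <- compOf == ci
    pc <- sum(inComp)
    jc <- sum(clusterAlive[clustComp == ci])
    ec <- sum(isEnd[inComp])
    bsel <- brComp == ci
    bl <- brLen[bsel]; bp <- brPix[bsel]
    bf <- brFrom[bsel]; bt <- brTo[bsel]
    if (!length(bl)) {
      if (pc == 1L) {
        bl <- 0; bp <- 1L; bf <- nodeOf[which(inComp)]; bt <- bf
      } else if (ec == 0L) {
        # node-free closed loop: one cycle branch over every edge
        loopLen <- 0
        for (i in which(inComp)) {
          for (j in adj[[i]]) if (j > i)
            loopLen <- loopLen +
              if (r[i] != r[j] && cc[i] != cc[j]) s2 else 1
        }
        bl <- loopLen; bp <- pc; bf <- 0L; bt <- 0L
      }
    }
    isLoop <- jc == 0L && ec == 0L && pc > 1L
    cls <- if (jc >= 1L || isLoop) "network"
           else if (pc > punctateMax) "rod" else "punctate"
    comps[[ci]] <- list(
      pixelCount = pc, class = cls,
      junctionCount = jc, endpointCount = ec,
      branchLengths = as.numeric(bl), branchPixels = as.integer(bp),
      branchFrom = as.integer(bf), branchTo = as.integer(bt),
      totalLength = sum(bl))
  }
  new("SkeletonGraph", components = comps, punctateMax = punctateMax,
      nPixels = n, sourceId = src)
}

#' Census of a skeleton graph
#'
#' Counts components by morphological class and totals their lengths:
#' punctate/rod lengths are the component branch totals of those classes,
#' network length is the sum of branch lengths over network components.
#'
#' @param graph a [SkeletonGraph-class].
#' @return list with `punctateCount`, `rodCount`, `networkCount`,
#'   `punctateLength`, `rodLength`, `networkLength`,
#'   `networkBranchCounts` (branches per network component) and
#'   `totalNetworkBranchCount`.
#' @export
componentCensus <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  cls <- vapply(graph@components, function(co) co$class, "")
  tot <- vapply(graph@components, function(co) co$totalLength, 0)
  nbr <- vapply(graph@components, function(co) length(co$branchLengths), 0L)
  list(
    punctateCount = sum(cls == "punctate"),
    rodCount = sum(cls == "rod"),
    networkCount = sum(cls == "network"),
    punctateLength = sum(tot[cls == "punctate"]),
    rodLength = sum(tot[cls == "rod"]),
    networkLength = sum(tot[cls == "network"]),
    networkBranchCounts = nbr[cls == "network"],
    totalNetworkBranchCount = sum(nbr[cls == "network"]))
}

#' Branch table of a skeleton graph
#'
#' Debug-level dump of every traced branch.
#'
#' @param graph a [SkeletonGraph-class].
#' @return data.frame with `component_id`, `branch_id`, `length`,
#'   `n_pixels`.
#' @export
branchTable <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  rows <- lapply(seq_along(graph@components), function(ci) {
    co <- graph@components[[ci]]
    if (!length(co$branchLengths)) return(NULL)
    data.frame(component_id = ci,
               branch_id = seq_along(co$branchLengths),
               length = co$branchLengths,
               n_pixels = co$branchPixels)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(component_id = integer(0), branch_id = integer(0),
                      length = numeric(0), n_pixels = integer(0))
  out
}
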