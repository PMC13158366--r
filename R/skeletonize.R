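# Zhang-Suen two-subiteration thinning.

# One thinning subpass, vectorized over the whole (padded) grid.
# sub = 1: delete iff 2<=B<=6, A==1, p2*p4*p6==0, p4*p6*p8==0
# sub = 2: delete iff 2<=B<=6, A==1, p2*p4*p8==0, p2*p6*p8==0
.zsSubpass <- function(m, sub) {
  p <- vector("list", 8L)
  for (k in seq_len(8L)) p[[k]] <- .shift(m, .N8[k, 1], .N8[k, 2])
  # p[[1]] = p2 (north) ... p[[8]] = p9 (NW)
  B <- p[[1]] + p[[2]] + p[[3]] + p[[4]] + p[[5]] + p[[6]] + p[[7]] + p[[8]]
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    A <- A + (p[[k]] == 0L & p[[nxt]] == 1L)
  }
  if (sub == 1L) {
    c3 <- p[[1]] * p[[3]] * p[[5]] == 0L  # p2*p4*p6
    c4 <- p[[3]] * p[[5]] * p[[7]] == 0L  # p4*p6*p8
  } else {
    c3 <- p[[1]] * p[[3]] * p[[7]] == 0L  # p2*p4*p8
    c4 <- p[[1]] * p[[5]] * p[[7]] == 0L  # p2*p6*p8
  }
  del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c3 & c4
  m[del] <- 0L
  m
}

#' Zhang-Suen thinning of a binary mask
#'
#' Reduces a binary mask to a one-pixel-wide skeleton by the classic
#' two-subiteration boundary-peeling scheme: in each iteration, boundary
#' pixels satisfying the neighbor-count (`2 <= B <= 6`), single-transition
#' (`A == 1`) and directional conditions are deleted simultaneously, first
#' for the south-east boundary subpass, then for the north-west one, until
#' a full iteration deletes nothing. The mask is processed against an
#' implicit background frame. The result preserves the number of
#' 8-connected components and contains no fully set 2x2 block.
#'
#' The classic deletion rules are used verbatim, with two corrective
#' post-steps: the rare fully set 2x2 block the simultaneous-deletion
#' scheme can leave where branches cross is resolved by deleting simple
#' pixels only (topology unchanged), and any input component the rules
#' erase completely (they remove an isolated 2x2 square entirely, which
#' would lose punctate blobs) is restored as its single medoid pixel, so
#' the 8-connected component count of the input is always preserved.
#' Terminal spur branches of up to
#' `pruneSpurs` pixels (thinning artifacts on noisy masks that would
#' inflate branch counts) can optionally be removed; the default leaves
#' the skeleton untouched.
#'
#' @param mask a [BinaryMask-class] or logical matrix.
#' @param pruneSpurs remove terminal branches with at most this many
#'   interior pixels after thinning (0 = off).
#' @return A [SkeletonImage-class].
#' @examples
#' m <- matrix(FALSE, 9, 24); m[3:7, 3:22] <- TRUE
#' skel <- zhangSuenThin(binaryMask(m))
#' sum(pixels(skel)) < sum(m)
#' @export
zhangSuenThin <- function(mask, pruneSpurs = 0L) {
  if (is(mask, "BinaryMask")) {
    src <- mask@sourceId
    m <- mask@pixels
  } else if (is.matrix(mask) && is.logical(mask)) {
    src <- ""
    m <- mask
  } else {
    stop("mask must be a BinaryMask or a logical matrix")
  }
  H <- nrow(m); W <- ncol(m)
  # implicit background frame
  g <- matrix(0L, H + 2L, W + 2L)
  g[2:(H + 1L), 2:(W + 1L)] <- m * 1L
  repeat {
    before <- sum(g)
    g <- .zsSubpass(g, 1L)
    g <- .zsSubpass(g, 2L)
    if (sum(g) == before) break
  }
  g <- .removeStaircases(g)
  g <- .removeBlockResiduals(g)
  out <- g[2:(H + 1L), 2:(W + 1L)] == 1L
  out <- .restoreVanished(m, out)
  if (pruneSpurs > 0L) out <- .pruneSpurs(out, as.integer(pruneSpurs))
  skeletonImage(out, sourceMaskId = src)
}

# Holt's staircase-removal passes. The two-subiteration rules leave
# staggered 2-px-wide diagonal staircases (every pixel keeps >= 3
# neighbors without forming a full 2x2 block); one north and one south
# pass of the standard staircase templates reduce them to single-pixel
# diagonals while preserving connectivity. Deletions are simultaneous
# within a pass.
.removeStaircases <- function(g) {
  shift <- function(dr, dc) .shift(g, dr, dc)
  for (pass in c("north", "south")) {
    N <- shift(-1, 0); S <- shift(1, 0); E <- shift(0, 1); W <- shift(0, -1)
    NE <- shift(-1, 1); NW <- shift(-1, -1)
    SE <- shift(1, 1); SW <- shift(1, -1)
    if (pass == "north") {
      del <- g == 1L & N == 1L &
        ((E == 1L & NE == 0L & SW == 0L & (W == 0L | S == 0L)) |
         (W == 1L & NW == 0L & SE == 0L & (E == 0L | S == 0L)))
    } else {
      del <- g == 1L & S == 1L &
        ((E == 1L & SE == 0L & NW == 0L & (W == 0L | N == 0L)) |
         (W == 1L & SW == 0L & NE == 0L & (E == 0L | N == 0L)))
    }
    g[del] <- 0L
  }
  g
}

# The deletion rules remove small compact blobs entirely (an isolated 2x2
# square satisfies both subpasses at every pixel), which would lose
# punctate objects. Restore the medoid pixel of any input component whose
# skeleton came out empty, keeping the skeleton a subset of the mask and
# the component count preserved.
.restoreVanished <- function(mask, skel) {
  lab <- .label8(mask)
  K <- max(lab)
  if (K == 0L) return(skel)
  gone <- setdiff(seq_len(K), unique(lab[skel]))
  for (k in gone) {
    idx <- which(lab == k)
    nr <- nrow(mask)
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    d2 <- (r - mean(r))^2 + (cc - mean(cc))^2
    skel[idx[which.min(d2)]] <- TRUE
  }
  skel
}

# 8-simple test at (r, c): the foreground pixels of the 8-neighbor ring
# form exactly one 8-connected component, and the pixel touches background
# through at least one 4-neighbor. Deleting such a pixel preserves the
# component structure. Ring positions 1..8 = N, NE, E, SE, S, SW, W, NW;
# two ring cells are 8-adjacent when consecutive, or when both axial and
# two apart (N-E, E-S, S-W, W-N).
.ringAdj <- local({
  a <- matrix(FALSE, 8, 8)
  for (i in 1:8) { j <- i %% 8L + 1L; a[i, j] <- a[j, i] <- TRUE }
  for (i in c(1L, 3L, 5L, 7L)) {
    j <- if (i == 7L) 1L else i + 2L
    a[i, j] <- a[j, i] <- TRUE
  }
  a
})

.isSimple <- function(g, r, c) {
  p <- c(g[r - 1L, c], g[r - 1L, c + 1L], g[r, c + 1L], g[r + 1L, c + 1L],
         g[r + 1L, c], g[r + 1L, c - 1L], g[r, c - 1L], g[r - 1L, c - 1L])
  fg <- which(p == 1L)
  if (length(fg) < 2L || length(fg) == 8L) return(FALSE)
  if (!(p[1L] == 0L || p[3L] == 0L || p[5L] == 0L || p[7L] == 0L))
    return(FALSE)
  # count components of fg under ring adjacency by label propagation
  lab <- seq_along(fg)
  repeat {
    ch <- FALSE
    for (i in seq_along(fg)) for (j in seq_along(fg)) {
      if (.ringAdj[fg[i], fg[j]] && lab[j] > lab[i]) {
        lab[j] <- lab[i]; ch <- TRUE
      }
    }
    if (!ch) break
  }
  length(unique(lab)) == 1L
}

# The two-subiteration scheme, deleting simultaneously within a subpass,
# can leave a fully set 2x2 block where branches cross (all four pixels
# fail the single-transition test at the same time). Remove such residuals
# by deleting 8-simple pixels from each block, in row-major order, until
# no block remains; topology is preserved by the simple-point condition.
.removeBlockResiduals <- function(g) {
  repeat {
    blk <- g[-nrow(g), -ncol(g)] & g[-1, -ncol(g)] &
           g[-nrow(g), -1] & g[-1, -1]
    w <- which(blk)
    if (!length(w)) return(g)
    nr <- nrow(g) - 1L
    changed <- FALSE
    for (wi in w) {
      r0 <- ((wi - 1L) %% nr) + 1L
      c0 <- ((wi - 1L) %/% nr) + 1L
      corners <- rbind(c(r0, c0), c(r0, c0 + 1L),
                       c(r0 + 1L, c0), c(r0 + 1L, c0 + 1L))
      if (!all(g[corners] == 1L)) next
      done <- FALSE
      for (k in seq_len(4L)) {
        r <- corners[k, 1L]; c <- corners[k, 2L]
        if (.isSimple(g, r, c)) {
          g[r, c] <- 0L
          changed <- TRUE
          done <- TRUE
          break
        }
      }
      if (!done) {
        # no simple corner (e.g. two diagonals crossing): delete the
        # top-left corner and re-attach any diagonal arm it disconnects
        # by shifting the contact onto a shared 4-neighbor
        g <- .deleteAndRepair(g, corners[1L, 1L], corners[1L, 2L])
        changed <- TRUE
      }
    }
    if (!changed) return(g)
  }
}

# Delete pixel (r, c) and, for each diagonal foreground neighbor of the
# deleted pixel that is not attached to any other pixel of its ring
# (i.e. whose arm the deletion severs), set one of the two shared
# 4-neighbor cells to restore the connection, avoiding new 2x2 blocks.
.deleteAndRepair <- function(g, r, c) {
  g[r, c] <- 0L
  ringOf <- function(rr, cc) {
    rbind(c(rr - 1L, cc), c(rr - 1L, cc + 1L), c(rr, cc + 1L),
          c(rr + 1L, cc + 1L), c(rr + 1L, cc), c(rr + 1L, cc - 1L),
          c(rr, cc - 1L), c(rr - 1L, cc - 1L))
  }
  pring <- ringOf(r, c)
  for (dr in c(-1L, 1L)) for (dc in c(-1L, 1L)) {
    qr <- r + dr; qc <- c + dc
    if (g[qr, qc] != 1L) next
    # other foreground pixels of p's ring that q touches
    others <- pring[g[pring] == 1L &
                      !(pring[, 1L] == qr & pring[, 2L] == qc), ,
                    drop = FALSE]
    if (nrow(others) &&
        any(abs(others[, 1L] - qr) <= 1L & abs(others[, 2L] - qc) <= 1L))
      next
    for (cand in list(c(r + dr, c), c(r, c + dc))) {
      if (g[cand[1L], cand[2L]] == 1L) break
      g[cand[1L], cand[2L]] <- 1L
      # reject the candidate if it completes a 2x2 block
      makesBlock <- FALSE
      for (br in (cand[1L] - 1L):cand[1L]) for (bc in (cand[2L] - 1L):cand[2L]) {
        if (g[br, bc] == 1L && g[br + 1L, bc] == 1L &&
            g[br, bc + 1L] == 1L && g[br + 1L, bc + 1L] == 1L)
          makesBlock <- TRUE
      }
      if (makesBlock) g[cand[1L], cand[2L]] <- 0L else break
    }
  }
  g
}

# Remove terminal branches with <= k pixels that end at a junction.
# Free rods and punctates (whose walks end at another endpoint, not a
# junction) are never touched.
.pruneSpurs <- function(skel, k) {
  nr <- nrow(skel); nc <- ncol(skel)
  nbrsOf <- function(i, excl) {
    r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
    out <- integer(0)
    for (kk in seq_len(8L)) {
      r2 <- r + .N8[kk, 1]; c2 <- cc + .N8[kk, 2]
      if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
        li <- (c2 - 1L) * nr + r2
        if (skel[li] && li != excl) out <- c(out, li)
      }
    }
    out
  }
  repeat {
    deg <- .neighborCount8(skel)
    ends <- which(skel & deg == 1L)
    if (!length(ends)) return(skel)
    junction <- skel & deg >= 3L
    removed <- FALSE
    for (e in ends) {
      if (!skel[e]) next
      path <- e; cur <- e; prev <- 0L
      hitJunction <- FALSE
      while (length(path) <= k) {
        nb <- nbrsOf(cur, prev)
        if (any(junction[nb])) { hitJunction <- TRUE; break }
        if (length(nb) != 1L) break  # other endpoint or ambiguity
        prev <- cur; cur <- nb
        path <- c(path, cur)
      }
      if (hitJunction && length(path) <= k) {
        skel[path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) return(skel)
  }
}
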