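# Shared fixtures: small constructed grids and an independent brute-force
# Otsu oracle. Everything is built in code at test time.

# Logical matrix from a character sketch ('.'/'#')
sketch <- function(...) {
  rows <- c(...)
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(x) x == "#"))
  matrix(m, nrow = length(rows))
}

# Brute-force Otsu: evaluate the between-class variance of every split
# {v <= t} / {v > t} directly from class weights and means.
bruteOtsu <- function(values, maxVal) {
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:(maxVal - 1L)) {
    lo <- values[values <= t]
    hi <- values[values > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(values)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; bestT <- t }
  }
  bestT
}

# 8-connected component count via two-pass flood fill (independent of the
# package's igraph-based labeling).
countComponents8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    stack <- list(c(i, j))
    lab[i, j] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  k
}

# A random blobby binary mask (unions of rectangles and disks), seeded.
randomMask <- function(seed, nr = 40L, nc = 40L, nObjects = 4L) {
  set.seed(seed)
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nObjects)) {
    if (runif(1) < 0.5) {
      r0 <- sample(nr - 8L, 1L); c0 <- sample(nc - 8L, 1L)
      m[r0:(r0 + sample(3:7, 1L)), c0:(c0 + sample(3:7, 1L))] <- TRUE
    } else {
      ctr <- c(runif(1, 6, nr - 6), runif(1, 6, nc - 6))
      rad <- runif(1, 2, 5)
      d2 <- (row(m) - ctr[1])^2 + (col(m) - ctr[2])^2
      m[d2 <= rad^2] <- TRUE
    }
  }
  m
}

# A small skeleton derived from a random mask (seeded).
randomSkel <- function(seed) {
  pixels(zhangSuenThin(binaryMask(randomMask(seed))))
}

# Per-cell object inventory for multi-cell fields: modest object sizes so
# everything fits inside a cell disk.
cellSceneSpec <- function(...) {
  sceneSpec(nPunctates = 3, nRods = 2, nNetworks = 1,
            rodLengthRange = c(15, 30), branchLengthRange = c(12, 22), ...)
}

# Quick scene helper used across tests.
quickScene <- function(seed, nP = 5, nR = 4, nN = 1, ...) {
  generateScene(sceneSpec(nPunctates = nP, nRods = nR, nNetworks = nN,
                          rngSeed = seed, ...))
}
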