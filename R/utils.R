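# Internal pixel-grid helpers shared by the thinning, labeling and graph code.

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
.shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# The 8-neighborhood, clockwise from north, as (dr, dc) offsets.
# p2 = north, p3 = NE, p4 = east, ..., p9 = NW.
.N8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
             dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Count of foreground 8-neighbors for every pixel.
.neighborCount8 <- function(mask) {
  m <- mask * 1L
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(8)) out <- out + .shift(m, .N8[k, 1], .N8[k, 2])
  out
}

# 8-connected component labeling via igraph; returns an integer matrix of
# labels 1..K (0 = background), numbered by first occurrence in row-major
# (row, col) scan order.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  fg <- integer(nr * nc)
  fg[idx] <- seq_len(n)
  edges <- list()
  # undirected edges: 4 of the 8 directions suffice
  for (k in c(3L, 4L, 5L, 6L)) {  # E, SE, S, SW
    dr <- .N8[k, 1]; dc <- .N8[k, 2]
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    r2 <- r + dr; c2 <- cc + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[nb]
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(fg[idx[ok][keep]], fg[nb[keep]])
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(el))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(n)
  }
  # renumber components by row-major order of their first pixel
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  ord <- order(r, cc)
  newid <- integer(max(memb))
  nxt <- 0L
  for (i in ord) {
    m <- memb[i]
    if (newid[m] == 0L) { nxt <- nxt + 1L; newid[m] <- nxt }
  }
  lab[idx] <- newid[memb]
  lab
}

# TRUE when the mask contains a fully set 2x2 block; returns the (row, col)
# of the top-left corner of the first such block, or NULL.
.find2x2 <- function(mask) {
  m <- mask * 1L
  blk <- m[-nrow(m), -ncol(m)] + m[-1, -ncol(m)] +
         m[-nrow(m), -1] + m[-1, -1]
  w <- which(blk == 4L)
  if (!length(w)) return(NULL)
  nr <- nrow(m) - 1L
  c(row = ((w[1] - 1L) %% nr) + 1L, col = ((w[1] - 1L) %/% nr) + 1L)
}

# Euclidean step length between two 8-adjacent pixels.
.stepLength <- function(r1, c1, r2, c2) {
  if (r1 != r2 && c1 != c2) sqrt(2) else 1
}

# Clamp and round a numeric matrix back onto the integer intensity scale.
.quantize <- function(m, bitDepth) {
  mx <- 2^bitDepth - 1
  out <- round(pmin(pmax(m, 0), mx))
  storage.mode(out) <- "integer"
  out
}
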