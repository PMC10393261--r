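# Internal numerical helpers shared across modules.

# Separable Gaussian smoothing with replicate (edge-clamped) boundary.
# Implemented as two banded-operator multiplies so that kernels larger than
# the image remain well-defined (boundary weights accumulate on the edge).
gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smoother <- function(n) {
    S <- matrix(0, n, n)
    i <- seq_len(n)
    for (o in -r:r) {
      j <- pmin(pmax(i + o, 1L), n)
      idx <- cbind(i, j)
      S[idx] <- S[idx] + k[o + r + 1L]
    }
    S
  }
  smoother(nrow(x)) %*% x %*% t(smoother(ncol(x)))
}

# Central-difference gradients with replicate edges; returns list(gr, gc).
imageGradient <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- x[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- x[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- x[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- x[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  list(gr = (dn - up) / 2, gc = (rt - lf) / 2)
}

# 8-connected component labelling of a logical matrix. EBImage::bwlabel is
# 4-connected, so the pixel adjacency graph (4 of the 8 neighbour offsets,
# undirected) is handed to igraph.
labelComponents8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  node <- integer(length(mask))
  node[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  nc <- ncol(mask)
  edges <- list()
  neigh <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (d in neigh) {
    ok <- rows + d[1L] >= 1L & rows + d[1L] <= nr & cols + d[2L] <= nc
    nidx <- idx[ok] + d[1L] + d[2L] * nr
    hit <- node[nidx] > 0L
    edges[[length(edges) + 1L]] <- cbind(node[idx[ok]][hit], node[nidx][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, t(el))
  lab[idx] <- igraph::components(g)$membership
  lab
}

# Ordered convex-hull polygon (rows, cols) of the TRUE pixels of a mask.
hullPolygon <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(pts[, 2L], pts[, 1L])
  cbind(row = pts[h, 1L], col = pts[h, 2L])
}

# Rasterize a polygon (rows, cols vertices) to a filled logical matrix.
fillPolygon <- function(poly, dims) {
  out <- matrix(FALSE, dims[1L], dims[2L])
  rr <- max(1L, floor(min(poly[, 1L]))):min(dims[1L], ceiling(max(poly[, 1L])))
  cc <- max(1L, floor(min(poly[, 2L]))):min(dims[2L], ceiling(max(poly[, 2L])))
  grid <- expand.grid(row = rr, col = cc)
  inside <- pracma::inpolygon(grid$col, grid$row, poly[, 2L], poly[, 1L],
                              boundary = TRUE)
  out[cbind(grid$row[inside], grid$col[inside])] <- TRUE
  out
}

# Bilinear interpolation of matrix px at fractional (rows, cols); NA outside.
bilinearSample <- function(px, rows, cols) {
  nr <- nrow(px); nc <- ncol(px)
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  out <- rep(NA_real_, length(rows))
  if (!any(ok)) return(out)
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * px[cbind(r0, c0)] +
       fr       * (1 - fc) * px[cbind(r0 + 1L, c0)] +
       (1 - fr) * fc       * px[cbind(r0, c0 + 1L)] +
       fr       * fc       * px[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}

# Wrap an angle into [0, pi) (axial orientation).
wrapAxial <- function(theta) {
  out <- theta %% pi
  out[out >= pi] <- 0  # guard against pi from floating point
  out
}

# Smallest axial angular difference between two orientations (mod pi).
axialDiff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}
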