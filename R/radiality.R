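#' Dominant local filament orientation by the structure tensor
#'
#' Estimates, at every pixel, the axial direction (modulo \eqn{\pi}) along
#' which the filament signal runs. Image gradients are taken at Gaussian
#' scale \code{sigmaPx}; the outer product of the gradient is smoothed at
#' the same scale, and the orientation is the eigenvector of the tensor's
#' smaller eigenvalue — the direction *along* the local stripes, orthogonal
#' to the dominant gradient. Coherence is the eigenvalue contrast
#' \eqn{(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)}: 1 for a perfect
#' stripe pattern, 0 where the tensor vanishes (flat regions) or is
#' isotropic.
#'
#' Angles are measured from the column axis towards the row axis, so
#' horizontal stripes (intensity varying with row) have angle 0. Because
#' orientation depends only on gradient *ratios*, the field is invariant to
#' a global positive intensity scaling.
#'
#' @param image a [ChannelImage-class] (typically the tubulin channel).
#' @param cell the [CellMask-class] restricting the field to the hull.
#' @param sigmaPx Gaussian gradient/integration scale in pixels (> 0);
#'   default 1.5, roughly the filament width.
#' @param coherenceMin pixels below this coherence are marked invalid;
#'   default 0 keeps every hull pixel. Raising it (e.g. 0.2) excludes flat
#'   cytoplasm whose orientation is noise.
#' @param roi optional logical matrix further restricting validity, e.g. an
#'   eroded cell mask that excludes the outline-gradient shell at the cell
#'   edge (whose orientation follows the cell boundary, not the filaments).
#' @return An [OrientationField-class].
#' @seealso [degreeOfRadiality()]
#' @export
orientationField <- function(image, cell, sigmaPx = 1.5, coherenceMin = 0,
                             roi = NULL) {
  if (sigmaPx <= 0) stop("sigmaPx must be > 0")
  if (coherenceMin < 0 || coherenceMin >= 1)
    stop("coherenceMin must lie in [0, 1)")
  px <- pixelData(image)
  if (!identical(dim(px), dim(hullMask(cell))))
    stop("image and cell mask rasters differ in shape")
  g <- imageGradient(gaussianSmooth(px, sigmaPx))
  Jrr <- gaussianSmooth(g$gr * g$gr, sigmaPx)
  Jcc <- gaussianSmooth(g$gc * g$gc, sigmaPx)
  Jrc <- gaussianSmooth(g$gr * g$gc, sigmaPx)

  tr <- Jrr + Jcc
  disc <- sqrt(((Jrr - Jcc) / 2)^2 + Jrc^2)
  lmin <- tr / 2 - disc
  scale <- max(tr)
  coh <- matrix(0, nrow(px), ncol(px))
  # floor tied to the image's dynamic range so that a constant image (whose
  # tensor is pure floating-point noise) yields coherence 0 everywhere,
  # while a global intensity scaling leaves the valid set unchanged
  floorTr <- (max(abs(px)) * 1e-10)^2 + .Machine$double.xmin
  nz <- tr > floorTr
  coh[nz] <- (2 * disc[nz]) / tr[nz]
  coh <- pmin(pmax(coh, 0), 1)

  # eigenvector of the smaller eigenvalue: (Jrc, lmin - Jrr); where that
  # degenerates (Jrc ~ 0 and lmin = Jrr) the minor axis is the row axis
  vr <- Jrc
  vc <- lmin - Jrr
  degen <- abs(vr) + abs(vc) <= scale * 1e-12
  vr[degen] <- ifelse(Jrr[degen] <= Jcc[degen], 1, 0)
  vc[degen] <- ifelse(Jrr[degen] <= Jcc[degen], 0, 1)
  angle <- wrapAxial(atan2(vr, vc))

  valid <- hullMask(cell) & coh >= coherenceMin & nz
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(valid)))
      stop("roi raster differs in shape")
    valid <- valid & (roi != 0)
  }
  angle[!valid] <- NA_real_
  new("OrientationField", angle = angle, coherence = coh, valid = valid)
}

# Binary erosion by a disc of radius r (px).
erodeMask <- function(mask, r) {
  if (r <= 0) return(mask)
  br <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  EBImage::erode(mask * 1, br) > 0
}

# Otsu threshold of a value vector (maximal between-class variance over a
# 256-level histogram). EBImage::otsu thresholds whole rasters; this gates
# intensities within an arbitrary pixel set (the cell interior).
otsuThreshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), levels)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  breaks[which.max(between[-levels]) + 1L]
}

#' Elliptical Fourier descriptor of the convex-hull contour
#'
#' Fits a closed-contour Kuhl-Giardina elliptical Fourier series to the
#' hull boundary. The boundary polygon is resampled at ~1 px arc-length
#' spacing before the harmonic integrals are taken, so the fit does not
#' depend on vertex density.
#'
#' @param cell a [CellMask-class].
#' @param nHarmonics number of harmonics (default 10).
#' @return An [EFDContour-class] with \code{scaleFraction = 1}.
#' @seealso [efdEvaluate()], [radialSections()]
#' @export
fitHullEFD <- function(cell, nHarmonics = 10L) {
  poly <- hullPolygon(hullMask(cell))
  if (nrow(poly) < 3L) stop("degenerate hull: fewer than 3 vertices")
  pts <- densifyPolygon(poly, spacing = 1)
  if (nrow(pts) < 3L * nHarmonics)
    stop("hull boundary has too few sample points for ", nHarmonics,
         " harmonics")
  efdFit(pts, nHarmonics)
}

# Resample a closed polygon at roughly `spacing` px along each edge.
densifyPolygon <- function(poly, spacing = 1) {
  n <- nrow(poly)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- poly[i, ]
    p1 <- poly[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    k <- max(1L, ceiling(len / spacing))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(p0[1L] + t * (p1[1L] - p0[1L]),
                      p0[2L] + t * (p1[2L] - p0[2L]))
  }
  pts <- do.call(rbind, out)
  colnames(pts) <- c("row", "col")
  pts
}

# Kuhl-Giardina EFD of a closed polyline given as (row, col) samples.
efdFit <- function(pts, nHarmonics) {
  x <- c(pts[, "col"], pts[1L, "col"])  # x = col, y = row
  y <- c(pts[, "row"], pts[1L, "row"])
  dx <- diff(x); dy <- diff(y)
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t <- c(0, cumsum(dt))
  T <- t[length(t)]
  phi <- 2 * pi * t / T
  coef <- matrix(0, nHarmonics, 4L,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(nHarmonics)) {
    cn <- cos(n * phi); sn <- sin(n * phi)
    const <- T / (2 * n^2 * pi^2)
    coef[n, "a"] <- const * sum(dx / dt * diff(cn))
    coef[n, "b"] <- const * sum(dx / dt * diff(sn))
    coef[n, "c"] <- const * sum(dy / dt * diff(cn))
    coef[n, "d"] <- const * sum(dy / dt * diff(sn))
  }
  # DC component (contour centroid by arc length)
  xi <- cumsum(dx) - dx / 2 + x[1L]
  yi <- cumsum(dy) - dy / 2 + y[1L]
  A0 <- sum(xi * dt) / T
  C0 <- sum(yi * dt) / T
  new("EFDContour", coefficients = coef, locus = c(C0, A0),
      scaleFraction = 1)
}

#' Evaluate an EFD contour
#'
#' Reconstructs \code{nPoints} evenly spaced (in curve parameter) points of
#' the descriptor, optionally scaled about a centre (used to generate the
#' intermediate contours of the radial sectioning).
#'
#' @param contour an [EFDContour-class].
#' @param nPoints number of reconstruction points.
#' @param scale uniform scale factor about \code{center}.
#' @param center \code{(row, col)} point to scale about; defaults to the
#'   contour locus.
#' @return Matrix with columns \code{row}, \code{col}.
#' @export
efdEvaluate <- function(contour, nPoints = 360L, scale = 1,
                        center = contour@locus) {
  phi <- seq(0, 2 * pi, length.out = nPoints + 1L)[-(nPoints + 1L)]
  co <- contour@coefficients
  x <- rep(contour@locus[2L], nPoints)
  y <- rep(contour@locus[1L], nPoints)
  for (n in seq_len(nrow(co))) {
    x <- x + co[n, "a"] * cos(n * phi) + co[n, "b"] * sin(n * phi)
    y <- y + co[n, "c"] * cos(n * phi) + co[n, "d"] * sin(n * phi)
  }
  rows <- center[1L] + scale * (y - center[1L])
  cols <- center[2L] + scale * (x - center[2L])
  cbind(row = rows, col = cols)
}

# Semi-axis lengths of the first harmonic ellipse.
efdFirstHarmonicAxes <- function(contour) {
  M <- matrix(contour@coefficients[1L, ], 2L, 2L, byrow = TRUE)
  sv <- svd(M)$d
  sort(sv, decreasing = TRUE)
}

#' Partition the hull into radial sections between intermediate contours
#'
#' Intermediate contour k (k = 1..K) is the outer hull contour scaled about
#' the cell centre by k/K — a linear interpolation between the centre of
#' mass and the outer edge. Section k is the band between contours k-1 and
#' k (contour 0 being the excluded 1-px centre disk); a pixel exactly on
#' contour k belongs to section k, the section whose outer edge it is. The
#' \code{relativeDistance} label of section k is k, in contour-spacing
#' units, so the conventional "relative radial distance 2" report denotes the
#' second section.
#'
#' @param outer the outer-hull [EFDContour-class] from [fitHullEFD()].
#' @param cell the [CellMask-class] (its hull is partitioned; its centroid
#'   is the scaling centre).
#' @param K number of sections (default 4, minimum 2).
#' @param center optional \code{(row, col)} override of the scaling centre.
#' @return A [RadialSectionMap-class].
#' @export
radialSections <- function(outer, cell, K = 4L, center = centerOfMass(cell)) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  hull <- hullMask(cell)
  nr <- nrow(hull); nc <- ncol(hull)

  # star-shaped radius function of the outer contour about the centre
  bnd <- efdEvaluate(outer, nPoints = 1440L)
  bphi <- atan2(bnd[, "row"] - center[1L], bnd[, "col"] - center[2L])
  brad <- sqrt((bnd[, "row"] - center[1L])^2 + (bnd[, "col"] - center[2L])^2)
  o <- order(bphi)
  bphi <- bphi[o]; brad <- brad[o]
  bphi <- c(bphi[length(bphi)] - 2 * pi, bphi, bphi[1L] + 2 * pi)
  brad <- c(brad[length(brad)], brad, brad[1L])

  idx <- which(hull)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  dr <- rows - center[1L]; dc <- cols - center[2L]
  r <- sqrt(dr^2 + dc^2)
  phi <- atan2(dr, dc)
  Rout <- stats::approx(bphi, brad, xout = phi, rule = 2)$y
  s <- r / pmax(Rout, .Machine$double.eps)

  sec <- as.integer(ceiling(s * K - 1e-9))
  sec[sec < 1L] <- 1L
  sec[sec > K] <- K   # hull pixels marginally outside the EFD fit
  sec[r <= 1] <- NA_integer_  # centre disk excluded

  si <- matrix(NA_integer_, nr, nc)
  si[idx] <- sec
  new("RadialSectionMap", sectionIndex = si, K = K,
      relativeDistance = as.numeric(seq_len(K)))
}

#' Degree of Radiality per radial section
#'
#' For each section s, over the valid orientation pixels p in s,
#' \deqn{DoR(s) = \frac{\sum_p |t(p)\cdot \hat r(p)|}{\max(\sum_p |t(p)\cdot
#' \hat c(p)|,\ \epsilon)}}
#' where t(p) is the unit vector of the local filament orientation and
#' \eqn{\hat r, \hat c} are the radial and circular unit fields. A purely
#' radial network gives a large DoR, a purely tangential one 0, and an
#' isotropic (uniform random) orientation field gives DoR close to 1
#' because \eqn{E|\cos\theta| = E|\sin\theta|}. Absolute dot products make
#' the axial sign ambiguity of the orientation irrelevant.
#'
#' The denominator guard \eqn{\epsilon} defaults to \code{1e-6} times the
#' number of valid pixels in the section, keeping a purely radial DoR
#' finite and independent of the intensity scale.
#'
#' @param field an [OrientationField-class].
#' @param fields radial/circular fields from [radialCircularFields()].
#' @param sections a [RadialSectionMap-class] on the same raster.
#' @param epsilon optional fixed denominator guard (> 0); default scales
#'   with the section's valid pixel count.
#' @param cellId identifier recorded on the profile.
#' @return A [DoRProfile-class] with one record per section; sections with
#'   no valid pixels have \code{nPixels = 0} and NA DoR.
#' @export
degreeOfRadiality <- function(field, fields, sections, epsilon = NULL,
                              cellId = "cell") {
  si <- sectionIndex(sections)
  if (!identical(dim(si), dim(validPixels(field))) ||
      !identical(dim(si), dim(fields$domain)))
    stop("field, radial/circular fields and section map rasters differ")
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be > 0")
  K <- nSections(sections)
  use <- validPixels(field) & fields$domain & !is.na(si)
  ang <- orientationAngle(field)[use]
  tr <- sin(ang); tc <- cos(ang)
  dotR <- abs(tr * fields$radialRow[use] + tc * fields$radialCol[use])
  dotC <- abs(tr * fields$circularRow[use] + tc * fields$circularCol[use])
  sidx <- si[use]
  num <- den <- numeric(K)
  nPix <- integer(K)
  for (k in seq_len(K)) {
    inK <- sidx == k
    nPix[k] <- sum(inK)
    num[k] <- sum(dotR[inK])
    den[k] <- sum(dotC[inK])
  }
  eps <- if (is.null(epsilon)) pmax(1e-6 * nPix, .Machine$double.xmin)
         else rep(epsilon, K)
  dor <- num / pmax(den, eps)
  dor[nPix == 0L] <- NA_real_
  new("DoRProfile", cellId = as.character(cellId),
      relativeDistance = sections@relativeDistance,
      dor = dor, nPixels = nPix)
}

#' Query a DoR profile at a relative radial distance
#'
#' @param profile a [DoRProfile-class].
#' @param relativeDistance the section label to query (default 2, the
#'   distance reported for microtubule pattern comparisons).
#' @return The section's DoR value.
#' @export
dorAt <- function(profile, relativeDistance = 2) {
  hit <- which(abs(profile@relativeDistance - relativeDistance) < 1e-9)
  if (!length(hit))
    stop("no section at relative distance ", relativeDistance,
         " (available: ", paste(profile@relativeDistance, collapse = ", "), ")")
  profile@dor[hit[1L]]
}

#' Full DoR pipeline for one tubulin image
#'
#' Convenience wrapper running segmentation, radial/circular fields,
#' structure-tensor orientation, hull EFD, radial sectioning and the DoR
#' computation in sequence.
#'
#' @param image tubulin [ChannelImage-class].
#' @param cell optional precomputed [CellMask-class]; segmented from
#'   \code{image} when missing.
#' @param K number of radial sections.
#' @param sigmaPx structure-tensor scale in pixels.
#' @param coherenceMin minimum coherence for a pixel to contribute.
#' @param nHarmonics EFD harmonics for the hull contour.
#' @param minAreaPx smallest component kept during segmentation.
#' @param boundaryExcludePx width (px) of the shell at the mask boundary
#'   excluded from the orientation field — the intensity step at the cell
#'   edge produces a spurious boundary-parallel orientation that would bias
#'   DoR downward; default 4 (about 2-3 structure-tensor scales).
#' @param intensityGate if TRUE (default), orientation pixels must also be
#'   filament-bright: above the Otsu threshold of the smoothed intensities
#'   inside the (eroded) mask. Orientation is only meaningful where there
#'   is filament signal; flat cytoplasm inherits a spurious long-range
#'   orientation from the nearest edge or filament.
#' @param cellId identifier recorded on the profile.
#' @return A [DoRProfile-class].
#' @examples
#' spec <- syntheticCellSpec(radialityAlpha = 1, seed = 7)
#' sim <- makeFilamentCell(spec)
#' prof <- analyzeRadiality(sim$image, coherenceMin = 0.2)
#' dorAt(prof, 2)
#' @export
analyzeRadiality <- function(image, cell = NULL, K = 4L, sigmaPx = 1.5,
                             coherenceMin = 0.2, nHarmonics = 10L,
                             minAreaPx = 100L, boundaryExcludePx = 4L,
                             intensityGate = TRUE, cellId = "cell") {
  if (is.null(cell)) cell <- segmentCell(image, minAreaPx = minAreaPx)
  fields <- radialCircularFields(cell)
  roi <- erodeMask(cellMask(cell), boundaryExcludePx)
  if (intensityGate) {
    sm <- gaussianSmooth(pixelData(image), sigmaPx)
    roi <- roi & sm > otsuThreshold(sm[roi])
  }
  field <- orientationField(image, cell, sigmaPx = sigmaPx,
                            coherenceMin = coherenceMin, roi = roi)
  outer <- fitHullEFD(cell, nHarmonics = nHarmonics)
  sections <- radialSections(outer, cell, K = K)
  degreeOfRadiality(field, fields, sections, cellId = cellId)
}
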