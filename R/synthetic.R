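#' Declare a synthetic cell
#'
#' Constructor for [SyntheticCellSpec-class]. Defaults describe the imaging
#' situation the pipeline targets: a spread T cell of ~10 um diameter at
#' 0.2 um/px (elliptical footprint, semi-axes 26 x 21 px), 60 microtubule
#' filaments organized from a centrosome offset from the cell centre, and
#' moderate additive Gaussian noise.
#'
#' @param semiAxes ellipse semi-axes in pixels (each >= 4).
#' @param epsilon boundary-perturbation amplitude in [0, 1).
#' @param lobes number of boundary lobes (cosine perturbation frequency).
#' @param radialityAlpha probability a filament is radial rather than
#'   tangential; 1 gives a purely radial network, 0 purely tangential.
#' @param nFilaments number of filaments.
#' @param centerOffsetPx \code{(row, col)} offset of the organizing centre
#'   from the footprint centre.
#' @param noiseSigma Gaussian noise sd in intensity units.
#' @param pixelSizeUm pixel size in micrometres.
#' @param seed RNG seed.
#' @return A [SyntheticCellSpec-class].
#' @export
syntheticCellSpec <- function(semiAxes = c(26, 21), epsilon = 0, lobes = 0L,
                              radialityAlpha = 1, nFilaments = 60L,
                              centerOffsetPx = c(3, -4), noiseSigma = 5,
                              pixelSizeUm = 0.2, seed = 1L) {
  new("SyntheticCellSpec", semiAxes = as.numeric(semiAxes),
      epsilon = as.numeric(epsilon), lobes = as.integer(lobes),
      radialityAlpha = as.numeric(radialityAlpha),
      nFilaments = as.integer(nFilaments),
      centerOffsetPx = as.numeric(centerOffsetPx),
      noiseSigma = as.numeric(noiseSigma),
      pixelSizeUm = as.numeric(pixelSizeUm), seed = as.integer(seed))
}

# Boundary radius r(theta) of the perturbed ellipse footprint.
footprintRadius <- function(theta, semiAxes, epsilon, lobes, phase = 0) {
  a <- semiAxes[1L]; b <- semiAxes[2L]   # a: row semi-axis, b: col semi-axis
  re <- a * b / sqrt((b * sin(theta))^2 + (a * cos(theta))^2)
  re * (1 + epsilon * cos(lobes * theta + phase))
}

# Rasterize the footprint mask on a raster sized to fit it (+ margin).
footprintMask <- function(semiAxes, epsilon, lobes, phase = 0, margin = 6L) {
  ext <- ceiling(max(semiAxes) * (1 + epsilon)) + margin
  n <- as.integer(2L * ext + 1L)
  ctr <- ext + 1
  dr <- matrix(seq_len(n) - ctr, n, n)
  dc <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  theta <- atan2(dr, dc)
  R <- footprintRadius(theta, semiAxes, epsilon, lobes, phase)
  list(mask = sqrt(dr^2 + dc^2) <= R, center = c(ctr, ctr))
}

#' Generate a rough binary mask
#'
#' A filled region whose boundary radius is the ellipse radius modulated by
#' \code{1 + epsilon * cos(lobes * theta + phase)}; \code{epsilon = 0} gives
#' the exact digitized ellipse (a disk for equal semi-axes), and
#' \code{lobes = 0} a uniformly scaled (still convex) ellipse. Used to
#' exercise the roughness metric with a known convex reference.
#'
#' @param semiAxes ellipse semi-axes in pixels (each >= 4).
#' @param epsilon perturbation amplitude, \code{0 <= epsilon < 1}.
#' @param lobes integer perturbation frequency (>= 0).
#' @param seed seed for the random phase of the perturbation.
#' @return Logical matrix.
#' @examples
#' sum(makeRoughMask(c(30, 30), 0, 0))        # digitized disk area ~ pi*30^2
#' @export
makeRoughMask <- function(semiAxes, epsilon = 0, lobes = 0L, seed = 1L) {
  if (epsilon >= 1) stop("epsilon must be < 1")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (any(semiAxes < 4)) stop("degenerate footprint: semi-axis < 4 px")
  phase <- if (lobes > 0L)
    withr::with_seed(seed, stats::runif(1, 0, 2 * pi)) else 0
  footprintMask(semiAxes, epsilon, as.integer(lobes), phase)$mask
}

# Draw one anti-aliased segment into the accumulator `acc` (pmax blend) and
# record its axial orientation where it passes within 1 px. Operates on an
# environment to avoid copying matrices per filament.
drawSegment <- function(env, p0, p1, amp, width = 0.8) {
  nr <- nrow(env$fil); nc <- ncol(env$fil)
  r0 <- max(1L, floor(min(p0[1L], p1[1L]) - 3))
  r1 <- min(nr, ceiling(max(p0[1L], p1[1L]) + 3))
  c0 <- max(1L, floor(min(p0[2L], p1[2L]) - 3))
  c1 <- min(nc, ceiling(max(p0[2L], p1[2L]) + 3))
  if (r0 > r1 || c0 > c1) return(invisible())
  rr <- r0:r1; cc <- c0:c1
  dr <- matrix(rr - p0[1L], length(rr), length(cc))
  dc <- matrix(cc - p0[2L], length(rr), length(cc), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- if (len2 > 0) pmin(pmax((dr * v[1L] + dc * v[2L]) / len2, 0), 1) else 0
  dist <- sqrt((dr - t * v[1L])^2 + (dc - t * v[2L])^2)
  contrib <- amp * exp(-dist^2 / (2 * width^2))
  sub <- env$fil[rr, cc]
  env$fil[rr, cc] <- pmax(sub, contrib)
  ang <- wrapAxial(atan2(v[1L], v[2L]))
  hit <- dist <= 1 & dist < env$bestD[rr, cc]
  if (any(hit)) {
    bd <- env$bestD[rr, cc]; or <- env$orient[rr, cc]
    bd[hit] <- dist[hit]; or[hit] <- ang
    env$bestD[rr, cc] <- bd; env$orient[rr, cc] <- or
  }
  invisible()
}

# Distance from `origin` to the mask boundary along direction theta.
rayExtent <- function(mask, origin, theta, step = 0.5) {
  d <- c(sin(theta), cos(theta))
  tmax <- sqrt(sum(dim(mask)^2))
  t <- seq(step, tmax, by = step)
  rows <- as.integer(round(origin[1L] + t * d[1L]))
  cols <- as.integer(round(origin[2L] + t * d[2L]))
  inside <- rows >= 1 & rows <= nrow(mask) & cols >= 1 & cols <= ncol(mask)
  inside[inside] <- mask[cbind(rows[inside], cols[inside])]
  out <- which(!inside)
  if (!length(out)) tmax else t[out[1L]] - step
}

#' Render a synthetic filament (tubulin-like) cell image
#'
#' Draws \code{nFilaments} straight anti-aliased segments inside the
#' footprint. Each filament is, independently with probability
#' \code{radialityAlpha}, a *radial* segment running from near the
#' organizing centre out towards the boundary at a uniformly random polar
#' angle, and otherwise a short *tangential* chord (length <= 15 px)
#' perpendicular to the local radius at a random interior point. Straight
#' segments make the drawn orientation an exact analytic ground truth. The
#' cell interior carries a uniform cytoplasmic level above background and
#' strictly below the filament intensity; Gaussian noise of sd
#' \code{noiseSigma} is added last and intensities clamped at 0.
#'
#' All randomness flows through one seeded generator per call (the global
#' RNG state is untouched), so identical specs give bit-identical images.
#'
#' @param spec a [SyntheticCellSpec-class].
#' @return List with \code{image} (a [ChannelImage-class]) and \code{truth}
#'   (a [GroundTruth-class]: footprint mask, drawn per-pixel axial
#'   orientation, organizing-centre position, drawn-pixel raster).
#' @examples
#' sim <- makeFilamentCell(syntheticCellSpec(radialityAlpha = 0, seed = 3))
#' sim$image
#' @export
makeFilamentCell <- function(spec) {
  validObject(spec)
  withr::with_seed(spec@seed, {
    phase <- if (spec@lobes > 0L) stats::runif(1, 0, 2 * pi) else 0
    fp <- footprintMask(spec@semiAxes, spec@epsilon, spec@lobes, phase)
    mask <- fp$mask
    oc <- fp$center + spec@centerOffsetPx
    ocr <- as.integer(round(oc[1L])); occ <- as.integer(round(oc[2L]))
    if (ocr < 1L || occ < 1L || ocr > nrow(mask) || occ > ncol(mask) ||
        !mask[ocr, occ])
      stop("organizing centre falls outside the footprint")

    env <- new.env()
    env$fil <- matrix(0, nrow(mask), ncol(mask))
    env$bestD <- matrix(Inf, nrow(mask), ncol(mask))
    env$orient <- matrix(NA_real_, nrow(mask), ncol(mask))

    for (f in seq_len(spec@nFilaments)) {
      radial <- stats::runif(1) < spec@radialityAlpha
      theta <- stats::runif(1, 0, 2 * pi)
      if (radial) {
        ext <- rayExtent(mask, oc, theta)
        d <- c(sin(theta), cos(theta))
        p0 <- oc + 2 * d
        p1 <- oc + max(3, 0.95 * ext) * d
        drawSegment(env, p0, p1, amp = 80)
      } else {
        ext <- rayExtent(mask, oc, theta)
        u <- stats::runif(1, 0.15, 0.9)
        q <- oc + u * ext * c(sin(theta), cos(theta))
        perp <- c(cos(theta), -sin(theta))
        h <- min(4, 0.45 * ext)
        drawSegment(env, q - h * perp, q + h * perp, amp = 80)
      }
    }

    px <- 10 + 90 * mask + env$fil
    if (spec@noiseSigma > 0)
      px <- px + stats::rnorm(length(px), 0, spec@noiseSigma)
    px <- pmax(px, 0)

    drawn <- is.finite(env$orient) & mask
    orient <- env$orient
    orient[!drawn] <- NA_real_
    list(
      image = ChannelImage(px, spec@pixelSizeUm, "tubulin"),
      truth = new("GroundTruth", mask = mask, orientation = orient,
                  centrosome = as.numeric(oc), drawnPixels = drawn)
    )
  })
}

#' Render a synthetic T cell-target conjugate (three channels)
#'
#' Emulates the stainings used for synapse-geometry measurements: a
#' cell-shaped "CD8" channel (uniform interior above background), an
#' "F-actin" channel with a bright annulus at the mask boundary, and a
#' "pericentrin" channel containing a single Gaussian punctum (sd 2 px) at
#' the centrosome position, placed at \code{centrosomeOffsetPx} from the
#' synapse centre. Both points must fall inside the footprint.
#'
#' @param centrosomeOffsetPx \code{(row, col)} offset of the centrosome
#'   from the synapse centre, in pixels.
#' @param synapseCenterPx \code{(row, col)} synapse-centre position in
#'   image coordinates; defaults to the boundary point east of the
#'   footprint centre.
#' @param spec a [SyntheticCellSpec-class] providing footprint, noise and
#'   seed.
#' @return List with [ChannelImage-class] elements \code{cd8},
#'   \code{factin}, \code{pericentrin}, the footprint \code{mask}, and the
#'   ground-truth \code{centrosome} and \code{synapseCenter} positions.
#' @export
makeConjugateImage <- function(centrosomeOffsetPx, synapseCenterPx = NULL,
                               spec = syntheticCellSpec()) {
  validObject(spec)
  withr::with_seed(spec@seed, {
    phase <- if (spec@lobes > 0L) stats::runif(1, 0, 2 * pi) else 0
    fp <- footprintMask(spec@semiAxes, spec@epsilon, spec@lobes, phase)
    mask <- fp$mask
    ctr <- fp$center
    if (is.null(synapseCenterPx)) {
      ext <- rayExtent(mask, ctr, 0)
      synapseCenterPx <- ctr + c(0, ext - 1)
    }
    centrosome <- synapseCenterPx + centrosomeOffsetPx
    inMask <- function(p) {
      r <- as.integer(round(p[1L])); c <- as.integer(round(p[2L]))
      r >= 1L && c >= 1L && r <= nrow(mask) && c <= ncol(mask) && mask[r, c]
    }
    if (!inMask(synapseCenterPx)) stop("synapse centre outside footprint")
    if (!inMask(centrosome)) stop("centrosome outside footprint")

    nr <- nrow(mask); nc <- ncol(mask)
    dr <- matrix(seq_len(nr) - ctr[1L], nr, nc)
    dc <- matrix(seq_len(nc) - ctr[2L], nr, nc, byrow = TRUE)
    theta <- atan2(dr, dc)
    R <- footprintRadius(theta, spec@semiAxes, spec@epsilon, spec@lobes, phase)
    rad <- sqrt(dr^2 + dc^2)

    noisy <- function(base) {
      if (spec@noiseSigma > 0)
        base <- base + stats::rnorm(length(base), 0, spec@noiseSigma)
      pmax(base, 0)
    }
    cd8 <- noisy(10 + 120 * mask)
    ring <- 150 * exp(-(rad - R)^2 / (2 * 3^2))  # ~0.6 um ring at 0.2 um/px
    factin <- noisy(10 + 15 * mask + ring)
    pr <- matrix(seq_len(nr) - centrosome[1L], nr, nc)
    pc <- matrix(seq_len(nc) - centrosome[2L], nr, nc, byrow = TRUE)
    punctum <- 200 * exp(-(pr^2 + pc^2) / (2 * 2^2))
    pericentrin <- noisy(10 + punctum)

    list(
      cd8 = ChannelImage(cd8, spec@pixelSizeUm, "cd8"),
      factin = ChannelImage(factin, spec@pixelSizeUm, "factin"),
      pericentrin = ChannelImage(pericentrin, spec@pixelSizeUm, "pericentrin"),
      mask = mask,
      centrosome = as.numeric(centrosome),
      synapseCenter = as.numeric(synapseCenterPx)
    )
  })
}
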