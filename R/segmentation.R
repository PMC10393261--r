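#' Build a CellMask from a binary raster
#'
#' Computes the filled convex hull and the hull's filled-region centre of
#' mass for a given single-cell foreground. Used internally by
#' [segmentCell()] and directly useful when ground-truth masks are
#' available.
#'
#' @param mask logical matrix with one cell's foreground.
#' @return A [CellMask-class].
#' @export
cellMaskFromBinary <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  poly <- hullPolygon(mask)
  if (nrow(poly) < 3L)
    stop("degenerate mask: convex hull is collinear")
  hull <- fillPolygon(poly, dim(mask)) | mask
  hp <- which(hull, arr.ind = TRUE)
  com <- c(mean(hp[, 1L]), mean(hp[, 2L]))
  new("CellMask", mask = mask, hull = hull, centerOfMass = com,
      areaPx = sum(mask))
}

#' Segment one cell by global Otsu thresholding
#'
#' Applies Otsu's threshold to the raw (unsmoothed) intensity raster,
#' removes 8-connected components smaller than \code{minAreaPx}, keeps the
#' largest surviving component, and derives the convex hull and its filled
#' centroid — the cell centre used by all radial constructs.
#'
#' Because Otsu picks a threshold between the intensity populations, the
#' segmentation is invariant to multiplying all intensities by a positive
#' constant.
#'
#' @param image a [ChannelImage-class] with at least two distinct values.
#' @param minAreaPx smallest component (in pixels) kept; default 100.
#' @return A [CellMask-class].
#' @examples
#' px <- matrix(10, 64, 64)
#' px[20:45, 20:45] <- 200
#' segmentCell(ChannelImage(px, 0.2))
#' @export
segmentCell <- function(image, minAreaPx = 100L) {
  px <- pixelData(image)
  rng <- range(px)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold undefined")
  th <- EBImage::otsu(px, range = rng, levels = 256L)
  fg <- px > th
  lab <- labelComponents8(fg)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minAreaPx)
  if (!length(keep))
    stop("no cell found: no connected component of at least ",
         minAreaPx, " px")
  best <- keep[which.max(sizes[keep])]
  cellMaskFromBinary(lab == best)
}

#' Radial and circular unit vector fields around the cell centre
#'
#' At every hull pixel p (excluding a 1-px disk at the centre, where the
#' direction is undefined) the radial field is the unit vector from the
#' hull centroid to p and the circular field is the radial field rotated by
#' +90 degrees (counter-clockwise in row-down coordinates; the sign is
#' irrelevant downstream because DoR takes absolute dot products).
#'
#' @param cell a [CellMask-class].
#' @return List with numeric matrices \code{radialRow}, \code{radialCol},
#'   \code{circularRow}, \code{circularCol} (NA outside the domain) and a
#'   logical \code{domain} raster.
#' @export
radialCircularFields <- function(cell) {
  hull <- hullMask(cell)
  com <- centerOfMass(cell)
  nr <- nrow(hull); nc <- ncol(hull)
  dr <- matrix(seq_len(nr) - com[1L], nr, nc)
  dc <- matrix(seq_len(nc) - com[2L], nr, nc, byrow = TRUE)
  dist <- sqrt(dr^2 + dc^2)
  domain <- hull & dist > 1
  radialRow <- ifelse(domain, dr / dist, NA_real_)
  radialCol <- ifelse(domain, dc / dist, NA_real_)
  list(radialRow = radialRow, radialCol = radialCol,
       circularRow = -radialCol, circularCol = radialRow,
       domain = domain)
}
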