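#' @import methods
NULL

#' ChannelImage: a single-channel fluorescence image plane
#'
#' The basic unit every stage of the pipeline consumes: a 2D non-negative
#' intensity raster together with its physical pixel size. Pixel values are
#' stored as-is — integer camera counts are converted to doubles without any
#' rescaling, so intensity thresholds (Otsu) operate on the native scale.
#'
#' Coordinates are 1-based \code{(row, col)} matrix indices with the row axis
#' pointing down; physical distances are pixel displacements multiplied by
#' \code{pixelSizeUm}.
#'
#' @slot pixels numeric matrix of intensities (finite, \eqn{\ge 0}), at least
#'   8 x 8.
#' @slot pixelSizeUm physical size of one pixel in micrometres (> 0).
#' @slot channelName free-text stain label, e.g. \code{"tubulin"}.
#'
#' @seealso [ChannelImage()] for the constructor, [readChannelImage()].
#' @exportClass ChannelImage
setClass("ChannelImage",
  representation(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    channelName = "character"
  )
)

setValidity("ChannelImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 8L || ncol(px) < 8L)
    return("raster must have at least 8 rows and 8 columns")
  if (any(!is.finite(px))) return("all intensities must be finite")
  if (any(px < 0)) return("all intensities must be >= 0")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (length(object@channelName) != 1L)
    return("channelName must be a single string")
  TRUE
})

#' Construct a ChannelImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSizeUm pixel size in micrometres (> 0).
#' @param channelName stain label.
#' @return A [ChannelImage-class] object.
#' @examples
#' img <- ChannelImage(matrix(runif(64 * 64), 64), pixelSizeUm = 0.2)
#' pixelSizeUm(img)
#' @export
ChannelImage <- function(pixels, pixelSizeUm, channelName = "channel") {
  new("ChannelImage", pixels = unname(as.matrix(pixels)) * 1.0,
      pixelSizeUm = as.numeric(pixelSizeUm),
      channelName = as.character(channelName))
}

#' ImageStack: an ordered set of confocal sections
#'
#' Holds the optical sections of one z-stack, all with identical raster
#' shape, plus the axial spacing and lateral pixel size. The stack exists
#' only to be reduced to a plane by [maxProject()].
#'
#' @slot slices list of numeric matrices, all the same dimension.
#' @slot zStepUm axial spacing between sections in micrometres (> 0).
#' @slot pixelSizeUm lateral pixel size in micrometres, inherited by
#'   projections.
#' @exportClass ImageStack
setClass("ImageStack",
  representation(slices = "list", zStepUm = "numeric", pixelSizeUm = "numeric")
)

setValidity("ImageStack", function(object) {
  sl <- object@slices
  if (length(sl) < 1L) return("stack must contain at least one slice")
  d <- dim(sl[[1L]])
  for (s in sl) {
    if (!is.matrix(s) || !is.numeric(s)) return("slices must be numeric matrices")
    if (!identical(dim(s), d)) return("all slices must have the same shape")
  }
  if (object@zStepUm <= 0) return("zStepUm must be > 0")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  TRUE
})

#' Construct an ImageStack
#' @param slices list of numeric matrices (identical shapes).
#' @param zStepUm axial spacing in micrometres.
#' @param pixelSizeUm lateral pixel size in micrometres.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(slices, zStepUm = 0.2, pixelSizeUm = 0.1) {
  new("ImageStack", slices = lapply(slices, function(s) unname(as.matrix(s)) * 1.0),
      zStepUm = as.numeric(zStepUm), pixelSizeUm = as.numeric(pixelSizeUm))
}

#' CellMask: single-cell segmentation mask with hull and centre
#'
#' Product of [segmentCell()]: the binary foreground of one cell (a single
#' 8-connected component), the filled convex hull of that mask, and the
#' centre of mass of the hull's filled region, which every radial construct
#' downstream treats as the cell centre.
#'
#' @slot mask logical matrix, the cell foreground.
#' @slot hull logical matrix, filled convex hull of \code{mask}
#'   (\code{mask} is a subset of \code{hull}).
#' @slot centerOfMass numeric length-2 \code{(row, col)} centroid of the
#'   filled hull.
#' @slot areaPx integer, number of foreground pixels.
#' @seealso [segmentCell()], [cellMaskFromBinary()]
#' @exportClass CellMask
setClass("CellMask",
  representation(
    mask = "matrix",
    hull = "matrix",
    centerOfMass = "numeric",
    areaPx = "integer"
  )
)

setValidity("CellMask", function(object) {
  if (!is.logical(object@mask) || !is.logical(object@hull))
    return("mask and hull must be logical matrices")
  if (!identical(dim(object@mask), dim(object@hull)))
    return("mask and hull must have the same shape")
  if (any(object@mask & !object@hull))
    return("mask must be contained in hull")
  if (object@areaPx != sum(object@mask))
    return("areaPx must equal the number of mask pixels")
  cm <- object@centerOfMass
  if (length(cm) != 2L || any(!is.finite(cm)))
    return("centerOfMass must be finite (row, col)")
  r <- as.integer(round(cm[1L])); c <- as.integer(round(cm[2L]))
  if (r < 1L || r > nrow(object@hull) || c < 1L || c > ncol(object@hull) ||
      !object@hull[r, c])
    return("centerOfMass must lie inside the hull")
  TRUE
})

#' OrientationField: per-pixel axial filament orientation
#'
#' Output of the structure-tensor step: the dominant local orientation
#' (axial, i.e. defined modulo \eqn{\pi}) of the filament signal at each
#' pixel, a coherence score in [0, 1] measuring how anisotropic the local
#' gradient distribution is, and a validity raster restricting the field to
#' hull pixels at or above the requested coherence.
#'
#' Angles are measured from the column axis towards the row axis (so
#' horizontal stripes have angle 0) and are \code{NA} outside \code{valid}.
#'
#' @slot angle numeric matrix of axial angles in \eqn{[0, \pi)}; \code{NA}
#'   where not valid.
#' @slot coherence numeric matrix in [0, 1]; 0 where the tensor vanishes.
#' @slot valid logical matrix: pixels where the orientation is defined.
#' @seealso [orientationField()]
#' @exportClass OrientationField
setClass("OrientationField",
  representation(angle = "matrix", coherence = "matrix", valid = "matrix")
)

setValidity("OrientationField", function(object) {
  if (!identical(dim(object@angle), dim(object@coherence)) ||
      !identical(dim(object@angle), dim(object@valid)))
    return("angle, coherence and valid must share one raster shape")
  if (!is.logical(object@valid)) return("valid must be logical")
  a <- object@angle[object@valid]
  if (any(!is.finite(a))) return("angle must be finite on valid pixels")
  if (any(a < 0 | a >= pi)) return("angles must lie in [0, pi)")
  if (any(is.finite(object@angle) & !object@valid))
    return("angle must be NA outside valid")
  co <- object@coherence
  if (any(is.finite(co) & (co < -1e-9 | co > 1 + 1e-9)))
    return("coherence must lie in [0, 1]")
  TRUE
})

#' EFDContour: elliptical Fourier descriptor of a closed contour
#'
#' Kuhl-Giardina harmonic representation of the convex-hull boundary. The
#' first harmonic is the best-fitting ellipse; higher harmonics add detail.
#' Intermediate contours used for radial sectioning are uniform scalings of
#' this descriptor about the cell centre (\code{scaleFraction} 1 denotes the
#' outer hull contour).
#'
#' @slot coefficients numeric matrix with one row per harmonic and columns
#'   \code{a, b} (column-coordinate cosine/sine) and \code{c, d}
#'   (row-coordinate cosine/sine).
#' @slot locus numeric length-2 \code{(row, col)} DC offset of the contour.
#' @slot scaleFraction scale relative to the outer contour, in (0, 1].
#' @seealso [fitHullEFD()], [efdEvaluate()]
#' @exportClass EFDContour
setClass("EFDContour",
  representation(coefficients = "matrix", locus = "numeric",
                 scaleFraction = "numeric")
)

setValidity("EFDContour", function(object) {
  if (ncol(object@coefficients) != 4L)
    return("coefficients must have four columns (a, b, c, d)")
  if (length(object@locus) != 2L) return("locus must be (row, col)")
  sf <- object@scaleFraction
  if (length(sf) != 1L || sf <= 0 || sf > 1)
    return("scaleFraction must lie in (0, 1]")
  TRUE
})

#' RadialSectionMap: annular sections between intermediate contours
#'
#' Assigns every hull pixel (outside a 1-px disk at the centre) to exactly
#' one of K concentric sections bounded by uniformly scaled copies of the
#' outer hull contour. Section k lies between contours (k-1)/K and k/K of
#' the outer contour; a pixel exactly on contour k belongs to section k.
#'
#' @slot sectionIndex integer matrix in \code{1..K}, \code{NA} outside the
#'   hull or inside the excluded centre disk.
#' @slot K number of sections.
#' @slot relativeDistance numeric length-K: the relative radial distance
#'   label of each section (the section index, in contour-spacing units).
#' @seealso [radialSections()]
#' @exportClass RadialSectionMap
setClass("RadialSectionMap",
  representation(sectionIndex = "matrix", K = "integer",
                 relativeDistance = "numeric")
)

setValidity("RadialSectionMap", function(object) {
  K <- object@K
  if (K < 2L) return("K must be >= 2")
  si <- object@sectionIndex
  v <- si[!is.na(si)]
  if (length(v) && (min(v) < 1L || max(v) > K))
    return("section indices must lie in 1..K")
  if (length(object@relativeDistance) != K)
    return("relativeDistance must have one entry per section")
  TRUE
})

#' DoRProfile: Degree of Radiality per radial section
#'
#' One record per radial section of a cell: the section's relative radial
#' distance from the cell centre, the DoR value (ratio of summed absolute
#' dot products of the filament orientation field with the radial versus
#' the circular unit field) and the number of valid orientation pixels that
#' contributed. A section with no valid pixels carries \code{nPixels = 0}
#' and \code{NA} DoR.
#'
#' @slot cellId cell identifier.
#' @slot relativeDistance numeric vector of section distances.
#' @slot dor numeric vector of DoR values (\eqn{\ge 0}).
#' @slot nPixels integer vector of contributing pixel counts.
#' @seealso [degreeOfRadiality()], [dorAt()]
#' @exportClass DoRProfile
setClass("DoRProfile",
  representation(cellId = "character", relativeDistance = "numeric",
                 dor = "numeric", nPixels = "integer")
)

setValidity("DoRProfile", function(object) {
  n <- length(object@relativeDistance)
  if (length(object@dor) != n || length(object@nPixels) != n)
    return("relativeDistance, dor and nPixels must have equal length")
  ok <- object@nPixels > 0L
  if (any(!is.finite(object@dor[ok])))
    return("dor must be finite for populated sections")
  if (any(object@dor[ok] < 0)) return("dor must be >= 0")
  TRUE
})

#' SyntheticCellSpec: parameters of one simulated cell image
#'
#' Declares everything the filament-cell generator needs: the elliptical
#' footprint and its boundary perturbation, the radial-versus-tangential
#' mixing of the filament network, the offset of the organizing centre
#' (centrosome) from the footprint centre, the noise level, and the seed.
#' Defaults emulate a spread T cell imaged at high magnification: a
#' mildly elliptical ~10 micrometre footprint at 0.2 um/px with a slightly
#' off-centre organizing centre.
#'
#' @slot semiAxes numeric length-2 ellipse semi-axes in pixels (each >= 4).
#' @slot epsilon boundary-perturbation amplitude in [0, 1): boundary radius
#'   is the ellipse radius times \code{1 + epsilon * cos(lobes * theta)}.
#' @slot lobes integer number of boundary lobes (>= 0).
#' @slot radialityAlpha probability in [0, 1] that a filament is radial
#'   (1 = purely radial network, 0 = purely tangential).
#' @slot nFilaments number of filaments to draw (> 0).
#' @slot centerOffsetPx numeric length-2 \code{(row, col)} offset of the
#'   organizing centre from the footprint centre, in pixels.
#' @slot noiseSigma additive Gaussian noise standard deviation (>= 0).
#' @slot pixelSizeUm pixel size in micrometres.
#' @slot seed integer RNG seed; identical specs render identical images.
#' @seealso [syntheticCellSpec()], [makeFilamentCell()]
#' @exportClass SyntheticCellSpec
setClass("SyntheticCellSpec",
  representation(
    semiAxes = "numeric", epsilon = "numeric", lobes = "integer",
    radialityAlpha = "numeric", nFilaments = "integer",
    centerOffsetPx = "numeric", noiseSigma = "numeric",
    pixelSizeUm = "numeric", seed = "integer"
  )
)

setValidity("SyntheticCellSpec", function(object) {
  if (length(object@semiAxes) != 2L || any(object@semiAxes < 4))
    return("semiAxes must be two values >= 4 px")
  if (object@epsilon < 0 || object@epsilon >= 1)
    return("epsilon must lie in [0, 1)")
  if (object@lobes < 0L) return("lobes must be >= 0")
  if (object@radialityAlpha < 0 || object@radialityAlpha > 1)
    return("radialityAlpha must lie in [0, 1]")
  if (object@nFilaments < 1L) return("nFilaments must be > 0")
  if (length(object@centerOffsetPx) != 2L)
    return("centerOffsetPx must be (row, col)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@pixelSizeUm <= 0) return("pixelSizeUm must be > 0")
  TRUE
})

#' GroundTruth: known answers for one synthetic cell
#'
#' Rendered alongside each synthetic image so downstream estimates can be
#' compared against construction: the footprint mask, the axial orientation
#' actually drawn at each filament pixel, the organizing-centre
#' (centrosome) position, and the raster of pixels where an orientation was
#' drawn. Orientation is defined exactly where \code{drawnPixels} is true,
#' and drawn pixels are a subset of the mask.
#'
#' @slot mask logical footprint raster.
#' @slot orientation numeric matrix of drawn axial angles in
#'   \eqn{[0, \pi)}; \code{NA} where nothing was drawn.
#' @slot centrosome numeric \code{(row, col)} organizing-centre position.
#' @slot drawnPixels logical raster marking where orientation is defined.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(mask = "matrix", orientation = "matrix",
                 centrosome = "numeric", drawnPixels = "matrix")
)

setValidity("GroundTruth", function(object) {
  if (!identical(dim(object@mask), dim(object@orientation)) ||
      !identical(dim(object@mask), dim(object@drawnPixels)))
    return("mask, orientation and drawnPixels must share one shape")
  if (any(object@drawnPixels & !object@mask))
    return("drawnPixels must be a subset of the mask")
  if (any(is.finite(object@orientation) != object@drawnPixels))
    return("orientation must be defined exactly on drawnPixels")
  TRUE
})
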