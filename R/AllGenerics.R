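#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The slot value: a matrix, a number or a vector depending on the
#'   accessor.
#' @name accessors
#' @examples
#' img <- ChannelImage(matrix(1, 16, 16), 0.1, "tubulin")
#' dim(pixelData(img)); pixelSizeUm(img); channelName(img)
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(x) standardGeneric("pixelData"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(x) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("hullMask", function(x) standardGeneric("hullMask"))
#' @rdname accessors
#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))
#' @rdname accessors
#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))
#' @rdname accessors
#' @export
setGeneric("orientationAngle", function(x) standardGeneric("orientationAngle"))
#' @rdname accessors
#' @export
setGeneric("coherence", function(x) standardGeneric("coherence"))
#' @rdname accessors
#' @export
setGeneric("validPixels", function(x) standardGeneric("validPixels"))
#' @rdname accessors
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))
#' @rdname accessors
#' @export
setGeneric("nSections", function(x) standardGeneric("nSections"))

#' @rdname accessors
#' @export
setMethod("pixelData", "ChannelImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "ChannelImage", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "ImageStack", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("channelName", "ChannelImage", function(x) x@channelName)
#' @rdname accessors
#' @export
setMethod("cellMask", "CellMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("cellMask", "GroundTruth", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("hullMask", "CellMask", function(x) x@hull)
#' @rdname accessors
#' @export
setMethod("centerOfMass", "CellMask", function(x) x@centerOfMass)
#' @rdname accessors
#' @export
setMethod("areaPx", "CellMask", function(x) x@areaPx)
#' @rdname accessors
#' @export
setMethod("orientationAngle", "OrientationField", function(x) x@angle)
#' @rdname accessors
#' @export
setMethod("orientationAngle", "GroundTruth", function(x) x@orientation)
#' @rdname accessors
#' @export
setMethod("coherence", "OrientationField", function(x) x@coherence)
#' @rdname accessors
#' @export
setMethod("validPixels", "OrientationField", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validPixels", "GroundTruth", function(x) x@drawnPixels)
#' @rdname accessors
#' @export
setMethod("sectionIndex", "RadialSectionMap", function(x) x@sectionIndex)
#' @rdname accessors
#' @export
setMethod("nSections", "RadialSectionMap", function(x) as.integer(x@K))

#' Tabular view of a DoR profile
#'
#' @param x a [DoRProfile-class].
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame with columns \code{cell_id}, \code{relative_distance},
#'   \code{dor}, \code{n_pixels}.
#' @export
as.data.frame.DoRProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(cell_id = x@cellId,
             relative_distance = x@relativeDistance,
             dor = x@dor,
             n_pixels = x@nPixels,
             stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage '%s': %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              object@channelName, nrow(object@pixels), ncol(object@pixels),
              object@pixelSizeUm, min(object@pixels), max(object@pixels)))
})

#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf("ImageStack: %d slices of %d x %d px, z-step %.3g um\n",
              length(object@slices), d[1L], d[2L], object@zStepUm))
})

#' @export
setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %d px cell on %d x %d raster, hull centre (%.1f, %.1f)\n",
              object@areaPx, nrow(object@mask), ncol(object@mask),
              object@centerOfMass[1L], object@centerOfMass[2L]))
})

#' @export
setMethod("show", "OrientationField", function(object) {
  cat(sprintf("OrientationField: %d valid px (mean coherence %.3f)\n",
              sum(object@valid),
              mean(object@coherence[object@valid])))
})

#' @export
setMethod("show", "RadialSectionMap", function(object) {
  cat(sprintf("RadialSectionMap: K = %d sections over %d px\n",
              object@K, sum(!is.na(object@sectionIndex))))
})

#' @export
setMethod("show", "DoRProfile", function(object) {
  cat(sprintf("DoRProfile for '%s':\n", object@cellId))
  print(as.data.frame(object), row.names = FALSE)
})

#' @export
setMethod("show", "SyntheticCellSpec", function(object) {
  cat(sprintf(paste0("SyntheticCellSpec: semi-axes (%g, %g) px, eps %.2f x %d lobes, ",
                     "alpha %.2f, %d filaments, noise %.2f, seed %d\n"),
              object@semiAxes[1L], object@semiAxes[2L], object@epsilon,
              object@lobes, object@radialityAlpha, object@nFilaments,
              object@noiseSigma, object@seed))
})
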