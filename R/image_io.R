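#' Read a single-plane grayscale TIFF as a ChannelImage
#'
#' Pixel values are read natively (\code{as.is}): integer pixel types become
#' doubles without rescaling, so downstream thresholds see camera counts.
#'
#' @param path path to a TIFF file containing exactly one grayscale plane.
#' @param pixelSizeUm physical pixel size in micrometres (> 0).
#' @param channelName stain label stored on the image.
#' @return A [ChannelImage-class].
#' @seealso [writeChannelImage()], [readImageStack()]
#' @export
readChannelImage <- function(path, pixelSizeUm, channelName = "channel") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(planes) != 1L)
    stop("expected a single-plane TIFF, found ", length(planes), " planes")
  px <- planes[[1L]]
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] == 1L) px <- px[, , 1L]
    else stop("expected a grayscale plane, found ", dim(px)[3L], " samples per pixel")
  }
  ChannelImage(px, pixelSizeUm, channelName)
}

#' Write a ChannelImage to TIFF
#'
#' Integer-valued rasters are written as 8/16-bit integer TIFF and round-trip
#' bit-exactly through [readChannelImage()]; non-integer rasters are written
#' as 32-bit float.
#'
#' @param image a [ChannelImage-class].
#' @param path output path.
#' @param bitsPerSample 8 or 16 for integer data (default 16).
#' @return \code{path}, invisibly.
#' @export
writeChannelImage <- function(image, path, bitsPerSample = 16L) {
  px <- pixelData(image)
  if (all(px == round(px))) {
    top <- 2^bitsPerSample - 1
    if (max(px) > top)
      stop("integer intensities exceed ", bitsPerSample, "-bit range")
    tiff::writeTIFF(px / top, path, bits.per.sample = as.integer(bitsPerSample))
  } else {
    tiff::writeTIFF(px / max(px, 1), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read a multi-plane TIFF as an ImageStack
#'
#' @param path path to a TIFF file with one or more planes of equal shape.
#' @param zStepUm axial spacing between planes in micrometres.
#' @param pixelSizeUm lateral pixel size in micrometres.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path, zStepUm, pixelSizeUm) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  ImageStack(planes, zStepUm = zStepUm, pixelSizeUm = pixelSizeUm)
}

#' Maximum-intensity projection of a z-stack
#'
#' Reduces the selected optical sections to one plane by the per-pixel
#' maximum; all downstream metrics are computed on such projections. Which
#' sections to project (e.g. the few at the cell-coverslip contact) is the
#' caller's choice via \code{sliceRange}.
#'
#' @param stack an [ImageStack-class].
#' @param sliceRange inclusive \code{(first, last)} 1-based slice indices;
#'   defaults to the full stack.
#' @param channelName label for the projected image.
#' @return A [ChannelImage-class] with the stack's pixel size.
#' @examples
#' st <- ImageStack(replicate(3, matrix(runif(256), 16), simplify = FALSE))
#' maxProject(st, c(1, 2))
#' @export
maxProject <- function(stack, sliceRange = c(1L, length(stack@slices)),
                       channelName = "projection") {
  n <- length(stack@slices)
  if (length(sliceRange) != 2L) stop("sliceRange must be (first, last)")
  a <- as.integer(sliceRange[1L]); b <- as.integer(sliceRange[2L])
  if (a < 1L || b > n || a > b)
    stop("sliceRange out of bounds for a ", n, "-slice stack")
  proj <- Reduce(pmax, stack@slices[a:b])
  ChannelImage(proj, pixelSizeUm(stack), channelName)
}

#' Read a point-annotation table
#'
#' Loads manually marked points (pericentrin puncta, synapse centres) from a
#' CSV with header \code{image_id,role,row,col}. Coordinates are 1-based
#' pixel positions.
#'
#' @param path CSV path.
#' @return data.frame with columns \code{image_id}, \code{role} (one of
#'   \code{"centrosome"}, \code{"synapse_center"}), \code{row}, \code{col}.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "role", "row", "col")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have header: ", paste(need, collapse = ","))
  bad <- setdiff(unique(df$role), c("centrosome", "synapse_center"))
  if (length(bad))
    stop("unknown annotation role(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$row)) || any(!is.finite(df$col)) ||
      any(df$row < 1) || any(df$col < 1))
    stop("row/col must be finite coordinates >= 1")
  df[need]
}

#' Default analysis configuration
#'
#' All tunable parameters of the pipeline with their defaults, as one list;
#' [readConfig()] overlays a YAML file on top of these.
#'
#' @return Named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    pixel_size_um = 0.2,
    channel_order = c("tubulin", "factin", "cd8", "pericentrin"),
    min_area_px = 100L,
    sigma_px = 1.5,
    coherence_min = 0,
    n_harmonics = 10L,
    n_sections = 4L,
    query_distance = 2,
    angles_deg = c(0, 45, 90, 135),
    welch = FALSE
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys are kept (forward compatibility); known keys override the
#' defaults from [defaultConfig()].
#'
#' @param path YAML file path.
#' @return Named list of parameters.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  utils::modifyList(defaultConfig(), user)
}
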