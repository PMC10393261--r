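#' Assign a centrosome-polarization distance to its reporting bin
#'
#' Bins partition the non-negative axis into "<=1" (distance at most 1 um),
#' "1-3" (more than 1 up to and including 3 um) and ">3" (beyond 3 um).
#' The 1-um boundary is closed on the left bin; the 3-um boundary closed on
#' the middle bin by symmetry.
#'
#' @param distanceUm numeric vector of distances in micrometres (>= 0).
#' @return Character vector of bin labels.
#' @export
distanceBin <- function(distanceUm) {
  if (any(distanceUm < 0)) stop("distances must be >= 0")
  ifelse(distanceUm <= 1, "<=1", ifelse(distanceUm <= 3, "1-3", ">3"))
}

#' Centrosome-to-synapse distance for one cell
#'
#' Euclidean in-plane distance between the annotated pericentrin punctum
#' and the annotated synapse centre, converted to micrometres and binned
#' for reporting. Symmetric in its two points.
#'
#' @param centrosome one annotation row (list or one-row data.frame with
#'   \code{image_id}, \code{row}, \code{col}) marking the centrosome.
#' @param synapseCenter annotation row marking the synapse centre on the
#'   same image.
#' @param pixelSizeUm pixel size in micrometres (> 0).
#' @return One-row data.frame with \code{cell_id}, \code{distance_um},
#'   \code{bin}.
#' @examples
#' a <- list(image_id = "c1", row = 10, col = 10)
#' b <- list(image_id = "c1", row = 10, col = 14)
#' centrosomeDistance(a, b, 0.5)   # 2 um, bin "1-3"
#' @export
centrosomeDistance <- function(centrosome, synapseCenter, pixelSizeUm) {
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  if (!identical(as.character(centrosome$image_id),
                 as.character(synapseCenter$image_id)))
    stop("annotations refer to different images: ",
         centrosome$image_id, " vs ", synapseCenter$image_id)
  d <- sqrt((centrosome$row - synapseCenter$row)^2 +
            (centrosome$col - synapseCenter$col)^2) * pixelSizeUm
  data.frame(cell_id = as.character(centrosome$image_id),
             distance_um = d, bin = distanceBin(d),
             stringsAsFactors = FALSE)
}

#' Batch centrosome distances from an annotation table
#'
#' Pairs the \code{centrosome} and \code{synapse_center} annotations of
#' each image and measures all distances.
#'
#' @param annotations data.frame from [readAnnotations()].
#' @param pixelSizeUm pixel size in micrometres.
#' @return data.frame of [centrosomeDistance()] rows, one per image with
#'   both annotations.
#' @export
centrosomeDistances <- function(annotations, pixelSizeUm) {
  ids <- unique(annotations$image_id)
  rows <- lapply(ids, function(id) {
    sub <- annotations[annotations$image_id == id, ]
    cen <- sub[sub$role == "centrosome", ]
    syn <- sub[sub$role == "synapse_center", ]
    if (nrow(cen) != 1L || nrow(syn) != 1L) return(NULL)
    centrosomeDistance(cen, syn, pixelSizeUm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no image with both a centrosome and a synapse_center annotation")
  out
}

#' Locate the pericentrin punctum inside the cell
#'
#' Position of the maximum of the Gaussian-smoothed (sd 2 px) channel
#' within the cell mask. If several pixels tie at the maximum, the
#' lexicographically smallest \code{(row, col)} is returned with a warning.
#'
#' @param image pericentrin [ChannelImage-class].
#' @param cell a [CellMask-class] on the same raster.
#' @param imageId identifier recorded on the annotation.
#' @return One-row data.frame annotation (\code{image_id}, \code{role},
#'   \code{row}, \code{col}).
#' @export
detectPunctum <- function(image, cell, imageId = "cell") {
  px <- pixelData(image)
  mask <- cellMask(cell)
  if (!identical(dim(px), dim(mask)))
    stop("image and mask rasters differ in shape")
  sm <- gaussianSmooth(px, 2)
  vals <- sm[mask]
  if (diff(range(vals)) == 0)
    stop("constant channel inside the mask: no punctum")
  sm[!mask] <- -Inf
  hits <- which(sm == max(sm), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  if (nrow(hits) > 1L)
    warning("multiple maxima; returning the lexicographically smallest")
  data.frame(image_id = as.character(imageId), role = "centrosome",
             row = hits[1L, 1L], col = hits[1L, 2L],
             stringsAsFactors = FALSE)
}

#' F-actin intensity profiles along lines through the cell centre
#'
#' For each requested angle, samples the bilinearly interpolated intensity
#' at 0.5-px steps along the full-width line through the hull centroid,
#' trimmed to the hull extent so the profile spans the whole cell and
#' nothing beyond. Positions are signed distances from the centre in
#' micrometres. The default four angles (0, 45, 90, 135 degrees) match
#' inspecting a synapse from several directions.
#'
#' @param image F-actin [ChannelImage-class].
#' @param cell a [CellMask-class] on the same raster.
#' @param anglesDeg numeric vector of line angles in degrees (non-empty);
#'   0 is horizontal (along columns).
#' @param cellId identifier recorded on each profile.
#' @return data.frame with columns \code{cell_id}, \code{angle_deg},
#'   \code{position_um}, \code{intensity}.
#' @export
factinProfiles <- function(image, cell, anglesDeg = c(0, 45, 90, 135),
                           cellId = "cell") {
  if (!length(anglesDeg)) stop("anglesDeg must be non-empty")
  px <- pixelData(image)
  hull <- hullMask(cell)
  if (!identical(dim(px), dim(hull)))
    stop("image and mask rasters differ in shape")
  com <- centerOfMass(cell)
  tmax <- sqrt(sum(dim(px)^2)) / 2
  t <- seq(-tmax, tmax, by = 0.5)
  out <- lapply(anglesDeg, function(a) {
    th <- a * pi / 180
    rows <- com[1L] + t * sin(th)
    cols <- com[2L] + t * cos(th)
    ri <- pmin(pmax(as.integer(round(rows)), 1L), nrow(hull))
    ci <- pmin(pmax(as.integer(round(cols)), 1L), ncol(hull))
    inHull <- hull[cbind(ri, ci)] &
      rows >= 1 & rows <= nrow(hull) & cols >= 1 & cols <= ncol(hull)
    span <- range(which(inHull))
    # a 4-px margin past the hull keeps boundary-localized signal (e.g. the
    # synaptic actin ring) fully inside the profile
    sel <- max(1L, span[1L] - 8L):min(length(t), span[2L] + 8L)
    data.frame(cell_id = as.character(cellId), angle_deg = a,
               position_um = t[sel] * pixelSizeUm(image),
               intensity = bilinearSample(px, rows[sel], cols[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
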