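#' Segment nuclei from a Hoechst/DAPI channel
#'
#' Builds the primary (nuclear) regions of interest: the counterstain
#' channel is median-filtered, thresholded (Otsu by default), holes are
#' filled, and touching nuclei are split by a watershed on the distance
#' transform. Objects touching the image border are excluded by default
#' because their secondary cytoplasmic region would be truncated.
#'
#' @param hoechst 2-D nonnegative intensity matrix (nuclear counterstain)
#' @param thresholdMethod \code{"otsu"} (parameter-free, the default) or
#'   \code{"fixed"}
#' @param threshold fixed intensity threshold, required when
#'   \code{thresholdMethod = "fixed"}
#' @param smoothSize median filter radius, px (0 disables smoothing)
#' @param minDistance watershed merge tolerance in distance-map units
#'   (px); peaks closer than this in depth are merged
#' @param excludeBorder drop objects touching the image border
#' @return a \linkS4class{LabeledMask}; its object table records label,
#'   centroid, area and mean counterstain intensity per nucleus. An
#'   all-zero image yields an empty mask.
#' @examples
#' ft <- generateField(fieldSpec(nCells = 30, seed = 3))
#' m <- segmentNuclei(getChannel(ft$field, "Hoechst"))
#' nObjects(m)
#' @export
segmentNuclei <- function(hoechst, thresholdMethod = c("otsu", "fixed"),
                          threshold = NULL, smoothSize = 1,
                          minDistance = 1, excludeBorder = TRUE) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!is.matrix(hoechst)) stop("hoechst must be a 2-D matrix")
  if (anyNA(hoechst)) stop("NaN/NA pixels in input")
  if (any(hoechst < 0)) stop("negative pixel intensities")
  hi <- max(hoechst)
  empty <- function() {
    z <- matrix(0L, nrow(hoechst), ncol(hoechst))
    new("LabeledMask", mask = z, objects = .objectStats(z, hoechst))
  }
  if (hi == 0) return(empty())
  x <- EBImage::Image(hoechst / hi)
  if (smoothSize > 0) x <- EBImage::medianFilter(x, smoothSize)
  thr <- if (thresholdMethod == "otsu") EBImage::otsu(x) * hi else {
    if (is.null(threshold)) stop("threshold required for method 'fixed'")
    threshold
  }
  bin <- EBImage::fillHull(x > thr / hi)
  if (!any(bin)) return(empty())
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = minDistance, ext = 1)
  mask <- matrix(as.integer(EBImage::imageData(lab)),
                 nrow(hoechst), ncol(hoechst))
  if (excludeBorder) {
    border <- unique(c(mask[1, ], mask[nrow(mask), ],
                       mask[, 1], mask[, ncol(mask)]))
    border <- border[border > 0]
    if (length(border)) mask[mask %in% border] <- 0L
  }
  keep <- sort(unique(as.vector(mask[mask > 0])))
  mask <- .relabel(mask, keep)$mask
  new("LabeledMask", mask = mask, objects = .objectStats(mask, hoechst))
}

#' Exclude cellular debris from a labelled mask
#'
#' Removes objects failing any of the area or mean-intensity criteria,
#' mirroring the exclusion of cellular debris from per-cell analysis.
#' Remaining objects are relabelled contiguously; the number removed is
#' available via \code{\link{nRemoved}}.
#'
#' @param mask a \linkS4class{LabeledMask}
#' @param minArea,maxArea retained object area bounds, px
#' @param minMeanIntensity minimum mean counterstain intensity
#' @return filtered \linkS4class{LabeledMask}
#' @export
filterDebris <- function(mask, minArea = 10, maxArea = 5000,
                         minMeanIntensity = 0) {
  stopifnot(is(mask, "LabeledMask"))
  if (minArea > maxArea) stop("minArea must be <= maxArea")
  tab <- mask@objects
  if (nrow(tab) == 0) return(mask)
  ok <- tab$area_px >= minArea & tab$area_px <= maxArea &
    tab$mean_intensity >= minMeanIntensity
  keep <- tab$label[ok]
  rl <- .relabel(mask@mask, keep)
  out <- tab[ok, , drop = FALSE]
  out$label <- rl$map[out$label]
  rownames(out) <- NULL
  new("LabeledMask", mask = rl$mask, objects = out,
      removed = as.integer(sum(!ok)))
}

#' Build secondary cytoplasmic regions of interest
#'
#' Expands every nucleus by a fixed-width ring; pixels contested between
#' neighbouring cells are assigned to the nearest nucleus (Voronoi-style
#' partition via seeded propagation), and nuclear pixels are excluded, so
#' cytoplasm regions of distinct cells are disjoint.
#'
#' @param mask a filtered \linkS4class{LabeledMask} of nuclei
#' @param ringWidth ring width in px (> 0)
#' @return a \linkS4class{CellROIs}
#' @export
buildCytoplasmROIs <- function(mask, ringWidth = 4) {
  stopifnot(is(mask, "LabeledMask"))
  if (ringWidth <= 0) stop("ringWidth must be > 0")
  nuc <- mask@mask
  if (max(nuc) == 0)
    return(new("CellROIs", nuclei = nuc, cytoplasm = nuc,
               labels = integer(0)))
  d <- EBImage::distmap(EBImage::Image(1 - (nuc > 0)))
  ring <- EBImage::imageData(d) > 0 & EBImage::imageData(d) <= ringWidth
  flat <- EBImage::Image(matrix(0, nrow(nuc), ncol(nuc)))
  cyto <- EBImage::propagate(flat, seeds = EBImage::Image(nuc),
                             mask = (nuc > 0) | ring, lambda = 1)
  cyto <- matrix(as.integer(EBImage::imageData(cyto)), nrow(nuc), ncol(nuc))
  cyto[nuc > 0] <- 0L
  new("CellROIs", nuclei = nuc, cytoplasm = cyto,
      labels = mask@objects$label)
}
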