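#' Standard hematoxylin/eosin stain vectors
#'
#' The widely used hematoxylin and eosin unit optical-density vectors
#' (columns H, E) for Beer--Lambert colour deconvolution; override per
#' image set if stains were measured.
#'
#' @return 3 x 2 matrix of unit-norm OD vectors (rows R, G, B)
#' @export
heStainVectors <- function() {
  v <- cbind(H = c(0.650, 0.704, 0.286), E = c(0.072, 0.990, 0.105))
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

# transmitted-light convention shared by composition and deconvolution:
# OD = -log10((I + 1) / I0) with I0 = 256 on 8-bit images
.I0 <- 256

#' Compose an RGB image from stain density maps
#'
#' Beer--Lambert forward model: per-pixel optical density is the stain
#' basis times the densities, and the stored 8-bit intensity is
#' \code{round(I0 * 10^(-OD) - 1)} clipped to [0, 255]. Exact inverse of
#' \code{\link{deconvolveHE}} up to rounding.
#'
#' @param densityH,densityE matrices of stain densities (OD units)
#' @param vectors 3 x 2 stain vector matrix
#' @return H x W x 3 integer array (0--255)
#' @export
composeHE <- function(densityH, densityE, vectors = heStainVectors()) {
  stopifnot(identical(dim(densityH), dim(densityE)))
  d <- rbind(as.vector(densityH), as.vector(densityE))
  od <- vectors %*% d # 3 x npix
  img <- round(.I0 * 10^(-od) - 1)
  img <- pmin(pmax(img, 0), 255)
  array(as.integer(t(img)), dim = c(dim(densityH), 3L))
}

#' Beer--Lambert colour deconvolution of an HE image
#'
#' Converts an RGB histology image to per-pixel optical density
#' (\code{OD = -log10((I + 1) / I0)}) and projects it onto the stain
#' basis by least squares, clipping negative densities at 0.
#'
#' @param rgb H x W x 3 array, 8-bit (0--255) or normalized [0, 1]
#' @param vectors 3 x 2 matrix of stain OD vectors (columns H, E); must
#'   not be collinear
#' @return a \linkS4class{StainMaps}
#' @export
deconvolveHE <- function(rgb, vectors = heStainVectors()) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3)
    stop("rgb must be an H x W x 3 array")
  if (max(rgb) <= 1) rgb <- rgb * 255
  if (qr(vectors)$rank < 2) stop("collinear stain vectors")
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  ivec <- t(matrix(rgb[, , 1:3], h * w, 3)) # 3 x npix
  od <- -log10((ivec + 1) / .I0)
  dens <- solve(crossprod(vectors), t(vectors) %*% od) # 2 x npix
  dens <- pmax(dens, 0)
  new("StainMaps", hematoxylin = matrix(dens[1, ], h, w),
      eosin = matrix(dens[2, ], h, w), vectors = vectors)
}

#' Tissue mask from total optical density
#'
#' Pixels whose total stain density exceeds a small floor; excludes
#' unstained glass/background so area fractions are relative to tissue.
#'
#' @param maps a \linkS4class{StainMaps}
#' @param floor minimum total OD for a tissue pixel
#' @return logical matrix
#' @export
tissueMask <- function(maps, floor = 0.15) {
  stopifnot(is(maps, "StainMaps"))
  maps@hematoxylin + maps@eosin > floor
}

#' Per-pixel eosin-over-hematoxylin ratio
#'
#' The HE de-coloration readout of necrosis: the ratio map is computed
#' where hematoxylin density reaches the floor and masked (NA) elsewhere,
#' with the mean ratio over unmasked pixels as summary. A fully masked
#' map carries an undefined (NA) mean.
#'
#' @param maps a \linkS4class{StainMaps}
#' @param hematoxylinFloor minimum hematoxylin density (> 0) for a valid
#'   ratio
#' @return a \linkS4class{NecrosisResult}
#' @export
eosinHematoxylinRatio <- function(maps, hematoxylinFloor = 0.05) {
  stopifnot(is(maps, "StainMaps"))
  if (hematoxylinFloor <= 0) stop("hematoxylinFloor must be > 0")
  ratio <- maps@eosin / maps@hematoxylin
  ratio[maps@hematoxylin < hematoxylinFloor] <- NA_real_
  mr <- if (all(is.na(ratio))) NA_real_ else mean(ratio, na.rm = TRUE)
  new("NecrosisResult", ratioMap = ratio, meanRatio = mr,
      floor = hematoxylinFloor)
}

#' Low-hematoxylin (necrotic) area fraction
#'
#' Fraction of tissue pixels whose hematoxylin density falls below a
#' threshold, the operational measure of necrotic area. The threshold is
#' Otsu's on the hematoxylin histogram within the tissue mask by default,
#' or a fixed value.
#'
#' @param maps a \linkS4class{StainMaps}
#' @param mask logical tissue mask (default \code{\link{tissueMask}})
#' @param thresholdMethod \code{"otsu"} or \code{"fixed"}
#' @param threshold fixed hematoxylin density threshold when
#'   \code{thresholdMethod = "fixed"}
#' @return the area fraction, with the threshold used as attribute
#'   \code{threshold}
#' @export
lowHematoxylinAreaFraction <- function(maps, mask = tissueMask(maps),
                                       thresholdMethod = c("otsu", "fixed"),
                                       threshold = NULL) {
  stopifnot(is(maps, "StainMaps"))
  thresholdMethod <- match.arg(thresholdMethod)
  if (!any(mask)) stop("empty tissue mask")
  hvals <- maps@hematoxylin[mask]
  thr <- if (thresholdMethod == "otsu") {
    hi <- max(hvals)
    if (hi == 0) 0 else {
      m <- matrix(hvals / hi, ncol = 1)
      as.numeric(EBImage::otsu(EBImage::Image(m))) * hi
    }
  } else {
    if (is.null(threshold)) stop("threshold required for method 'fixed'")
    threshold
  }
  structure(mean(hvals < thr), threshold = thr)
}

#' Count leukocyte-like puncta in a tissue region
#'
#' Detects small, strongly hematoxylin-dense blobs (lymphocyte-like
#' infiltrating cells) within a region: the hematoxylin density map is
#' thresholded in OD space (making the count invariant to uniform
#' brightness changes of the RGB image), connected components are
#' labelled, and blobs are counted whose equivalent diameter lies in the
#' given band.
#'
#' @param x a \linkS4class{StainMaps} or an RGB array (deconvolved with
#'   default stain vectors)
#' @param region logical region mask (e.g. the necrotic area)
#' @param minDiameter,maxDiameter equivalent-diameter band, px
#' @param odThreshold hematoxylin density above which a pixel is
#'   punctum-candidate
#' @return the count per view field
#' @export
countLeukocytes <- function(x, region = NULL, minDiameter = 2,
                            maxDiameter = 8, odThreshold = 1.2) {
  if (!is(x, "StainMaps")) x <- deconvolveHE(x)
  if (minDiameter <= 0 || maxDiameter <= minDiameter)
    stop("invalid diameter band")
  hmap <- x@hematoxylin
  if (is.null(region)) region <- matrix(TRUE, nrow(hmap), ncol(hmap))
  if (!any(region)) stop("empty region mask")
  cand <- hmap >= odThreshold & region
  if (!any(cand)) return(0L)
  lab <- EBImage::bwlabel(EBImage::Image(cand))
  area <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  dia <- 2 * sqrt(area / pi)
  sum(dia >= minDiameter & dia <= maxDiameter)
}

#' Percent marker-positive cells in an immunofluorescence field
#'
#' Tissue immunofluorescence readout: nuclei are segmented from the
#' counterstain (DAPI/Hoechst) channel, debris is excluded, and each cell
#' is scored positive when its marker measurement crosses the threshold
#' -- the nuclear mean for markers read in the nucleus (HMGB1 loss,
#' direction \code{"below"}) or the whole-cell mean for cytoplasmic
#' markers (CASP-3a, p-eIF2alpha, CD3, F4/80; direction \code{"above"}).
#'
#' @param field a \linkS4class{FieldImage} whose first channel is the
#'   counterstain and which carries the marker in channel \code{marker}
#' @param markerThreshold calibrated decision threshold (feature units)
#' @param direction \code{"above"} or \code{"below"}
#' @param measure \code{"nuclear"} or \code{"cell"} mean
#' @param counterstain,marker channel names
#' @param minArea,maxArea debris bounds passed to
#'   \code{\link{filterDebris}}
#' @param ringWidth cytoplasm ring width for \code{measure = "cell"}
#' @return list with \code{percent} (NA with \code{flag} when no nuclei
#'   are found), \code{nCells}, \code{positive}, and the per-cell
#'   \code{table}
#' @export
percentPositiveCells <- function(field, markerThreshold,
                                 direction = c("above", "below"),
                                 measure = c("cell", "nuclear"),
                                 counterstain = "Hoechst", marker = "GFP",
                                 minArea = 10, maxArea = 5000,
                                 ringWidth = 4) {
  direction <- match.arg(direction)
  measure <- match.arg(measure)
  stopifnot(is(field, "FieldImage"))
  nuc <- segmentNuclei(getChannel(field, counterstain))
  nuc <- filterDebris(nuc, minArea, maxArea)
  if (nObjects(nuc) == 0)
    return(list(percent = NA_real_, nCells = 0L, positive = NA_integer_,
                table = NULL, flag = "no nuclei found"))
  rois <- buildCytoplasmROIs(nuc, ringWidth)
  ch <- getChannel(field, marker)
  vals <- vapply(rois@labels, function(k) {
    nm <- rois@nuclei == k
    if (measure == "nuclear") nuclearMeanIntensity(ch, nm)
    else cellMeanIntensity(ch, nm, rois@cytoplasm == k)
  }, numeric(1))
  pos <- if (direction == "above") vals > markerThreshold
         else vals < markerThreshold
  list(percent = 100 * mean(pos), nCells = length(vals),
       positive = as.integer(sum(pos)),
       table = data.frame(cell_id = rois@labels, value = vals,
                          positive = pos),
       flag = NA_character_)
}
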