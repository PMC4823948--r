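#' @import methods
NULL

#' FieldImage: one microscopy view field
#'
#' Container for a single acquired view field: a set of named, equally
#' shaped 2-D intensity rasters (one per fluorescence channel, in camera
#' counts) plus well/field metadata. Channels are conventionally named
#' \code{"Hoechst"} (nuclear counterstain), \code{"GFP"} (biosensor or
#' quinacrine) and \code{"PI"} (propidium iodide).
#'
#' @slot channels named list of numeric matrices, all of identical shape
#' @slot well well identifier (e.g. \code{"B03"})
#' @slot field view-field index within the well
#' @export
setClass("FieldImage",
  representation(channels = "list", well = "character", field = "integer"),
  prototype(channels = list(), well = NA_character_, field = NA_integer_))

setValidity("FieldImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("channels must be matrices")
  dims <- vapply(ch, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all channels must have identical dimensions")
  TRUE
})

#' LabeledMask: labelled object raster with per-object table
#'
#' Integer label raster (0 = background, k = object k) aligned to a
#' \linkS4class{FieldImage} channel, together with a per-object table of
#' area, centroid and mean counterstain intensity. Produced by
#' \code{\link{segmentNuclei}} and consumed by \code{\link{filterDebris}}
#' and \code{\link{buildCytoplasmROIs}}.
#'
#' @slot mask integer matrix of labels; labels are contiguous 1..K
#' @slot objects data.frame with columns \code{label}, \code{y}, \code{x},
#'   \code{area_px}, \code{mean_intensity}; one row per nonzero label
#' @slot removed number of objects removed by the last filtering step
#' @export
setClass("LabeledMask",
  representation(mask = "matrix", objects = "data.frame", removed = "integer"),
  prototype(removed = 0L))

setValidity("LabeledMask", function(object) {
  k <- max(object@mask, 0)
  if (k != nrow(object@objects))
    return("object table rows must correspond 1:1 to nonzero labels")
  if (k > 0 && !setequal(object@mask[object@mask > 0], seq_len(k)))
    return("labels must be contiguous 1..K")
  TRUE
})

#' CellROIs: per-cell nucleus and cytoplasm masks
#'
#' Primary (nuclear) and secondary (cytoplasmic ring) regions of interest
#' for every retained cell. The cytoplasm of cell k is a fixed-width
#' expansion of its nucleus, with contested pixels assigned to the nearest
#' nucleus so that cytoplasm regions of distinct cells are disjoint and
#' never overlap any nucleus.
#'
#' @slot nuclei integer label matrix of nuclear masks
#' @slot cytoplasm integer label matrix of cytoplasmic masks (same labels)
#' @slot labels integer vector of cell labels present
#' @export
setClass("CellROIs",
  representation(nuclei = "matrix", cytoplasm = "matrix", labels = "integer"))

setValidity("CellROIs", function(object) {
  if (!identical(dim(object@nuclei), dim(object@cytoplasm)))
    return("nucleus and cytoplasm rasters must have identical dimensions")
  if (any(object@nuclei > 0 & object@cytoplasm > 0))
    return("cytoplasm must not overlap nuclei")
  TRUE
})

#' ThresholdModel: control-calibrated decision threshold
#'
#' Per-assay decision threshold derived from Gaussian fits to feature
#' values of negative and positive control populations, with a
#' directionality stating on which side of the threshold a cell (or
#' cytometry event) counts as positive. See \code{\link{fitThreshold}}.
#'
#' @slot assay assay label the threshold applies to
#' @slot direction \code{"above"} (values above threshold are positive) or
#'   \code{"below"}
#' @slot negMean,negSd Gaussian fit to the negative control values
#' @slot posMean,posSd Gaussian fit to the positive control values
#'   (\code{NA} when calibrated without a positive control)
#' @slot threshold the decision threshold, in feature units
#' @slot k SD multiplier used by the \code{k_sigma} method
#' @slot method \code{"intersection"} or \code{"k_sigma"}
#' @export
setClass("ThresholdModel",
  representation(assay = "character", direction = "character",
    negMean = "numeric", negSd = "numeric",
    posMean = "numeric", posSd = "numeric",
    threshold = "numeric", k = "numeric", method = "character"))

setValidity("ThresholdModel", function(object) {
  if (!object@direction %in% c("above", "below"))
    return("direction must be 'above' or 'below'")
  if (!is.finite(object@threshold)) return("threshold must be finite")
  if (!is.na(object@negSd) && object@negSd <= 0)
    return("negSd must be positive")
  if (!is.na(object@posSd) && object@posSd <= 0)
    return("posSd must be positive")
  TRUE
})

#' StainMaps: per-stain optical-density rasters
#'
#' Result of Beer--Lambert colour deconvolution of an RGB histology image:
#' hematoxylin and eosin density maps (optical-density units, clipped at 0)
#' and the stain vector basis used. See \code{\link{deconvolveHE}}.
#'
#' @slot hematoxylin hematoxylin density matrix (OD units)
#' @slot eosin eosin density matrix (OD units)
#' @slot vectors 3 x 2 matrix of unit OD stain vectors (columns H, E)
#' @export
setClass("StainMaps",
  representation(hematoxylin = "matrix", eosin = "matrix", vectors = "matrix"))

setValidity("StainMaps", function(object) {
  if (!identical(dim(object@hematoxylin), dim(object@eosin)))
    return("density maps must have identical dimensions")
  if (any(object@hematoxylin < 0) || any(object@eosin < 0))
    return("densities must be >= 0")
  if (!identical(dim(object@vectors), c(3L, 2L)))
    return("vectors must be a 3 x 2 matrix")
  TRUE
})

#' NecrosisResult: eosin/hematoxylin ratio map
#'
#' Per-pixel eosin-over-hematoxylin ratio, masked (NA) where the
#' hematoxylin density falls below a floor, with its mean over the
#' unmasked tissue. See \code{\link{eosinHematoxylinRatio}}.
#'
#' @slot ratioMap matrix of ratios, NA where masked
#' @slot meanRatio mean ratio over unmasked pixels (NA when fully masked)
#' @slot floor hematoxylin floor used for masking
#' @export
setClass("NecrosisResult",
  representation(ratioMap = "matrix", meanRatio = "numeric", floor = "numeric"))
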