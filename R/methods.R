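#' @rdname FieldImage-class
#' @export
setMethod("channelNames", "FieldImage", function(x) names(x@channels))

#' @rdname FieldImage-class
#' @export
setMethod("getChannel", "FieldImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel '", name, "' in this field (have: ",
         paste(names(x@channels), collapse = ", "), ")")
  x@channels[[name]]
})

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("FieldImage:", d[1], "x", d[2], "px,",
      length(object@channels), "channel(s):",
      paste(names(object@channels), collapse = ", "), "\n")
  cat("  well:", object@well, " field:", object@field, "\n")
})

#' @rdname LabeledMask-class
#' @export
setMethod("maskRaster", "LabeledMask", function(x) x@mask)

#' @rdname LabeledMask-class
#' @export
setMethod("objectTable", "LabeledMask", function(x) x@objects)

#' @rdname LabeledMask-class
#' @export
setMethod("nObjects", "LabeledMask", function(x) nrow(x@objects))

#' @rdname LabeledMask-class
#' @export
setMethod("nRemoved", "LabeledMask", function(x) x@removed)

setMethod("show", "LabeledMask", function(object) {
  d <- dim(object@mask)
  cat("LabeledMask:", d[1], "x", d[2], "px,",
      nrow(object@objects), "object(s)")
  if (object@removed > 0) cat(" (", object@removed, " removed)", sep = "")
  cat("\n")
})

#' @rdname CellROIs-class
#' @export
setMethod("nucleusMask", "CellROIs", function(x) x@nuclei)

#' @rdname CellROIs-class
#' @export
setMethod("cytoplasmMask", "CellROIs", function(x) x@cytoplasm)

setMethod("show", "CellROIs", function(object) {
  cat("CellROIs:", length(object@labels), "cell(s),",
      sum(object@cytoplasm > 0), "cytoplasm px\n")
})

#' @rdname ThresholdModel-class
#' @export
setMethod("thresholdValue", "ThresholdModel", function(x) x@threshold)

#' @rdname ThresholdModel-class
#' @export
setMethod("thresholdDirection", "ThresholdModel", function(x) x@direction)

setMethod("show", "ThresholdModel", function(object) {
  cat("ThresholdModel [", object@assay, "]\n", sep = "")
  cat("  method:", object@method, " direction:", object@direction,
      "is positive\n")
  cat(sprintf("  neg: N(%.4g, %.4g)", object@negMean, object@negSd))
  if (!is.na(object@posMean))
    cat(sprintf("  pos: N(%.4g, %.4g)", object@posMean, object@posSd))
  cat("\n  threshold:", format(object@threshold), "\n")
})

#' @rdname StainMaps-class
#' @export
setMethod("hematoxylin", "StainMaps", function(x) x@hematoxylin)

#' @rdname StainMaps-class
#' @export
setMethod("eosin", "StainMaps", function(x) x@eosin)

#' @rdname StainMaps-class
#' @export
setMethod("stainVectors", "StainMaps", function(x) x@vectors)

setMethod("show", "StainMaps", function(object) {
  d <- dim(object@hematoxylin)
  cat("StainMaps:", d[1], "x", d[2], "px; mean OD  H:",
      format(mean(object@hematoxylin), digits = 3), " E:",
      format(mean(object@eosin), digits = 3), "\n")
})

setMethod("show", "NecrosisResult", function(object) {
  cat("NecrosisResult: mean eosin/hematoxylin ratio",
      format(object@meanRatio, digits = 4),
      sprintf("(hematoxylin floor %.3g, %.1f%% masked)\n", object@floor,
              100 * mean(is.na(object@ratioMap))))
})
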