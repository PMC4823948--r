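#' @rdname FieldImage-class
#' @param object,x a \linkS4class{FieldImage}
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FieldImage-class
#' @param name channel name
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname LabeledMask-class
#' @export
setGeneric("maskRaster", function(x) standardGeneric("maskRaster"))

#' @rdname LabeledMask-class
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname LabeledMask-class
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname LabeledMask-class
#' @export
setGeneric("nRemoved", function(x) standardGeneric("nRemoved"))

#' @rdname CellROIs-class
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))

#' @rdname CellROIs-class
#' @export
setGeneric("cytoplasmMask", function(x) standardGeneric("cytoplasmMask"))

#' @rdname ThresholdModel-class
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname ThresholdModel-class
#' @export
setGeneric("thresholdDirection", function(x) standardGeneric("thresholdDirection"))

#' @rdname StainMaps-class
#' @export
setGeneric("hematoxylin", function(x) standardGeneric("hematoxylin"))

#' @rdname StainMaps-class
#' @export
setGeneric("eosin", function(x) standardGeneric("eosin"))

#' @rdname StainMaps-class
#' @export
setGeneric("stainVectors", function(x) standardGeneric("stainVectors"))
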