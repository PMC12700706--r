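#' @rdname gridDim
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname punctaAccessors
#' @export
setGeneric("nPuncta", function(x) standardGeneric("nPuncta"))

#' @rdname punctaAccessors
#' @export
setGeneric("punctaTable", function(x) standardGeneric("punctaTable"))

#' @rdname punctaAccessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname punctaAccessors
#' @export
setGeneric("roiOf", function(x) standardGeneric("roiOf"))

#' @rdname punctaAccessors
#' @export
setGeneric("pixelSets", function(x) standardGeneric("pixelSets"))

#' @rdname punctaToMask
#' @export
setGeneric("punctaToMask", function(x) standardGeneric("punctaToMask"))

#' @rdname colocAccessors
#' @export
setGeneric("colocCounts", function(x) standardGeneric("colocCounts"))

#' @rdname colocAccessors
#' @export
setGeneric("colocTotals", function(x) standardGeneric("colocTotals"))

#' @rdname colocAccessors
#' @export
setGeneric("colocPercent", function(x) standardGeneric("colocPercent"))

#' @rdname colocAccessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname rotatePuncta
#' @export
setGeneric("rotatePuncta", function(x, angle) standardGeneric("rotatePuncta"))

#' @rdname compositionAccessors
#' @export
setGeneric("compositionFractions",
           function(x) standardGeneric("compositionFractions"))
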