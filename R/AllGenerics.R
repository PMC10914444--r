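#' @export
setGeneric("buildPattern", function(x) standardGeneric("buildPattern"))

#' @export
setGeneric("flankMaxDist", function(x) standardGeneric("flankMaxDist"))

#' @export
setGeneric("barcodeMaxDist", function(x) standardGeneric("barcodeMaxDist"))

#' @export
setGeneric("windowPad", function(x) standardGeneric("windowPad"))

#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @export
setGeneric("umiLength", function(x) standardGeneric("umiLength"))

#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setGeneric("qualities", function(x) standardGeneric("qualities"))

#' @export
setGeneric("keptBarcodes", function(x) standardGeneric("keptBarcodes"))

#' @export
setGeneric("inflectionRank", function(x) standardGeneric("inflectionRank"))

#' @export
setGeneric("plotKnee", function(x, ...) standardGeneric("plotKnee"))
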