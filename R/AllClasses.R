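#' Read-structure description
#'
#' A `ReadStructure` declares the expected layout of each read as an ordered
#' list of segments: fixed-sequence flanks (e.g. a primer and a polyT stretch)
#' and variable segments (a cell barcode and/or a UMI, known only by length).
#' The search pattern is the concatenation of segment contributions, with
#' every variable base rendered as the wildcard `?`.
#'
#' @slot segments a `data.frame` with columns `kind` (`"FLANK"`, `"BARCODE"`
#'   or `"UMI"`), `sequence` (flanks only, `NA` otherwise), `length`
#'   (variable segments only) and `name`.
#' @slot flankMaxDist maximum edit distance allowed when searching for the
#'   full flank pattern in a read (default 8).
#' @slot barcodeMaxDist maximum edit distance allowed when error-correcting a
#'   barcode against the whitelist (default 2).
#' @slot windowPad bases of context kept on each side of the variable region
#'   when the barcode window is extracted (default 5).
#'
#' @seealso [readStructure()], [tenXv3Structure()], [buildPattern()]
#' @name ReadStructure-class
#' @rdname ReadStructure-class
#' @exportClass ReadStructure
setClass("ReadStructure",
  representation(
    segments = "data.frame",
    flankMaxDist = "integer",
    barcodeMaxDist = "integer",
    windowPad = "integer"
  )
)

.validReadStructure <- function(object) {
  seg <- object@segments
  msgs <- character(0)
  need <- c("kind", "sequence", "length", "name")
  if (!all(need %in% names(seg)))
    return(paste("segments must have columns", paste(need, collapse = ", ")))
  if (nrow(seg) == 0L) return("structure must contain at least one segment")
  if (!all(seg$kind %in% c("FLANK", "BARCODE", "UMI")))
    msgs <- c(msgs, "segment kind must be FLANK, BARCODE or UMI")
  if (sum(seg$kind == "FLANK") < 1L)
    msgs <- c(msgs, "at least one FLANK segment is required")
  if (sum(seg$kind == "BARCODE") > 1L)
    msgs <- c(msgs, "at most one BARCODE segment is allowed")
  if (sum(seg$kind == "UMI") > 1L)
    msgs <- c(msgs, "at most one UMI segment is allowed")
  fl <- seg$kind == "FLANK"
  if (any(fl & (is.na(seg$sequence) | !nzchar(seg$sequence))))
    msgs <- c(msgs, "FLANK segments need a non-empty sequence")
  if (any(fl & !is.na(seg$length)))
    msgs <- c(msgs, "FLANK segments must not carry a length")
  if (any(!fl & (is.na(seg$length) | seg$length < 1L)))
    msgs <- c(msgs, "BARCODE/UMI segments need length >= 1")
  if (any(!fl & !is.na(seg$sequence)))
    msgs <- c(msgs, "BARCODE/UMI segments must not carry a sequence")
  bad <- fl & !is.na(seg$sequence) &
    grepl("[^ACGTN]", seg$sequence)
  if (any(bad))
    msgs <- c(msgs, "FLANK sequences must be over {A,C,G,T,N}")
  ib <- which(seg$kind == "BARCODE"); iu <- which(seg$kind == "UMI")
  if (length(ib) == 1L && length(iu) == 1L && abs(ib - iu) != 1L)
    msgs <- c(msgs, "BARCODE and UMI segments must be adjacent")
  if (object@flankMaxDist < 0L || object@barcodeMaxDist < 0L ||
      object@windowPad < 0L)
    msgs <- c(msgs, "distance and pad parameters must be non-negative")
  if (length(msgs)) msgs else TRUE
}
setValidity("ReadStructure", .validReadStructure)

#' Set of sequencing reads
#'
#' An in-memory batch of sequencing records: identifiers, optional header
#' descriptions, sequences and optional per-base qualities.  Streaming
#' readers ([openReads()]) yield `ReadSet` chunks; [simulateReads()] produces
#' one together with its truth table.
#'
#' @slot id character vector of read identifiers (first whitespace-delimited
#'   header token).
#' @slot description remainder of the header line (`""` when absent).
#' @slot sequence uppercase read sequences.
#' @slot quality Phred+33 quality strings, or `NA` when the source had none.
#'
#' @seealso [ReadSet()], [openReads()], [writeReads()]
#' @name ReadSet-class
#' @rdname ReadSet-class
#' @exportClass ReadSet
setClass("ReadSet",
  representation(
    id = "character",
    description = "character",
    sequence = "character",
    quality = "character"
  )
)

.validReadSet <- function(object) {
  n <- length(object@id)
  if (length(object@description) != n || length(object@sequence) != n ||
      length(object@quality) != n)
    return("id, description, sequence and quality must have equal length")
  if (any(!nzchar(object@sequence)))
    return("sequences must be non-empty")
  has_q <- !is.na(object@quality)
  if (any(nchar(object@quality[has_q]) != nchar(object@sequence[has_q])))
    return("quality strings must match sequence length")
  TRUE
}
setValidity("ReadSet", .validReadSet)

#' Knee-plot filtering result
#'
#' Result of [kneeFilter()]: the inflection point of the barcode
#' rank-frequency curve, located as the most negative rolling-window
#' derivative in log-log space, and the barcodes kept (ranks up to and
#' including the inflection).
#'
#' @slot inflectionRank rank of the inflection point (last kept rank).
#' @slot countAtInflection read count of the barcode at that rank.
#' @slot kept character vector of kept barcodes, in rank order.
#' @slot derivative `data.frame` with columns `rank` and `slope`.
#' @slot searchRange integer vector of length 2, the rank range searched.
#' @slot lowConfidence `TRUE` when the winning slope is not clearly separated
#'   from the background (|slope| below twice the median |slope| in range),
#'   i.e. the curve has no pronounced knee.
#' @slot rankTable the sorted `data.frame` of `barcode`, `count`, `rank` the
#'   knee was computed on (after any whitelist restriction).
#'
#' @seealso [kneeFilter()], [plotKnee()], [keptBarcodes()]
#' @name KneeResult-class
#' @rdname KneeResult-class
#' @exportClass KneeResult
setClass("KneeResult",
  representation(
    inflectionRank = "integer",
    countAtInflection = "integer",
    kept = "character",
    derivative = "data.frame",
    searchRange = "integer",
    lowConfidence = "logical",
    rankTable = "data.frame"
  )
)

.validKneeResult <- function(object) {
  if (object@inflectionRank < 1L) return("inflectionRank must be >= 1")
  if (length(object@searchRange) != 2L) return("searchRange must be length 2")
  if (length(object@kept) != object@inflectionRank)
    return("kept must contain exactly inflectionRank barcodes")
  TRUE
}
setValidity("KneeResult", .validKneeResult)
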