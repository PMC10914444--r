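#' Segment constructors
#'
#' Building blocks for [readStructure()]: a fixed-sequence flank, a cell
#' barcode of known length, or a UMI of known length.
#'
#' @param sequence flank sequence over `{A,C,G,T,N}` (case-insensitive).
#' @param length length in bases of the variable segment.
#' @param name segment label used in reporting.
#' @return a one-row segment `data.frame` suitable for [readStructure()].
#' @examples
#' readStructure(flankSegment("ACGTACGT"), barcodeSegment(16), umiSegment(12),
#'               flankSegment("TTTTTTTTT", name = "polyT"))
#' @name segments-constructors
NULL

#' @rdname segments-constructors
#' @export
flankSegment <- function(sequence, name = "flank") {
  data.frame(kind = "FLANK", sequence = toupper(sequence),
             length = NA_integer_, name = name, stringsAsFactors = FALSE)
}

#' @rdname segments-constructors
#' @export
barcodeSegment <- function(length = 16L, name = "barcode") {
  data.frame(kind = "BARCODE", sequence = NA_character_,
             length = as.integer(length), name = name, stringsAsFactors = FALSE)
}

#' @rdname segments-constructors
#' @export
umiSegment <- function(length = 12L, name = "umi") {
  data.frame(kind = "UMI", sequence = NA_character_,
             length = as.integer(length), name = name, stringsAsFactors = FALSE)
}

#' Construct a read structure
#'
#' Assembles segment descriptions (in read order, 5' to 3') into a
#' [ReadStructure], the declarative description of what to search for in each
#' read.  At least one flank is required; at most one barcode and one UMI are
#' allowed, and when both are present they must be adjacent.
#'
#' @param ... segment `data.frame`s from [flankSegment()], [barcodeSegment()],
#'   [umiSegment()], in read order.
#' @param flankMaxDist maximum edit distance for the flank pattern search
#'   (default 8).
#' @param barcodeMaxDist maximum edit distance for barcode error correction
#'   (default 2).
#' @param windowPad context bases kept either side of the extracted variable
#'   region (default 5).
#' @return a validated [ReadStructure].
#' @examples
#' rs <- readStructure(flankSegment("ACGGT", "primer"), barcodeSegment(8),
#'                     flankMaxDist = 2)
#' buildPattern(rs)
#' @export
readStructure <- function(..., flankMaxDist = 8L, barcodeMaxDist = 2L,
                          windowPad = 5L) {
  seg <- do.call(rbind, list(...))
  new("ReadStructure", segments = seg,
      flankMaxDist = as.integer(flankMaxDist),
      barcodeMaxDist = as.integer(barcodeMaxDist),
      windowPad = as.integer(windowPad))
}

#' Default 10x Genomics 3' v3 read structure
#'
#' The default layout of a 10x Chromium 3' v3 read-1/cDNA junction as seen in
#' long reads: 22 bp of the read-1 primer suffix, a 16 bp cell barcode, a
#' 12 bp UMI, then 9 bp of polyT.  The 28 wildcard bases in between the
#' flanks are the variable region.
#'
#' @inheritParams readStructure
#' @return a [ReadStructure].
#' @examples
#' tenXv3Structure()
#' @export
tenXv3Structure <- function(flankMaxDist = 8L, barcodeMaxDist = 2L,
                            windowPad = 5L) {
  readStructure(
    flankSegment("CTACACGACGCTCTTCCGATCT", name = "primer"),
    barcodeSegment(16L),
    umiSegment(12L),
    flankSegment("TTTTTTTTT", name = "polyT"),
    flankMaxDist = flankMaxDist, barcodeMaxDist = barcodeMaxDist,
    windowPad = windowPad
  )
}

.segLengths <- function(seg) {
  ifelse(seg$kind == "FLANK", nchar(seg$sequence), seg$length)
}

#' Build the search pattern of a structure
#'
#' Concatenates segment contributions in order: flanks contribute their
#' sequence, variable segments contribute one `?` wildcard per base.
#'
#' @param x a [ReadStructure].
#' @return a single pattern string.
#' @examples
#' buildPattern(readStructure(flankSegment("ACG"), barcodeSegment(2)))
#' @rdname buildPattern
#' @export
setMethod("buildPattern", "ReadStructure", function(x) {
  seg <- x@segments
  paste(ifelse(seg$kind == "FLANK", seg$sequence,
               strrep("?", .segLengths(seg))), collapse = "")
})

#' @rdname ReadStructure-class
#' @param x a `ReadStructure`.
#' @export
setMethod("segments", "ReadStructure", function(x) x@segments)

#' @rdname ReadStructure-class
#' @export
setMethod("flankMaxDist", "ReadStructure", function(x) x@flankMaxDist)

#' @rdname ReadStructure-class
#' @export
setMethod("barcodeMaxDist", "ReadStructure", function(x) x@barcodeMaxDist)

#' @rdname ReadStructure-class
#' @export
setMethod("windowPad", "ReadStructure", function(x) x@windowPad)

#' @rdname ReadStructure-class
#' @export
setMethod("barcodeLength", "ReadStructure", function(x) {
  i <- which(x@segments$kind == "BARCODE")
  if (length(i)) x@segments$length[i] else NA_integer_
})

#' @rdname ReadStructure-class
#' @export
setMethod("umiLength", "ReadStructure", function(x) {
  i <- which(x@segments$kind == "UMI")
  if (length(i)) x@segments$length[i] else NA_integer_
})

setMethod("show", "ReadStructure", function(object) {
  seg <- object@segments
  len <- .segLengths(seg)
  lab <- ifelse(seg$kind == "FLANK",
                paste0("[", seg$name, " ", seg$sequence, "]"),
                paste0("[", seg$name, " ", len, "nt]"))
  cat("ReadStructure:", paste(lab, collapse = "-"), "\n")
  cat("  pattern length:", sum(len),
      "| flank maxDist:", object@flankMaxDist,
      "| barcode maxDist:", object@barcodeMaxDist,
      "| window pad:", object@windowPad, "\n")
})

# Pre-computed search engine for one structure: pattern, 0-based variable
# span in pattern coordinates, barcode/UMI geometry.  Internal.
.compileStructure <- function(structure, whitelist = NULL,
                              discover = FALSE, maxIter = 10L) {
  validObject(structure)
  seg <- structure@segments
  len <- .segLengths(seg)
  off <- cumsum(c(0L, len))
  isVar <- seg$kind != "FLANK"
  eng <- list(
    pattern = buildPattern(structure),
    hasVar = any(isVar),
    flankMaxDist = structure@flankMaxDist,
    barcodeMaxDist = structure@barcodeMaxDist,
    pad = structure@windowPad,
    maxIter = as.integer(maxIter),
    discover = discover,
    whitelist = whitelist
  )
  if (eng$hasVar) {
    vi <- which(isVar)
    eng$qlo <- off[min(vi)]            # 0-based start of variable span
    eng$qhi <- off[max(vi) + 1L]       # 0-based exclusive end
    ib <- which(seg$kind == "BARCODE")
    iu <- which(seg$kind == "UMI")
    eng$bcLen <- if (length(ib)) seg$length[ib] else NA_integer_
    eng$umiLen <- if (length(iu)) seg$length[iu] else NA_integer_
    eng$bcOff <- if (length(ib)) off[ib] - eng$qlo else NA_integer_
    eng$umiAfter <- if (length(ib) && length(iu)) iu > ib else NA
  }
  if (!is.null(whitelist)) {
    wl <- unique(toupper(whitelist))
    if (!length(wl)) stop("whitelist is empty; use discovery mode instead")
    if (eng$hasVar && !is.na(eng$bcLen) && any(nchar(wl) != eng$bcLen))
      stop("all whitelist barcodes must have the structure's barcode length (",
           eng$bcLen, ")")
    eng$whitelist <- wl
  }
  eng
}
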