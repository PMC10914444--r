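#' Extract the barcode window from a located flank match
#'
#' Locates the variable (barcode + UMI) region inside an infix hit by a
#' global alignment traceback of the pattern against the matched substring
#' (wildcard columns define the variable interval), then widens it by the
#' structure's `windowPad` on each side, clipped to the read bounds.  The
#' padding guarantees that the true barcode is contained in the window even
#' when indels in the flanks shift the alignment.
#'
#' @param sequence the read sequence the hit was found on (already
#'   strand-normalized).
#' @param hit a hit from [infixSearch()] of `buildPattern(structure)` on
#'   `sequence` (1-based inclusive `start`/`end`).
#' @param structure the [ReadStructure] that produced the pattern.
#' @return a list with the `window` sequence, its 1-based inclusive
#'   `start`/`end` in the read, and the unpadded variable-region interval
#'   `varStart`/`varEnd`.
#' @examples
#' rs <- tenXv3Structure()
#' read <- paste0("CTACACGACGCTCTTCCGATCT",
#'                "ACGTACGTACGTACGT", "TTGGCCAATTGG", "TTTTTTTTT")
#' hit <- infixSearch(buildPattern(rs), read, flankMaxDist(rs))
#' extractWindow(read, hit, rs)$window
#' @export
extractWindow <- function(sequence, hit, structure) {
  eng <- .compileStructure(structure)
  if (!eng$hasVar)
    stop("structure has no variable segment; ",
         "search-only mode bypasses extraction")
  seq <- toupper(sequence)
  s0 <- hit$start - 1L
  v <- cpp_locate_variable(eng$pattern, substr(seq, hit$start, hit$end),
                           eng$qlo, eng$qhi)
  vs0 <- s0 + v[1]; ve0 <- s0 + v[2]
  ws0 <- max(0L, vs0 - eng$pad); we0 <- min(nchar(seq), ve0 + eng$pad)
  list(window = substr(seq, ws0 + 1L, we0), start = ws0 + 1L, end = we0,
       varStart = vs0 + 1L, varEnd = ve0)
}
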