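#' Discover putative barcodes without a whitelist
#'
#' For every read (both strands, with the same mask-iterate chimera loop as
#' [demultiplex()]), the barcode-length substring immediately following the
#' left flank's alignment end is taken as the putative barcode and tallied.
#' Substrings containing `N` (or mask sentinel) or truncated below the
#' barcode length are skipped.  The total count equals the number of valid
#' flank-bearing extractions.
#'
#' @param input a [ReadSet], file path, `"-"`, or connection.
#' @param structure a [ReadStructure] with a `BARCODE` segment.
#' @param chunkSize records per processing chunk.
#' @param quiet suppress the summary message.
#' @return a data.frame with columns `barcode` and `count`, sorted by
#'   decreasing count (ties broken lexicographically), with attribute
#'   `totalReads` (reads scanned) and `extractions` (valid extractions,
#'   equal to `sum(count)`).
#' @examples
#' sim <- simulateReads(simConfig(nReads = 50, nBarcodes = 3, seed = 7,
#'                                subRate = 0, insRate = 0, delRate = 0,
#'                                chimeraRate = 0))
#' discoverBarcodes(sim$reads, tenXv3Structure(), quiet = TRUE)
#' @export
discoverBarcodes <- function(input, structure, chunkSize = 5000L,
                             quiet = FALSE) {
  eng <- .compileStructure(structure, discover = TRUE)
  if (!eng$hasVar || is.na(eng$bcLen))
    stop("discovery mode needs a structure with a BARCODE segment")
  eng$splitChimeras <- TRUE
  counts <- integer(0)
  nReads <- 0L
  processChunk <- function(reads) {
    seqs <- reads@sequence
    found <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      recs <- .demuxOne(seqs[i], eng)
      bcs <- vapply(recs, `[[`, "", "barcode")
      found[[i]] <- bcs[!is.na(bcs)]
    }
    nReads <<- nReads + length(seqs)
    tab <- table(unlist(found, use.names = FALSE))
    if (length(tab)) {
      nm <- names(tab)
      old <- counts[nm]
      old[is.na(old)] <- 0L
      counts[nm] <<- old + as.integer(tab)
    }
  }
  if (is(input, "ReadSet")) {
    nChunks <- ceiling(length(input) / chunkSize)
    for (k in seq_len(max(nChunks, 0L))) {
      idx <- seq.int((k - 1L) * chunkSize + 1L,
                     min(k * chunkSize, length(input)))
      processChunk(input[idx])
    }
  } else {
    st <- openReads(input)
    on.exit(st$close())
    repeat {
      r <- st$nextChunk(chunkSize)
      if (is.null(r)) break
      processChunk(r)
    }
  }
  df <- data.frame(barcode = names(counts), count = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$barcode), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "totalReads") <- nReads
  attr(df, "extractions") <- sum(df$count)
  if (!quiet)
    message(sprintf("discover: %d reads | %d extractions | %d distinct barcodes",
                    nReads, sum(df$count), nrow(df)))
  df
}

#' Rolling-window derivative of the knee curve
#'
#' Approximates the derivative of the barcode rank-frequency ("knee plot")
#' curve in log10-log10 space: for 1-based ranks `i = 1 .. N - window`,
#' `slope[i] = (log10 count[i + window] - log10 count[i]) /
#' (log10(i + window) - log10(i))`.  Counts must be sorted in decreasing
#' order, so all slopes are non-positive.
#'
#' @param counts numeric vector of counts, sorted decreasing.
#' @param window rolling window width in ranks (default 20).
#' @return numeric vector of `length(counts) - window` slopes.
#' @examples
#' rollingDerivative(c(100, 100, 100, 1, 1, 1), window = 1)
#' @export
rollingDerivative <- function(counts, window = 20L) {
  window <- as.integer(window)
  n <- length(counts)
  if (window < 1L) stop("window must be >= 1")
  if (n < window + 1L)
    stop("need more than ", window, " entries to compute the derivative ",
         "(got ", n, "); try a smaller window")
  if (is.unsorted(rev(counts)))
    stop("counts must be sorted in decreasing order")
  i <- seq_len(n - window)
  (log10(counts[i + window]) - log10(counts[i])) /
    (log10(i + window) - log10(i))
}

#' Locate the knee inflection point
#'
#' The inflection point of the knee curve is the rank whose rolling-window
#' slope is most negative within the search range; ties resolve to the
#' smallest rank.  The inflection rank becomes the cutoff: barcodes ranked
#' at or below it are considered real cells.
#'
#' @param slopes slope vector from [rollingDerivative()].
#' @param searchRange integer vector `c(lo, hi)` of ranks to search
#'   (1-based, within `1 .. length(slopes)`).
#' @return the inflection rank (integer).
#' @examples
#' findInflection(c(-0.1, -5, -0.1))
#' @export
findInflection <- function(slopes, searchRange = c(1L, length(slopes))) {
  lo <- as.integer(searchRange[1]); hi <- as.integer(searchRange[2])
  if (lo < 1L || hi > length(slopes) || lo > hi)
    stop("empty or out-of-bounds search range [", lo, ", ", hi, "]")
  idx <- lo:hi
  idx[which.min(slopes[idx])]
}

#' Knee-plot barcode filtering
#'
#' Calls true cell barcodes from a barcode frequency table.  Entries are
#' optionally restricted to a whitelist, sorted by decreasing count (ties
#' broken lexicographically so the curve is deterministic), and the rolling
#' log-log derivative of the rank-frequency curve is minimized within the
#' search range; the most negative slope marks the inflection region and the
#' cutoff is placed at the steepest single-rank drop inside it.  Barcodes
#' ranked at or below the cutoff are kept and can be passed back to
#' [demultiplex()] as the whitelist for error-tolerant assignment.
#'
#' Two numerical details make the detector robust on real frequency tables.
#' First, tied counts are collapsed to one curve point carrying their average
#' rank before the derivative is taken (the convention of
#' `DropletUtils::barcodeRanks`): with one rank per barcode the huge run of
#' count-1 and count-2 ambient barcodes produces an integer-count step whose
#' log-rank denominator is nearly zero, so the most negative raw slope would
#' always sit deep in the ambient tail rather than at the knee.  Second,
#' because a width-`window` slope only localizes the drop to `window` ranks,
#' the reported inflection is the largest one-step drop of `log10(count)`
#' inside the winning window — the top of the cliff.
#'
#' @param counts data.frame with columns `barcode` and `count`, as returned
#'   by [discoverBarcodes()] or [readBarcodeCounts()].
#' @param window rolling window width in curve points (default 20); when the
#'   collapsed curve has fewer points the window shrinks to the curve length
#'   minus one.
#' @param searchRange rank range (in barcode ranks) searched for the
#'   inflection; default `c(10, N - window)`, skipping the first 9 ranks to
#'   avoid overloaded-droplet artifacts (clamped to valid bounds).
#' @param whitelist optional barcode set; when given, non-members are
#'   discarded before the knee is computed.
#' @return a [KneeResult].
#' @examples
#' counts <- data.frame(
#'   barcode = sprintf("BC%04d", 1:120),
#'   count = c(rep(500L, 60), rep(4L, 60)))
#' kr <- kneeFilter(counts, window = 5)
#' inflectionRank(kr)
#' @export
kneeFilter <- function(counts, window = 20L, searchRange = NULL,
                       whitelist = NULL) {
  stopifnot(is.data.frame(counts), all(c("barcode", "count") %in%
                                       names(counts)))
  window <- as.integer(window)
  df <- counts[, c("barcode", "count")]
  if (!is.null(whitelist))
    df <- df[df$barcode %in% toupper(whitelist), , drop = FALSE]
  df <- df[order(-df$count, df$barcode), , drop = FALSE]
  n <- nrow(df)
  if (n < window + 1L)
    stop("only ", n, " barcodes after whitelist restriction; ",
         "need more than the window width (", window,
         ") - try a smaller window")
  rownames(df) <- NULL
  df$rank <- seq_len(n)

  # collapse tied counts: one point per unique count, average rank
  uc <- sort(unique(df$count), decreasing = TRUE)
  m <- length(uc)
  grp <- factor(match(df$count, uc), levels = seq_len(m))
  reprRank <- vapply(split(df$rank, grp), mean, 0)
  firstRank <- vapply(split(df$rank, grp), min, 0L)
  lastRank <- vapply(split(df$rank, grp), max, 0L)
  if (m < 2L)
    stop("all barcode counts are identical; the curve has no knee")
  wEff <- min(window, m - 1L)
  i <- seq_len(m - wEff)
  slopes <- (log10(uc[i + wEff]) - log10(uc[i])) /
    (log10(reprRank[i + wEff]) - log10(reprRank[i]))

  if (is.null(searchRange))
    searchRange <- c(min(10L, n - window), n - window)
  searchRange <- as.integer(searchRange)
  if (searchRange[1] > searchRange[2])
    stop("empty search range [", searchRange[1], ", ", searchRange[2], "]")
  # a window is eligible when its rank span overlaps the search range
  eligible <- which(lastRank[i + wEff] >= searchRange[1] &
                    firstRank[i] <= searchRange[2])
  if (!length(eligible))
    stop("no curve points inside the search range [", searchRange[1], ", ",
         searchRange[2], "]")
  iBest <- eligible[which.min(slopes[eligible])]

  # cutoff: steepest single-rank drop of log10(count) in the winning window,
  # clamped to the search range
  a <- max(firstRank[iBest], searchRange[1])
  b <- min(lastRank[iBest + wEff], searchRange[2] + window)
  if (a >= b) { a <- firstRank[iBest]; b <- lastRank[iBest + wEff] }
  r <- a:(b - 1L)
  drops <- log10(df$count[r]) - log10(df$count[r + 1L])
  infl <- r[which.max(drops)]

  # low confidence: the winning slope does not stand out from the background
  # (needs at least three slopes for the median to be a meaningful background)
  lowConf <- length(eligible) >= 3L &&
    abs(slopes[iBest]) < 2 * abs(median(slopes[eligible]))
  new("KneeResult",
      inflectionRank = as.integer(infl),
      countAtInflection = as.integer(df$count[infl]),
      kept = df$barcode[seq_len(infl)],
      derivative = data.frame(rank = reprRank[i], slope = slopes),
      searchRange = searchRange,
      lowConfidence = lowConf,
      rankTable = df)
}

#' @rdname KneeResult-class
#' @param x a `KneeResult`.
#' @export
setMethod("keptBarcodes", "KneeResult", function(x) x@kept)

#' @rdname KneeResult-class
#' @export
setMethod("inflectionRank", "KneeResult", function(x) x@inflectionRank)

#' @export
setMethod("show", "KneeResult", function(object) {
  cat("KneeResult:", length(object@kept), "barcodes kept of",
      nrow(object@rankTable), "\n")
  cat("  inflection at rank", object@inflectionRank,
      "(count", object@countAtInflection, ")",
      if (object@lowConfidence) "[low confidence: no pronounced knee]" else "",
      "\n")
  cat("  search range:", object@searchRange[1], "-", object@searchRange[2],
      "\n")
})

#' Diagnostic knee plot
#'
#' Log-log rank-frequency curve with the inflection point marked, for manual
#' inspection of the cutoff.
#'
#' @param x a [KneeResult].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @rdname plotKnee
#' @export
setMethod("plotKnee", "KneeResult", function(x, ...) {
  df <- x@rankTable
  graphics::plot(df$rank, df$count, log = "xy", type = "l",
                 xlab = "barcode rank", ylab = "read count",
                 main = "Barcode rank-frequency knee", ...)
  graphics::abline(v = x@inflectionRank, col = "red", lty = 2)
  graphics::points(x@inflectionRank, x@countAtInflection, col = "red",
                   pch = 19)
  graphics::mtext(sprintf("inflection rank %d (count %d)%s",
                          x@inflectionRank, x@countAtInflection,
                          if (x@lowConfidence) " - low confidence" else ""),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
})
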