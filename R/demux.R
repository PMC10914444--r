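#' Error-correct an extraction window against a barcode whitelist
#'
#' Every whitelist barcode is aligned semi-globally inside the window (both
#' window ends free) and its Levenshtein distance computed.  The unique
#' lowest-distance barcode is reported when its distance is at most
#' `maxDist`; when two or more barcodes attain the lowest distance the
#' window is ambiguous and no barcode is assigned.  The result does not
#' depend on whitelist order.
#'
#' @param window extracted sequence window (variable region plus padding).
#' @param whitelist character vector of candidate barcodes (deduplicated).
#' @param maxDist maximum acceptable barcode edit distance (default 2).
#' @return a list with `status` (`"ASSIGNED"`, `"AMBIGUOUS"` or
#'   `"NO_BARCODE"`), `barcode`, `distance`, and the matched interval
#'   `start`/`end` (1-based inclusive, window coordinates) when assigned.
#' @examples
#' assignBarcode("GATCTAAAACCCCGGGGTTTTACGTACGTACGTTTTT",
#'               c("AAAACCCCGGGGTTTT", "TTTTGGGGCCCCAAAA"), maxDist = 2)
#' @export
assignBarcode <- function(window, whitelist, maxDist = 2L) {
  whitelist <- unique(toupper(whitelist))
  if (!length(whitelist))
    stop("whitelist is empty; use discovery mode instead")
  a <- cpp_assign_barcode(toupper(window), whitelist, as.integer(maxDist))
  if (a$idx < 0L)
    return(list(status = "NO_BARCODE", barcode = NA_character_,
                distance = NA_integer_, start = NA_integer_,
                end = NA_integer_))
  if (a$nmin > 1L)
    return(list(status = "AMBIGUOUS", barcode = NA_character_,
                distance = a$dist, start = NA_integer_, end = NA_integer_))
  list(status = "ASSIGNED", barcode = whitelist[a$idx + 1L],
       distance = a$dist, start = a$start + 1L, end = a$end)
}

# One strand pass of the mask-iterate loop.  `work` is the (possibly
# reverse-complemented) read with any prior hits masked.  Returns the hits
# found on this strand (coordinates on `work`) and the further-masked read.
.scanStrand <- function(work, eng) {
  hits <- vector("list", eng$maxIter)
  nh <- 0L
  L <- nchar(work)
  for (it in seq_len(eng$maxIter)) {
    h <- cpp_infix_search(eng$pattern, work, eng$flankMaxDist)
    if (h$dist < 0L) break
    s0 <- h$start; e0 <- h$end
    rec <- list(pStart = s0 + 1L, pEnd = e0, flankDist = h$dist,
                status = "MATCHED", barcode = NA_character_,
                bcDist = NA_integer_, umi = NA_character_,
                umiTrunc = NA)
    if (eng$hasVar) {
      v <- cpp_locate_variable(eng$pattern, substr(work, s0 + 1L, e0),
                               eng$qlo, eng$qhi)
      vs0 <- s0 + v[1]; ve0 <- s0 + v[2]
      ws0 <- max(0L, vs0 - eng$pad); we0 <- min(L, ve0 + eng$pad)
      window <- substr(work, ws0 + 1L, we0)
      rec$winStart <- ws0 + 1L; rec$winEnd <- we0
      if (eng$discover) {
        pb <- substr(work, vs0 + eng$bcOff + 1L, vs0 + eng$bcOff + eng$bcLen)
        ok <- nchar(pb) == eng$bcLen && !grepl("[NX]", pb)
        rec$status <- if (ok) "COUNTED" else "SKIPPED"
        rec$barcode <- if (ok) pb else NA_character_
      } else {
        a <- cpp_assign_barcode(window, eng$whitelist, eng$barcodeMaxDist)
        if (a$idx < 0L) {
          rec$status <- "NO_BARCODE"
        } else if (a$nmin > 1L) {
          rec$status <- "AMBIGUOUS"
          rec$bcDist <- a$dist
        } else {
          rec$status <- "ASSIGNED"
          rec$barcode <- eng$whitelist[a$idx + 1L]
          rec$bcDist <- a$dist
          bs0 <- ws0 + a$start; be0 <- ws0 + a$end
          if (!is.na(eng$umiLen)) {
            if (isTRUE(eng$umiAfter)) {
              umi <- substr(work, be0 + 1L, min(L, be0 + eng$umiLen))
            } else {
              umi <- substr(work, max(0L, bs0 - eng$umiLen) + 1L, bs0)
            }
            rec$umi <- umi
            rec$umiTrunc <- nchar(umi) < eng$umiLen
          }
        }
      }
    }
    nh <- nh + 1L
    hits[[nh]] <- rec
    substr(work, s0 + 1L, e0) <- strrep("X", e0 - s0)
    if (!eng$splitChimeras) break
  }
  list(hits = hits[seq_len(nh)], work = work)
}

# Demultiplex one read: forward mask-iterate pass, then the same loop on the
# reverse complement with the images of all forward hits masked.  Returns a
# list of record lists in original-read coordinate order.
.demuxOne <- function(seq, eng) {
  L <- nchar(seq)
  fw <- .scanStrand(seq, eng)
  rcWork <- reverseComplement(seq)
  for (h in fw$hits) {
    # map [s,e] through i -> L + 1 - i
    substr(rcWork, L - h$pEnd + 1L, L - h$pStart + 1L) <-
      strrep("X", h$pEnd - h$pStart + 1L)
  }
  doRc <- eng$splitChimeras || !length(fw$hits)
  rv <- if (doRc) .scanStrand(rcWork, eng) else list(hits = list())
  recs <- c(
    lapply(fw$hits, function(h) {
      h$strand <- "+"; h$origStart <- h$pStart; h$origEnd <- h$pEnd; h
    }),
    lapply(rv$hits, function(h) {
      h$strand <- "-"
      h$origStart <- L - h$pEnd + 1L
      h$origEnd <- L - h$pStart + 1L
      h
    })
  )
  if (length(recs) > 1L)
    recs <- recs[order(vapply(recs, `[[`, 0L, "origStart"))]
  recs
}

# Fill trimmed sequences: each assigned record keeps the insert running from
# the end of its own matched structure to the next structural boundary in its
# own 5'->3' orientation (reverse-complemented for minus-strand hits so the
# insert always reads downstream of the barcode).
.splitTrim <- function(seq, qual, recs) {
  L <- nchar(seq)
  starts <- vapply(recs, `[[`, 0L, "origStart")
  ends <- vapply(recs, `[[`, 0L, "origEnd")
  hasQ <- !is.na(qual)
  for (k in seq_along(recs)) {
    if (recs[[k]]$strand == "+") {
      nxt <- starts[starts > ends[k]]
      tEnd <- if (length(nxt)) min(nxt) - 1L else L
      tStart <- ends[k] + 1L
      recs[[k]]$trimmedSeq <- if (tStart <= tEnd)
        substr(seq, tStart, tEnd) else ""
      recs[[k]]$trimmedQual <- if (hasQ && tStart <= tEnd)
        substr(qual, tStart, tEnd) else if (hasQ) "" else NA_character_
    } else {
      prv <- ends[ends < starts[k]]
      tStart <- if (length(prv)) max(prv) + 1L else 1L
      tEnd <- starts[k] - 1L
      if (tStart <= tEnd) {
        recs[[k]]$trimmedSeq <- reverseComplement(substr(seq, tStart, tEnd))
        recs[[k]]$trimmedQual <- if (hasQ)
          cpp_strrev(substr(qual, tStart, tEnd)) else NA_character_
      } else {
        recs[[k]]$trimmedSeq <- ""
        recs[[k]]$trimmedQual <- if (hasQ) "" else NA_character_
      }
    }
  }
  recs
}

#' Demultiplex a single read
#'
#' Runs the full per-read engine: semi-global flank search, variable-region
#' extraction, barcode error correction, iterative masking to catch chimeric
#' reads, and a reverse-complement pass; assigned hits are then split and
#' trimmed.  Exposed mainly for inspection and testing; use [demultiplex()]
#' for streams.
#'
#' @param sequence a single read sequence.
#' @param structure a [ReadStructure].
#' @param whitelist character vector of known barcodes, or `NULL` for
#'   search-only structures (no variable segments).
#' @param quality optional quality string.
#' @param id read identifier used in the output.
#' @param splitChimeras iterate masked re-search to find further structure
#'   copies (default `TRUE`); when `FALSE` at most one record is returned.
#' @return a data.frame with one row per assigned hit (or a single failure
#'   row), containing the barcode, distance, UMI, strand, status, flank edit
#'   distance, matched pattern interval and trimmed insert.
#' @examples
#' rs <- tenXv3Structure()
#' bc <- "ACGTACGTACGTACGT"; umi <- "TTGGCCAATTGG"
#' read <- paste0("GGG", "CTACACGACGCTCTTCCGATCT", bc, umi,
#'                "TTTTTTTTT", "CATCATCATGGTGGT")
#' demultiplexRead(read, rs, whitelist = c(bc, "GGGGCCCCAAAATTTT"))
#' @export
demultiplexRead <- function(sequence, structure, whitelist = NULL,
                            quality = NA_character_, id = "read",
                            splitChimeras = TRUE) {
  eng <- .compileStructure(structure, whitelist = whitelist,
                           discover = FALSE)
  if (eng$hasVar && is.null(whitelist))
    stop("a whitelist is required for structures with a barcode; ",
         "use discoverBarcodes() for discovery mode")
  eng$splitChimeras <- isTRUE(splitChimeras)
  recs <- .demuxOne(toupper(sequence), eng)
  .recordsToFrame(list(.finalizeRead(toupper(sequence), quality, id, recs,
                                     eng)))
}

# Keep assigned (or matched, for search-only structures) records; when none
# remain, emit a single failure record describing the best failed hit (or
# NO_FLANK).  Returns a list of flat record lists.
.finalizeRead <- function(seq, qual, id, recs, eng) {
  keepStatus <- if (eng$hasVar && !eng$discover) "ASSIGNED"
    else if (eng$discover) "COUNTED" else "MATCHED"
  keep <- vapply(recs, function(r) r$status == keepStatus, TRUE)
  out <- recs[keep]
  if (length(out)) {
    out <- .splitTrim(seq, qual, out)
    for (k in seq_along(out)) {
      out[[k]]$readId <- id
      out[[k]]$subReadIndex <- k - 1L
    }
    return(out)
  }
  # failure record: best failed hit by flank distance, then position
  status <- "NO_FLANK"
  flankDist <- NA_integer_
  strand <- NA_character_
  pS <- NA_integer_; pE <- NA_integer_
  if (length(recs)) {
    o <- order(vapply(recs, `[[`, 0L, "flankDist"),
               vapply(recs, `[[`, 0L, "origStart"))
    b <- recs[[o[1]]]
    status <- b$status
    flankDist <- b$flankDist
    strand <- b$strand
    pS <- b$origStart; pE <- b$origEnd
  }
  list(list(readId = id, subReadIndex = 0L, status = status,
            barcode = NA_character_, bcDist = NA_integer_,
            umi = NA_character_, umiTrunc = NA, strand = strand,
            flankDist = flankDist, origStart = pS, origEnd = pE,
            trimmedSeq = seq, trimmedQual = qual))
}

# Flatten a list (over reads) of lists of record lists into one data.frame.
.recordsToFrame <- function(perRead) {
  flat <- unlist(perRead, recursive = FALSE, use.names = FALSE)
  if (!length(flat)) {
    return(data.frame(readId = character(0), subReadIndex = integer(0),
                      barcode = character(0), barcodeDist = integer(0),
                      umi = character(0), umiTruncated = logical(0),
                      strand = character(0), status = character(0),
                      flankDist = integer(0), patternStart = integer(0),
                      patternEnd = integer(0), trimmedSeq = character(0),
                      trimmedQual = character(0), stringsAsFactors = FALSE))
  }
  gchr <- function(f) vapply(flat, function(r) {
    v <- r[[f]]; if (is.null(v)) NA_character_ else as.character(v)
  }, "")
  gint <- function(f) vapply(flat, function(r) {
    v <- r[[f]]; if (is.null(v) || is.na(v)) NA_integer_ else as.integer(v)
  }, 0L)
  glgl <- function(f) vapply(flat, function(r) {
    v <- r[[f]]; if (is.null(v)) NA else as.logical(v)
  }, NA)
  data.frame(
    readId = gchr("readId"),
    subReadIndex = gint("subReadIndex"),
    barcode = gchr("barcode"),
    barcodeDist = gint("bcDist"),
    umi = gchr("umi"),
    umiTruncated = glgl("umiTrunc"),
    strand = gchr("strand"),
    status = gchr("status"),
    flankDist = gint("flankDist"),
    patternStart = gint("origStart"),
    patternEnd = gint("origEnd"),
    trimmedSeq = gchr("trimmedSeq"),
    trimmedQual = gchr("trimmedQual"),
    stringsAsFactors = FALSE
  )
}

#' Demultiplex a stream of reads
#'
#' Streaming driver over [demultiplexRead()]'s engine: finds the flank
#' pattern in every read within `flankMaxDist(structure)` edits, extracts the
#' barcode window, error-corrects against the whitelist (unique lowest
#' distance at most `barcodeMaxDist(structure)`), iterates with masking on
#' both strands to split chimeric reads, and trims each assigned sub-read to
#' its insert.  For structures without variable segments the driver degrades
#' to pure error-tolerant search and reports matching reads unmodified.
#'
#' Trimmed reads are written as `{barcode}_{umi}#{read_id}_{sub_read_index}`
#' records; reads with no assigned hit can be routed to a separate unassigned
#' sink, so the pipeline is lossless.  Output is a pure function of the
#' input: it is independent of `chunkSize` and of whitelist order.
#'
#' @param input a [ReadSet], file path, `"-"` for standard input, or
#'   connection.
#' @param structure a [ReadStructure].
#' @param whitelist character vector of barcodes, or a whitelist file path;
#'   `NULL` only for search-only structures.
#' @param output optional sink for trimmed assigned reads (path, `""` for
#'   standard output, or connection); `NULL` suppresses read output.
#' @param unassignedOutput optional sink for reads with no assigned hit,
#'   written unmodified.
#' @param outputFormat `"auto"`, `"fasta"` or `"fastq"`.
#' @param splitChimeras iterate masked re-search (default `TRUE`).
#' @param chunkSize records processed per chunk (memory/speed trade-off
#'   only; results are identical for any value).
#' @param quiet suppress the end-of-run summary on the message stream.
#' @return (invisibly for large streams) the assignment data.frame, one row
#'   per assigned sub-read plus one failure row per unassigned read, with a
#'   `summary` attribute (reads, assigned reads, records, chimeric reads).
#' @examples
#' sim <- simulateReads(simConfig(nReads = 20, nBarcodes = 4, seed = 1,
#'                                subRate = 0, insRate = 0, delRate = 0,
#'                                chimeraRate = 0))
#' a <- demultiplex(sim$reads, tenXv3Structure(), whitelist = sim$whitelist,
#'                  quiet = TRUE)
#' table(a$status)
#' @export
demultiplex <- function(input, structure, whitelist = NULL, output = NULL,
                        unassignedOutput = NULL,
                        outputFormat = c("auto", "fasta", "fastq"),
                        splitChimeras = TRUE, chunkSize = 5000L,
                        quiet = FALSE) {
  outputFormat <- match.arg(outputFormat)
  if (is.character(whitelist) && length(whitelist) == 1L &&
      file.exists(whitelist) && !grepl("^[ACGTN]+$", toupper(whitelist)))
    whitelist <- readWhitelist(whitelist)
  eng <- .compileStructure(structure, whitelist = whitelist,
                           discover = FALSE)
  if (eng$hasVar && is.null(eng$whitelist))
    stop("a whitelist is required for structures with a barcode; ",
         "use discoverBarcodes() for discovery mode")
  eng$splitChimeras <- isTRUE(splitChimeras)

  outSink <- if (!is.null(output)) .openSink(output) else NULL
  unSink <- if (!is.null(unassignedOutput)) .openSink(unassignedOutput)
    else NULL
  on.exit({
    if (!is.null(outSink) && outSink$own) close(outSink$con)
    if (!is.null(unSink) && unSink$own) close(unSink$con)
  })

  okStatus <- if (eng$hasVar) "ASSIGNED" else "MATCHED"
  frames <- list()
  nReads <- 0L; nAssignedReads <- 0L; nChimeric <- 0L; nRecords <- 0L

  processChunk <- function(reads) {
    ids <- reads@id; seqs <- reads@sequence; quals <- reads@quality
    perRead <- vector("list", length(reads))
    for (i in seq_along(perRead)) {
      recs <- .demuxOne(seqs[i], eng)
      perRead[[i]] <- .finalizeRead(seqs[i], quals[i], ids[i], recs, eng)
    }
    df <- .recordsToFrame(perRead)
    ok <- df$status == okStatus
    nReads <<- nReads + length(reads)
    nRecords <<- nRecords + sum(ok)
    perOk <- vapply(perRead, function(rs) sum(vapply(rs, function(r)
      r$status == okStatus, TRUE)), 0L)
    nAssignedReads <<- nAssignedReads + sum(perOk > 0L)
    nChimeric <<- nChimeric + sum(perOk > 1L)
    if (!is.null(outSink) && any(ok)) {
      sub <- df[ok, , drop = FALSE]
      if (eng$hasVar) {
        outIds <- paste0(sub$barcode, "_",
                         ifelse(is.na(sub$umi), "", sub$umi), "#",
                         sub$readId, "_", sub$subReadIndex)
        writeReads(ReadSet(outIds, sub$trimmedSeq, quality = sub$trimmedQual),
                   outSink$con, format = outputFormat)
      } else {
        keepIdx <- match(unique(sub$readId), ids)
        writeReads(reads[keepIdx], outSink$con, format = outputFormat)
      }
    }
    if (!is.null(unSink)) {
      bad <- setdiff(ids, df$readId[ok])
      if (length(bad))
        writeReads(reads[match(bad, ids)], unSink$con, format = outputFormat)
    }
    frames[[length(frames) + 1L]] <<- df
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
    on.exit(st$close(), add = TRUE)
    repeat {
      r <- st$nextChunk(chunkSize)
      if (is.null(r)) break
      processChunk(r)
    }
  }
  res <- do.call(rbind, frames)
  if (is.null(res)) res <- .recordsToFrame(list())
  smry <- list(reads = nReads, assignedReads = nAssignedReads,
               records = nRecords, chimericReads = nChimeric)
  attr(res, "summary") <- smry
  if (!quiet)
    message(sprintf(
      "demultiplex: %d reads | %d assigned (%.1f%%) | %d records | %d chimeric",
      nReads, nAssignedReads,
      if (nReads) 100 * nAssignedReads / nReads else 0,
      nRecords, nChimeric))
  if (is.null(output)) res else invisible(res)
}
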