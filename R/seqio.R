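#' Open a streaming reader over FASTA/FASTQ input
#'
#' Auto-detects FASTA vs FASTQ from the first record marker (`>` vs `@`) and
#' gzip compression from the magic bytes; reads from a file path, an open
#' connection, or standard input (`"-"`).  Records are yielded in file order
#' in bounded-size chunks, so memory stays constant per chunk regardless of
#' file size.  Multi-line (wrapped) FASTA is supported; FASTQ must be in the
#' standard four-line form.
#'
#' @param source file path, `"-"` for standard input, or an open connection.
#' @return a `ReadStream`: a list with `nextChunk(n)`, returning a [ReadSet]
#'   of up to `n` records or `NULL` at end of input, and `close()`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' st <- openReads(fq)
#' st$nextChunk(10)
#' st$close()
#' @export
openReads <- function(source) {
  ownCon <- TRUE
  if (inherits(source, "connection")) {
    con <- source
    ownCon <- FALSE
    if (!isOpen(con)) open(con, "r")
  } else if (identical(source, "-") || identical(source, "stdin")) {
    con <- file("stdin", open = "r")
  } else {
    if (!file.exists(source)) stop("cannot open reads source: ", source)
    magic <- readBin(source, "raw", n = 2L)
    con <- if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
               magic[2] == as.raw(0x8b)) {
      gzfile(source, open = "r")
    } else {
      file(source, open = "r")
    }
  }
  env <- new.env(parent = emptyenv())
  env$buf <- character(0)
  env$eof <- FALSE
  env$format <- NA_character_
  env$nSeen <- 0L       # records already yielded, for error reporting

  fill <- function(minLines) {
    while (length(env$buf) < minLines && !env$eof) {
      x <- readLines(con, n = max(minLines - length(env$buf), 4096L))
      if (!length(x)) env$eof <- TRUE else env$buf <- c(env$buf, x)
    }
  }
  detect <- function() {
    fill(1L)
    first <- env$buf[nzchar(env$buf)][1]
    if (is.na(first)) return(FALSE)   # empty input: empty stream, not an error
    env$format <- if (startsWith(first, ">")) "fasta"
      else if (startsWith(first, "@")) "fastq"
      else stop("cannot detect FASTA/FASTQ format from first record marker '",
                substr(first, 1, 1), "'")
    TRUE
  }

  nextFastq <- function(n) {
    fill(4L * n)
    take <- min(length(env$buf), 4L * n)
    rem <- take %% 4L
    if (rem != 0L) {
      # tolerate trailing blank lines at EOF, otherwise truncated quartet
      tailLines <- env$buf[(take - rem + 1L):take]
      if (env$eof && length(env$buf) == take && all(!nzchar(tailLines))) {
        env$buf <- env$buf[seq_len(take - rem)]
        take <- take - rem
      } else {
        stop("truncated FASTQ record at record index ",
             env$nSeen + take %/% 4L + 1L)
      }
    }
    if (take == 0L) return(NULL)
    lines <- env$buf[seq_len(take)]
    env$buf <- env$buf[-seq_len(take)]
    k <- take %/% 4L
    hd <- lines[seq(1L, take, by = 4L)]
    sq <- lines[seq(2L, take, by = 4L)]
    pl <- lines[seq(3L, take, by = 4L)]
    qu <- lines[seq(4L, take, by = 4L)]
    bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
    if (length(bad))
      stop("malformed FASTQ record at record index ", env$nSeen + bad[1])
    bad <- which(nchar(qu) != nchar(sq))
    if (length(bad))
      stop("FASTQ sequence/quality length mismatch at record index ",
           env$nSeen + bad[1])
    env$nSeen <- env$nSeen + k
    hd <- substring(hd, 2L)
    id <- sub("\\s.*$", "", hd)
    desc <- ifelse(grepl("\\s", hd), sub("^\\S+\\s+", "", hd), "")
    ReadSet(id = id, sequence = sq, quality = qu, description = desc)
  }

  nextFasta <- function(n) {
    repeat {
      hdr <- which(startsWith(env$buf, ">"))
      if (length(hdr) >= n + 1L || env$eof) break
      fill(length(env$buf) + 8192L)
    }
    hdr <- which(startsWith(env$buf, ">"))
    if (!length(hdr)) {
      if (length(env$buf[nzchar(env$buf)]))
        stop("malformed FASTA at record index ", env$nSeen + 1L,
             ": expected '>' header")
      return(NULL)
    }
    take <- if (length(hdr) >= n + 1L) hdr[n + 1L] - 1L else length(env$buf)
    lines <- env$buf[seq_len(take)]
    env$buf <- env$buf[-seq_len(take)]
    lines <- lines[nzchar(lines)]
    isHdr <- startsWith(lines, ">")
    if (!isHdr[1])
      stop("malformed FASTA at record index ", env$nSeen + 1L,
           ": expected '>' header")
    grp <- cumsum(isHdr)
    hd <- substring(lines[isHdr], 2L)
    k <- length(hd)
    sq <- character(k)
    body <- !isHdr
    if (any(body)) {
      pieces <- vapply(split(lines[body], grp[body]),
                       paste, "", collapse = "")
      sq[as.integer(names(pieces))] <- pieces
    }
    empty <- which(!nzchar(sq))
    if (length(empty))
      stop("empty sequence in FASTA at record index ", env$nSeen + empty[1])
    env$nSeen <- env$nSeen + k
    id <- sub("\\s.*$", "", hd)
    desc <- ifelse(grepl("\\s", hd), sub("^\\S+\\s+", "", hd), "")
    ReadSet(id = id, sequence = sq, description = desc)
  }

  stream <- list(
    nextChunk = function(n = 5000L) {
      n <- as.integer(n)
      if (is.na(env$format) && !detect()) return(NULL)
      if (env$format == "fastq") nextFastq(n) else nextFasta(n)
    },
    format = function() env$format,
    close = function() if (ownCon) try(close(con), silent = TRUE)
  )
  class(stream) <- "ReadStream"
  stream
}

#' Read an entire FASTA/FASTQ source into memory
#'
#' Convenience wrapper around [openReads()] for small inputs.
#'
#' @inheritParams openReads
#' @param chunkSize records per underlying chunk.
#' @return a [ReadSet] (possibly empty).
#' @export
readReads <- function(source, chunkSize = 5000L) {
  st <- openReads(source)
  on.exit(st$close())
  chunks <- list()
  repeat {
    r <- st$nextChunk(chunkSize)
    if (is.null(r)) break
    chunks[[length(chunks) + 1L]] <- r
  }
  if (!length(chunks))
    return(ReadSet(character(0), character(0)))
  .concatReadSets(chunks)
}

.openSink <- function(sink, append = FALSE) {
  if (inherits(sink, "connection"))
    return(list(con = sink, own = FALSE))
  if (identical(sink, "") || identical(sink, "-"))
    return(list(con = stdout(), own = FALSE))
  mode <- if (append) "at" else "wt"
  con <- if (grepl("\\.gz$", sink)) gzfile(sink, mode) else file(sink, mode)
  list(con = con, own = TRUE)
}

#' Write reads as FASTA or FASTQ
#'
#' Output is never line-wrapped, so same-format round trips through
#' [openReads()] are byte-exact.  When FASTQ output is requested for records
#' without qualities, a constant `I` (Phred 40) string is fabricated and a
#' message is emitted.
#'
#' @param x a [ReadSet] (or data.frame with columns `id`, `sequence` and
#'   optionally `quality`, `description`).
#' @param sink file path (`.gz` for compressed output), `""`/`"-"` for
#'   standard output, or an open connection.
#' @param format `"auto"` (FASTQ when qualities are present), `"fasta"` or
#'   `"fastq"`.
#' @param append append to `sink` instead of truncating.
#' @return (invisibly) the number of records written.
#' @export
writeReads <- function(x, sink = "", format = c("auto", "fasta", "fastq"),
                       append = FALSE) {
  format <- match.arg(format)
  if (is.data.frame(x)) {
    x <- ReadSet(x$id, x$sequence,
                 quality = if ("quality" %in% names(x)) x$quality else
                   NA_character_,
                 description = if ("description" %in% names(x))
                   x$description else "")
  }
  stopifnot(is(x, "ReadSet"))
  n <- length(x)
  if (format == "auto")
    format <- if (n && any(!is.na(x@quality))) "fastq" else "fasta"
  out <- .openSink(sink, append)
  if (out$own) on.exit(close(out$con))
  if (n == 0L) return(invisible(0L))
  desc <- ifelse(nzchar(x@description), paste0(" ", x@description), "")
  if (format == "fastq") {
    qual <- x@quality
    fab <- is.na(qual)
    if (any(fab)) {
      message("fabricating constant 'I' qualities for ", sum(fab),
              " record(s) without quality strings")
      qual[fab] <- strrep("I", nchar(x@sequence[fab]))
    }
    lines <- as.vector(rbind(paste0("@", x@id, desc), x@sequence, "+", qual))
  } else {
    lines <- as.vector(rbind(paste0(">", x@id, desc), x@sequence))
  }
  writeLines(lines, out$con)
  invisible(n)
}

#' Write the per-read assignment table
#'
#' Tab-separated with a single `#`-prefixed header line; columns are
#' `read_id`, `sub_read_index`, `barcode`, `distance`, `umi`, `strand`,
#' `status`, `flank_edit_distance`.
#'
#' @param assignments the data.frame returned by [demultiplex()].
#' @param sink file path, `""` for standard output, or connection.
#' @return (invisibly) the number of rows written.
#' @export
writeAssignments <- function(assignments, sink = "") {
  out <- .openSink(sink)
  if (out$own) on.exit(close(out$con))
  cols <- c("readId", "subReadIndex", "barcode", "barcodeDist", "umi",
            "strand", "status", "flankDist")
  header <- "#read_id\tsub_read_index\tbarcode\tdistance\tumi\tstrand\tstatus\tflank_edit_distance"
  vals <- lapply(cols, function(cl) {
    v <- as.character(assignments[[cl]])
    ifelse(is.na(v), "NA", v)
  })
  writeLines(c(header, do.call(paste, c(vals, sep = "\t"))), out$con)
  invisible(nrow(assignments))
}

#' Read and write barcode frequency tables
#'
#' Tab-separated `barcode<TAB>count`, sorted by decreasing count with ties
#' broken lexicographically; a single `#`-prefixed header line is written and
#' skipped on read.
#'
#' @param sink,source file path, `""`/`"-"` for a standard stream, or
#'   connection.
#' @param counts a data.frame with columns `barcode` and `count`.
#' @return `readBarcodeCounts` returns the data.frame; `writeBarcodeCounts`
#'   (invisibly) the number of rows written.
#' @name barcode-counts-io
NULL

#' @rdname barcode-counts-io
#' @export
writeBarcodeCounts <- function(counts, sink = "") {
  out <- .openSink(sink)
  if (out$own) on.exit(close(out$con))
  counts <- counts[order(-counts$count, counts$barcode), , drop = FALSE]
  writeLines(c("#barcode\tcount",
               paste(counts$barcode, counts$count, sep = "\t")), out$con)
  invisible(nrow(counts))
}

#' @rdname barcode-counts-io
#' @export
readBarcodeCounts <- function(source) {
  lines <- readLines(if (identical(source, "-")) file("stdin") else source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(barcode = character(0), count = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(barcode = toupper(vapply(parts, `[[`, "", 1L)),
                   count = as.integer(vapply(parts, `[[`, "", 2L)),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$barcode), , drop = FALSE]
}

#' Read or write a barcode whitelist (one barcode per line)
#'
#' @param source,sink file path or connection.
#' @param barcodes character vector of barcodes.
#' @return `readWhitelist` returns a character vector.
#' @name whitelist-io
NULL

#' @rdname whitelist-io
#' @export
readWhitelist <- function(source) {
  x <- readLines(source)
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname whitelist-io
#' @export
writeWhitelist <- function(barcodes, sink) {
  out <- .openSink(sink)
  if (out$own) on.exit(close(out$con))
  writeLines(barcodes, out$con)
  invisible(length(barcodes))
}
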