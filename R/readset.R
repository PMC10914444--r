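#' Construct a ReadSet
#'
#' @param id character vector of read identifiers.
#' @param sequence read sequences (uppercased on ingest).
#' @param quality optional Phred+33 quality strings (`NA` when absent).
#' @param description optional header remainders.
#' @return a [ReadSet].
#' @examples
#' ReadSet(c("r1", "r2"), c("ACGT", "GGTTA"))
#' @export
ReadSet <- function(id, sequence, quality = NA_character_, description = "") {
  n <- length(id)
  new("ReadSet",
      id = as.character(id),
      description = rep_len(as.character(description), n),
      sequence = toupper(as.character(sequence)),
      quality = rep_len(as.character(quality), n))
}

#' @rdname ReadSet-class
#' @param x a `ReadSet`.
#' @export
setMethod("readIds", "ReadSet", function(x) x@id)

#' @rdname ReadSet-class
#' @export
setMethod("sequences", "ReadSet", function(x) x@sequence)

#' @rdname ReadSet-class
#' @export
setMethod("qualities", "ReadSet", function(x) x@quality)

#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  new("ReadSet", id = x@id[i], description = x@description[i],
      sequence = x@sequence[i], quality = x@quality[i])
})

#' @export
setMethod("show", "ReadSet", function(object) {
  n <- length(object)
  cat("ReadSet of", n, "reads",
      if (all(is.na(object@quality))) "(no qualities)" else "(with qualities)",
      "\n")
  if (n) {
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      s <- object@sequence[i]
      cat("  ", object@id[i], " [", nchar(s), " nt] ",
          if (nchar(s) > 40) paste0(substr(s, 1, 40), "...") else s, "\n",
          sep = "")
    }
    if (n > k) cat("  ...\n")
  }
})

#' @export
as.data.frame.ReadSet <- function(x, ...) {
  data.frame(id = x@id, description = x@description, sequence = x@sequence,
             quality = x@quality, stringsAsFactors = FALSE)
}

.concatReadSets <- function(chunks) {
  new("ReadSet",
      id = unlist(lapply(chunks, function(r) r@id), use.names = FALSE),
      description = unlist(lapply(chunks, function(r) r@description),
                           use.names = FALSE),
      sequence = unlist(lapply(chunks, function(r) r@sequence),
                        use.names = FALSE),
      quality = unlist(lapply(chunks, function(r) r@quality),
                       use.names = FALSE))
}
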