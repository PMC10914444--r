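#' Simulation configuration
#'
#' Bundles and validates the parameters of the read simulator.  Defaults
#' emulate noisy long-read single-cell cDNA sequencing at desk scale: an
#' ONT-like error profile of 5% substitutions and 2.5% each insertions and
#' deletions (roughly 10% total per-base error), 3% chimeric reads, and
#' strand flips for half the molecules.
#'
#' @param nReads number of reads to generate.
#' @param barcodes explicit barcode whitelist to draw from, or `NULL` to
#'   generate one with [generateWhitelist()].
#' @param nBarcodes,barcodeLength,minPairwiseDist whitelist generation
#'   parameters used when `barcodes` is `NULL`.
#' @param umiLength UMI length in bases.
#' @param insertLengthRange `c(min, max)` of the random cDNA insert length.
#' @param junkLengthRange `c(min, max)` of random unrelated sequence added at
#'   each read end (exercises infix rather than prefix search).
#' @param subRate,insRate,delRate per-base substitution / insertion /
#'   deletion probabilities, applied template-wide (flanks included).
#' @param chimeraRate probability that a read is a two-part chimera
#'   (concatenation of two independent molecules).
#' @param rcFraction probability that a molecule is flipped to the reverse
#'   strand.
#' @param abundance `"uniform"` or `"lognormal"` barcode abundance.
#' @param abundanceMeanlog,abundanceSdlog log-normal abundance parameters.
#' @param barcodeEdits when set to an integer k, the iid error process is
#'   replaced by exactly k random edits confined to the barcode segment
#'   (used to validate guaranteed error correction).
#' @param seed integer seed; the simulator is fully deterministic per seed.
#' @return a validated `simConfig` list.
#' @examples
#' simConfig(nReads = 100, nBarcodes = 8, seed = 42)
#' @export
simConfig <- function(nReads = 1000L, barcodes = NULL, nBarcodes = 96L,
                      barcodeLength = 16L, minPairwiseDist = 5L,
                      umiLength = 12L, insertLengthRange = c(50L, 200L),
                      junkLengthRange = c(0L, 50L), subRate = 0.05,
                      insRate = 0.025, delRate = 0.025, chimeraRate = 0.03,
                      rcFraction = 0.5,
                      abundance = c("uniform", "lognormal"),
                      abundanceMeanlog = 0, abundanceSdlog = 1,
                      barcodeEdits = NA_integer_, seed = 1L) {
  abundance <- match.arg(abundance)
  rates <- c(subRate, insRate, delRate, chimeraRate, rcFraction)
  if (any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]")
  if (!is.null(barcodes)) barcodes <- toupper(barcodes)
  cfg <- list(nReads = as.integer(nReads), barcodes = barcodes,
              nBarcodes = as.integer(nBarcodes),
              barcodeLength = as.integer(barcodeLength),
              minPairwiseDist = as.integer(minPairwiseDist),
              umiLength = as.integer(umiLength),
              insertLengthRange = as.integer(insertLengthRange),
              junkLengthRange = as.integer(junkLengthRange),
              subRate = subRate, insRate = insRate, delRate = delRate,
              chimeraRate = chimeraRate, rcFraction = rcFraction,
              abundance = abundance, abundanceMeanlog = abundanceMeanlog,
              abundanceSdlog = abundanceSdlog,
              barcodeEdits = as.integer(barcodeEdits), seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(len) {
  vapply(len, function(l) paste(sample(.BASES, l, replace = TRUE),
                                collapse = ""), "")
}

# uniform draw from an integer range, safe for degenerate lo == hi
.sampleRange <- function(range) {
  if (range[1] >= range[2]) return(range[1])
  sample(seq.int(range[1], range[2]), 1L)
}

#' Generate a spaced barcode whitelist
#'
#' Draws random barcodes by rejection sampling until `n` distinct barcodes
#' with pairwise Levenshtein distance at least `minPairwiseDist` are found.
#'
#' @param n number of barcodes.
#' @param length barcode length in bases.
#' @param minPairwiseDist minimum pairwise Levenshtein distance.
#' @param seed integer seed.
#' @param maxAttempts rejection budget before declaring infeasibility.
#' @return character vector of `n` barcodes.
#' @examples
#' generateWhitelist(4, 16, 5, seed = 1)
#' @export
generateWhitelist <- function(n, length, minPairwiseDist, seed = 1L,
                              maxAttempts = 200L * n) {
  set.seed(seed)
  out <- character(0)
  attempts <- 0L
  while (base::length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not place ", n, " barcodes of length ", length,
           " with min pairwise distance ", minPairwiseDist, " after ",
           maxAttempts, " attempts; the spacing is infeasible")
    cand <- .randSeq(length)
    if (base::length(out)) {
      d <- cpp_bounded_levenshtein(cand, out, minPairwiseDist - 1L)
      if (any(d >= 0L)) next   # within forbidden distance of an accepted one
    }
    out <- c(out, cand)
  }
  out
}

# Apply the iid error process to one segment: substitutions first, then at
# most one insertion after each original base, then per-base deletion.
# Returns the mutated string.
.mutateSeq <- function(s, subRate, insRate, delRate) {
  if (!nzchar(s) || (subRate == 0 && insRate == 0 && delRate == 0))
    return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hit <- runif(n) < subRate
  if (any(hit)) {
    idx <- match(ch[hit], .BASES)
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    ch[hit] <- .BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  pieces <- ch
  ins <- runif(n) < insRate
  if (any(ins))
    pieces[ins] <- paste0(ch[ins],
                          sample(.BASES, sum(ins), replace = TRUE))
  del <- runif(n) < delRate
  if (any(del)) pieces[del] <- substring(pieces[del], 2L)
  paste(pieces, collapse = "")
}

# Apply exactly k random edits (sub/ins/del, uniform) to a string.
.injectEdits <- function(s, k) {
  for (i in seq_len(k)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    op <- sample(c("sub", "ins", "del"), 1L)
    if (op == "sub") {
      p <- sample.int(n, 1L)
      ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
    } else if (op == "ins") {
      p <- sample.int(n + 1L, 1L)
      ch <- append(ch, sample(.BASES, 1L), after = p - 1L)
    } else {
      p <- sample.int(n, 1L)
      ch <- ch[-p]
    }
    s <- paste(ch, collapse = "")
  }
  s
}

#' Simulate reads with known barcodes, UMIs and errors
#'
#' Generates single-cell-style reads following a [ReadStructure]: random
#' junk, the structure's flanks with a sampled barcode and random UMI, a
#' random insert, and more junk; then applies the iid substitution /
#' insertion / deletion error process template-wide, forms two-part chimeras
#' with probability `chimeraRate`, and flips strands with probability
#' `rcFraction`.  Segment boundaries are tracked through the error process,
#' so the truth table carries exact post-error coordinates.
#'
#' @param config a [simConfig()].
#' @param structure the [ReadStructure] to emulate (default
#'   [tenXv3Structure()]); its barcode/UMI lengths are taken from `config`.
#' @return a list with `reads` (a [ReadSet] with constant `I` qualities),
#'   `truth` (a data.frame with one row per molecule: `readId`, `part`,
#'   `barcode`, `umi`, `strand`, `chimeric`, `insert`, `template` (the
#'   error-free plus-strand molecule), and 1-based inclusive
#'   coordinates of the structure pattern, barcode and UMI in the final
#'   read), and `whitelist` (the barcodes drawn from).
#' @examples
#' sim <- simulateReads(simConfig(nReads = 5, nBarcodes = 3, seed = 1))
#' sim$truth[, c("readId", "barcode", "strand", "chimeric")]
#' @export
simulateReads <- function(config, structure = tenXv3Structure()) {
  stopifnot(inherits(config, "simConfig"))
  wl <- config$barcodes
  if (is.null(wl))
    wl <- generateWhitelist(config$nBarcodes, config$barcodeLength,
                            config$minPairwiseDist, seed = config$seed)
  else set.seed(config$seed)

  seg <- structure@segments
  exactK <- config$barcodeEdits
  weights <- switch(config$abundance,
    uniform = rep(1, length(wl)),
    lognormal = rlnorm(length(wl), config$abundanceMeanlog,
                       config$abundanceSdlog))
  weights <- weights / sum(weights)

  nReads <- config$nReads
  chim <- runif(nReads) < config$chimeraRate
  nParts <- ifelse(chim, 2L, 1L)

  # Generate one molecule: returns sequence, per-feature intervals (1-based
  # inclusive, molecule coordinates), strand, and its truth fields.
  makePart <- function() {
    bc <- sample(wl, 1L, prob = weights)
    umi <- .randSeq(config$umiLength)
    insert <- .randSeq(.sampleRange(config$insertLengthRange))
    junk5 <- .randSeq(.sampleRange(config$junkLengthRange))
    junk3 <- .randSeq(.sampleRange(config$junkLengthRange))
    pieces <- character(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      pieces[i] <- switch(seg$kind[i],
        FLANK = seg$sequence[i],
        BARCODE = bc,
        UMI = umi)
    }
    tmpl <- c(junk5, pieces, insert, junk3)
    labels <- c("junk5", seg$kind, "insert", "junk3")
    if (!is.na(exactK)) {
      ib <- which(labels == "BARCODE")
      tmpl[ib] <- .injectEdits(tmpl[ib], exactK)
      mut <- tmpl
    } else {
      mut <- vapply(tmpl, .mutateSeq, "", subRate = config$subRate,
                    insRate = config$insRate, delRate = config$delRate,
                    USE.NAMES = FALSE)
    }
    lens <- nchar(mut)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    pat <- which(labels %in% c("FLANK", "BARCODE", "UMI"))
    ivs <- list(
      pattern = c(min(starts[pat]), max(ends[pat])),
      barcode = c(starts[labels == "BARCODE"], ends[labels == "BARCODE"]),
      umi = if (any(labels == "UMI"))
        c(starts[labels == "UMI"], ends[labels == "UMI"]) else c(NA, NA)
    )
    readSeq <- paste(mut, collapse = "")
    template <- paste(tmpl, collapse = "")
    strand <- "+"
    if (runif(1) < config$rcFraction) {
      L <- nchar(readSeq)
      readSeq <- reverseComplement(readSeq)
      ivs <- lapply(ivs, function(iv) c(L - iv[2] + 1L, L - iv[1] + 1L))
      strand <- "-"
    }
    list(seq = readSeq, ivs = ivs, strand = strand, barcode = bc, umi = umi,
         insert = insert, template = template)
  }

  seqs <- character(nReads)
  truthRows <- vector("list", nReads)
  for (r in seq_len(nReads)) {
    parts <- lapply(seq_len(nParts[r]), function(p) makePart())
    offset <- 0L
    rows <- vector("list", length(parts))
    for (p in seq_along(parts)) {
      pp <- parts[[p]]
      rows[[p]] <- data.frame(
        readId = sprintf("read%06d", r), part = p, barcode = pp$barcode,
        umi = pp$umi, strand = pp$strand, chimeric = nParts[r] > 1L,
        insert = pp$insert, template = pp$template,
        patternStart = pp$ivs$pattern[1] + offset,
        patternEnd = pp$ivs$pattern[2] + offset,
        bcStart = pp$ivs$barcode[1] + offset,
        bcEnd = pp$ivs$barcode[2] + offset,
        umiStart = pp$ivs$umi[1] + offset,
        umiEnd = pp$ivs$umi[2] + offset,
        stringsAsFactors = FALSE)
      offset <- offset + nchar(pp$seq)
    }
    seqs[r] <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
    truthRows[[r]] <- do.call(rbind, rows)
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  reads <- ReadSet(sprintf("read%06d", seq_len(nReads)), seqs,
                   quality = strrep("I", nchar(seqs)))
  list(reads = reads, truth = truth, whitelist = wl)
}
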