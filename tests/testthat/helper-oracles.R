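# Independent oracles, kept deliberately naive: the textbook edit-distance
# recurrence filled as a full matrix, and infix search by enumeration over
# all substring starts.  These never share code with the package's compiled
# implementation.

oracleLev <- function(a, b, wildcard = FALSE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1] <- 0:m; D[1, ] <- 0:n
  cost <- function(p, t) {
    if (wildcard && p == "?") return(if (t == "X") 1L else 0L)
    if (p == "X" || t == "X") return(1L)
    if (p == t) 0L else 1L
  }
  for (i in seq_len(m)) for (j in seq_len(n))
    D[i + 1L, j + 1L] <- min(D[i, j] + cost(A[i], B[j]),
                             D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L)
  D[m + 1L, n + 1L]
}

# Brute-force semi-global search: for each start, one DP against the text
# suffix whose last row yields the distance to every end; the winner is the
# lexicographically smallest (distance, start, end).  Returns NULL or a list
# with 1-based inclusive start/end plus the distance, matching infixSearch().
oracleInfix <- function(pattern, text, maxDist) {
  A <- strsplit(pattern, "")[[1]]
  m <- length(A)
  n <- nchar(text)
  cost <- function(p, t) {
    if (p == "?") return(if (t == "X") 1L else 0L)
    if (p == "X" || t == "X") return(1L)
    if (p == t) 0L else 1L
  }
  best <- NULL
  for (s0 in 0:n) {
    B <- if (s0 < n) strsplit(substr(text, s0 + 1L, n), "")[[1]] else
      character(0)
    k <- length(B)
    prev <- 0:k
    if (m > 0) for (i in seq_len(m)) {
      cur <- integer(k + 1L)
      cur[1] <- i
      for (j in seq_len(k))
        cur[j + 1L] <- min(prev[j] + cost(A[i], B[j]),
                           prev[j + 1L] + 1L, cur[j] + 1L)
      prev <- cur
    }
    for (l in 0:k) {
      d <- prev[l + 1L]; e0 <- s0 + l
      if (is.null(best) || d < best$d ||
          (d == best$d && (s0 < best$s || (s0 == best$s && e0 < best$e))))
        best <- list(d = d, s = s0, e = e0)
    }
  }
  if (best$d > maxDist) return(NULL)
  list(start = best$s + 1L, end = best$e, distance = best$d)
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Error-free structured read for the default 10x v3 layout.
TENX_PRIMER <- "CTACACGACGCTCTTCCGATCT"
TENX_POLYT <- "TTTTTTTTT"
makeTenXRead <- function(bc, umi, insert = "", junk5 = "", junk3 = "") {
  paste0(junk5, TENX_PRIMER, bc, umi, TENX_POLYT, insert, junk3)
}

# Exactly k random edits (substitution / insertion / deletion) into a string;
# used to build controlled error-correction cases.
.injectEditsForTest <- function(s, k) {
  for (i in seq_len(k)) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "sub") {
      p <- sample.int(n, 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    } else if (op == "ins") {
      p <- sample.int(n + 1, 1)
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = p - 1)
    } else {
      ch <- ch[-sample.int(n, 1)]
    }
    s <- paste(ch, collapse = "")
  }
  s
}

# Synthetic cell/ambient count mixture for knee-filter validation: cell
# barcode counts ~ NegBin(mean 200, size 10), ambient ~ 1 + Geometric(p=0.5)
# (mean 2).  Returns the count table plus the truth partition.
makeKneeMixture <- function(nCells = 500L, nAmbient = 5000L, seed = 1L) {
  set.seed(seed)
  bcs <- character(0)
  while (length(bcs) < nCells + nAmbient)
    bcs <- unique(c(bcs, vapply(seq_len(nCells + nAmbient - length(bcs)),
                                function(i) randSeq(16), "")))
  cells <- bcs[seq_len(nCells)]
  ambient <- bcs[nCells + seq_len(nAmbient)]
  counts <- data.frame(
    barcode = c(cells, ambient),
    count = c(pmax(1L, stats::rnbinom(nCells, mu = 200, size = 10)),
              1L + stats::rgeom(nAmbient, prob = 0.5)),
    stringsAsFactors = FALSE)
  list(counts = counts, cells = cells, ambient = ambient)
}
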