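#' Levenshtein distance
#'
#' Minimum number of substitutions, insertions and deletions transforming one
#' sequence into another.  The mask sentinel `X` mismatches every symbol,
#' including itself, so masked intervals never align for free.  Vectorised
#' with the usual recycling rules.
#'
#' @param a,b character vectors of sequences over `{A,C,G,T,N,X}`.
#' @return integer vector of distances.
#' @examples
#' levenshteinDist("GATTACA", "GCATGCA")
#' levenshteinDist("ACGT", c("ACGT", "ACCT", ""))
#' @export
levenshteinDist <- function(a, b) {
  cpp_levenshtein(toupper(as.character(a)), toupper(as.character(b)))
}

#' Bounded Levenshtein distance
#'
#' Like [levenshteinDist()] but computed in a band of width `2 * maxDist + 1`;
#' pairs whose distance exceeds `maxDist` return `NA` (the "exceeded" marker).
#'
#' @param a,b character vectors of sequences.
#' @param maxDist maximum distance of interest (non-negative integer).
#' @return integer vector; `NA` where the distance exceeds `maxDist`.
#' @examples
#' boundedLevenshtein("AAAA", c("AAAT", "TTTT"), maxDist = 2)
#' @export
boundedLevenshtein <- function(a, b, maxDist) {
  stopifnot(length(maxDist) == 1L, maxDist >= 0)
  d <- cpp_bounded_levenshtein(toupper(as.character(a)),
                               toupper(as.character(b)), as.integer(maxDist))
  d[d < 0L] <- NA_integer_
  d
}

#' Semi-global (infix) pattern search
#'
#' Finds the substring of `text` with the lowest edit distance to `pattern`,
#' with both substring ends free.  `?` in the pattern is a wildcard that
#' substitutes against `A/C/G/T/N` at no cost (indels touching it still cost
#' one); `N` in the text matches only `N` and `?`.  Among equal-distance hits
#' the smallest start wins, then the smallest end (leftmost, shortest).
#'
#' @param pattern search pattern, possibly containing `?` wildcards.
#' @param text sequence to search in (may contain the mask sentinel `X`,
#'   which matches nothing).
#' @param maxDist maximum acceptable edit distance.
#' @return a list with 1-based inclusive `start`, `end` and the `distance`,
#'   or `NULL` when no substring achieves `<= maxDist`.
#' @examples
#' infixSearch("ACGT", "TTACGTTT", maxDist = 2)
#' infixSearch("AC??GT", "GGACTAGTGG", maxDist = 2)
#' @export
infixSearch <- function(pattern, text, maxDist) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern),
            is.character(text), length(text) == 1L,
            length(maxDist) == 1L, maxDist >= 0)
  h <- cpp_infix_search(toupper(pattern), toupper(text), as.integer(maxDist))
  if (h$dist < 0L) return(NULL)
  list(start = h$start + 1L, end = h$end, distance = h$dist)
}

#' Reverse complement
#'
#' Standard reverse complement over `{A,C,G,T,N,X}`; `N` and the mask
#' sentinel `X` self-complement, so masked intervals survive strand flips.
#' Any other character is a hard error naming the character and its position.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' reverseComplement(c("ACGT", "AACG", "ANCA"))
#' @export
reverseComplement <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Mask an interval of a sequence
#'
#' Replaces the bases in `[start, end]` (1-based, inclusive) with the mask
#' sentinel `X`, preserving length.  Masked intervals mismatch everything, so
#' a previously matched structure cannot be found again during chimera
#' iteration.
#'
#' @param x a single sequence.
#' @param start,end 1-based inclusive interval bounds.
#' @return the masked sequence.
#' @examples
#' maskInterval("ACGTACGT", 3, 4)
#' @export
maskInterval <- function(x, start, end) {
  stopifnot(length(x) == 1L, length(start) == 1L, length(end) == 1L)
  n <- nchar(x)
  if (start < 1L || end > n || start > end)
    stop("interval [", start, ",", end, "] out of bounds for length ", n)
  substr(x, start, end) <- strrep("X", end - start + 1L)
  x
}
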