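#' Hamming distance between two equal-length DNA strings
#'
#' @param p,q character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hammingDistance("ACGT", "TGCA")
#' @export
hammingDistance <- function(p, q) {
  if (nchar(p) != nchar(q))
    stop(sprintf("length mismatch: %d vs %d", nchar(p), nchar(q)))
  cpp_hamming(p, q)
}

#' Test (l,d)-similarity of two l-patterns
#'
#' Two l-patterns are (l,d)-similar when their Hamming distance does not
#' exceed d.
#'
#' @param p,q character scalars of length \code{condition@l}.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @return logical scalar.
#' @export
isSimilar <- function(p, q, condition) {
  if (nchar(p) != condition@l || nchar(q) != condition@l)
    stop("patterns must have length l")
  hammingDistance(p, q) <= condition@d
}

#' Cut an l-pattern into its gamma-segments
#'
#' Returns the \code{beta} non-overlapping segments whose concatenation is
#' the pattern; the last segment holds the remainder when gamma does not
#' divide l.
#'
#' @param p character scalar of length \code{scheme@l}.
#' @param scheme a \code{\link{segmentScheme}}.
#' @return character vector of \code{beta} segments, in order.
#' @examples
#' splitSegments("ACGT", segmentScheme(DiscoveryCondition(4, 2), gamma = 2))
#' @export
splitSegments <- function(p, scheme) {
  if (nchar(p) != scheme@l) stop("pattern length must equal l")
  ends <- cumsum(scheme@segmentLengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  substring(p, starts, ends)
}

#' Per-segment mismatch budget
#'
#' The mismatch allowance of a segment of the given length:
#' \code{floor(segmentLength * d / l)}. For full-length (gamma) segments this
#' is the classical \code{floor(gamma * d / l)}; the length-proportional form
#' extends the pigeonhole guarantee to a short remainder segment.
#'
#' @param segmentLength length of the segment, in bases.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @return non-negative integer budget.
#' @export
segmentBudget <- function(segmentLength, condition) {
  if (segmentLength < 1L || segmentLength > condition@l)
    stop("segmentLength must be in [1, l]")
  as.integer((segmentLength * condition@d) %/% condition@l)
}

#' Hamming ball of a segment string
#'
#' All strings over {A,C,G,T} of the same length within Hamming distance
#' \code{delta} of \code{upsilon}, including \code{upsilon} itself. The ball
#' has \code{sum_{j=0}^{delta} choose(len, j) * 3^j} members.
#'
#' @param upsilon a segment string over A/C/G/T.
#' @param delta non-negative radius, at most \code{nchar(upsilon)}.
#' @return character vector (unique, unordered set).
#' @examples
#' hammingNeighborhood("TG", 1)
#' @export
hammingNeighborhood <- function(upsilon, delta) {
  if (delta > nchar(upsilon)) stop("delta must not exceed the segment length")
  ball <- upsilon
  frontier <- upsilon
  for (j in seq_len(delta)) {
    frontier <- unique(unlist(lapply(frontier, singleSubstitutions)))
    frontier <- setdiff(frontier, ball)
    ball <- c(ball, frontier)
  }
  ball
}

# all strings at Hamming distance exactly 1 from s
singleSubstitutions <- function(s) {
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (i in seq_len(n)) {
    for (b in DNA_BASES[DNA_BASES != chars[i]]) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

#' Group keys of a candidate pattern
#'
#' A candidate joins exactly the \code{beta} groups keyed by its own exact
#' segments: segment i of the pattern at segment index i.
#'
#' @param p an l-pattern.
#' @param scheme a \code{\link{segmentScheme}}.
#' @return data.frame with columns \code{upsilon} (segment string) and
#'   \code{segment} (1-based segment index), one row per key.
#' @examples
#' candidateGroupKeys("ACGT", segmentScheme(DiscoveryCondition(4, 2), 2))
#' @export
candidateGroupKeys <- function(p, scheme) {
  segs <- splitSegments(p, scheme)
  data.frame(upsilon = segs, segment = seq_along(segs),
             stringsAsFactors = FALSE)
}

#' Group keys of a source pattern
#'
#' A source pattern joins, at every segment index i, the groups of all
#' segment strings within the segment's mismatch budget of its own i-th
#' segment (its Hamming ball). Together with \code{\link{candidateGroupKeys}}
#' this guarantees every (l,d)-similar candidate/source pair meets in at
#' least one group.
#'
#' @inheritParams candidateGroupKeys
#' @param q an l-pattern.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @return data.frame with columns \code{upsilon}, \code{segment} and
#'   \code{dist} (known mismatches between \code{upsilon} and the pattern's
#'   segment).
#' @export
sourceGroupKeys <- function(q, scheme, condition) {
  segs <- splitSegments(q, scheme)
  out <- lapply(seq_along(segs), function(i) {
    delta <- segmentBudget(scheme@segmentLengths[i], condition)
    ball <- hammingNeighborhood(segs[i], delta)
    data.frame(upsilon = ball, segment = i,
               dist = vapply(ball, cpp_hamming, integer(1), q = segs[i]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

# canonical string form of group keys, used by the R-path group index
groupKeyStrings <- function(keys) paste0(keys$segment, ":", keys$upsilon)
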