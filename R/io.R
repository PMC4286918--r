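#' Clean a raw DNA sequence
#'
#' Upper-cases the sequence and replaces every character outside {A,C,G,T}
#' (ambiguity codes, gaps, "don't care" universal characters) by 'A', the
#' standard preprocessing for large EST-style databases before uniqueness
#' screening.
#'
#' @param raw character vector of raw sequences.
#' @return character vector of cleaned sequences (same lengths).
#' @examples
#' cleanSequence("ACGNRT")
#' @export
cleanSequence <- function(raw) {
  gsub("[^ACGT]", "A", toupper(raw))
}

#' Load and preprocess a FASTA file
#'
#' Reads a (possibly gzipped) FASTA file, discards the description lines,
#' cleans each sequence with \code{\link{cleanSequence}} and drops records
#' shorter than \code{minLength} bases (default 36, the conventional EST
#' cutoff).
#'
#' @param path FASTA file path.
#' @param minLength minimum cleaned-sequence length to keep.
#' @return named character vector of cleaned sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
loadFasta <- function(path, minLength = 36L) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e)
                     stop(sprintf("malformed FASTA '%s': %s", path,
                                  conditionMessage(e)), call. = FALSE))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  cleaned <- cleanSequence(as.character(seqs))
  names(cleaned) <- ids
  cleaned[nchar(cleaned) >= minLength]
}

#' Extract the l-pattern dataset from sequences
#'
#' Slides a window of length l (stride 1 by default) over each sequence;
#' windows never span records. Provenance records the sequence id and the
#' 0-based window start; dataset order is record order, then offset order.
#'
#' @param seqs named character vector of cleaned sequences (as from
#'   \code{\link{loadFasta}}).
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param stride window stride in bases.
#' @return a \code{\link{PatternDataset}}.
#' @export
extractPatterns <- function(seqs, condition, stride = 1L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  l <- condition@l
  pats <- character(0); ids <- character(0); offs <- integer(0)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[[i]])
    if (n < l) next
    starts <- seq.int(1L, n - l + 1L, by = stride)
    pats <- c(pats, substring(seqs[[i]], starts, starts + l - 1L))
    ids <- c(ids, rep.int(names(seqs)[i], length(starts)))
    offs <- c(offs, starts - 1L)
  }
  new("PatternDataset", patterns = pats, seqId = ids,
      offset = as.integer(offs), condition = condition)
}

#' Split a view into two halves
#'
#' The left half takes \code{ceiling(size / 2)} patterns, the right the
#' remainder; the halves are disjoint, ordered and cover the view. No
#' pattern data is touched.
#'
#' @param view a \code{\link{patternView}} of size >= 2.
#' @return list with elements \code{left} and \code{right}.
#' @export
splitView <- function(view) {
  size <- viewSize(view)
  if (size < 2L) stop("cannot split a view of size < 2")
  mid <- view@begin + as.integer(ceiling(size / 2))
  list(left = patternView(view@begin, mid), right = patternView(mid, view@end))
}

#' Read a plain pattern-list file
#'
#' One l-mer per line; lines are cleaned (upper-cased, non-ACGT to 'A') and
#' must all share one length.
#'
#' @param path text file path.
#' @param d mismatch tolerance recorded in the returned dataset's condition.
#' @return a \code{\link{PatternDataset}} with synthetic provenance (line
#'   order).
#' @export
readPatternList <- function(path, d = 0L) {
  lines <- readLines(path)
  lines <- cleanSequence(lines[nzchar(lines)])
  if (length(lines) == 0L) stop("empty pattern list")
  if (length(unique(nchar(lines))) != 1L)
    stop("pattern list lines must all have the same length")
  PatternDataset(lines, DiscoveryCondition(nchar(lines[1L]), d))
}

#' Write the patterns of a dataset, one per line
#'
#' @param dataset a \code{\link{PatternDataset}}.
#' @param path output path.
#' @export
writePatternList <- function(dataset, path) {
  writeLines(dataset@patterns, path)
}

#' Write a signature set as TSV
#'
#' Columns: signature, sequence_id, offset (0-based).
#'
#' @param x a \code{\link{SignatureSet}}.
#' @param path output path.
#' @export
writeSignatureTSV <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a signature set as FASTA
#'
#' Headers are \code{<sequence_id>:<offset>}.
#'
#' @inheritParams writeSignatureTSV
#' @export
writeSignatureFasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x@patterns)
  names(s) <- sprintf("%s:%d", x@seqId, x@offset)
  Biostrings::writeXStringSet(s, path)
}
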