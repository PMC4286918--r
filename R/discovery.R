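#' Build the segment-group index of a candidate set
#'
#' Every candidate is inserted into exactly \code{beta} groups, keyed by its
#' own segments; groups without candidates are never stored. Source patterns
#' are later funnelled into these groups (and only these) by
#' \code{\link{assignChunkToGroups}}.
#'
#' @param candidates character vector of l-patterns (the candidate set Xi).
#' @param scheme a \code{\link{segmentScheme}}.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @return A group index: an environment mapping key strings
#'   \code{"<segment>:<upsilon>"} to lists with elements \code{cand}
#'   (candidate positions), \code{src} (source positions in the current
#'   chunk) and \code{srcDist} (known segment mismatches per source member).
#' @export
buildCandidateIndex <- function(candidates, scheme, condition) {
  if (scheme@l != condition@l)
    stop("segment scheme does not match the discovery condition")
  idx <- new.env(parent = emptyenv())
  for (c in seq_along(candidates)) {
    keys <- groupKeyStrings(candidateGroupKeys(candidates[c], scheme))
    for (k in keys) {
      g <- if (exists(k, envir = idx, inherits = FALSE))
        get(k, envir = idx) else list(cand = integer(0), src = integer(0),
                                      srcDist = integer(0))
      g$cand <- c(g$cand, c)
      assign(k, g, envir = idx)
    }
  }
  idx
}

#' Split a source view into ordered chunks
#'
#' The source is streamed in contiguous chunks of at most \code{chunkBudget}
#' patterns so that arbitrarily large sources are processed under a fixed
#' memory envelope; all but the last chunk are full.
#'
#' @param n number of source patterns (or a character vector, whose length is
#'   used).
#' @param chunkBudget positive chunk size in patterns (\code{Inf} for a
#'   single chunk).
#' @return list of integer index vectors partitioning \code{1:n} in order.
#' @export
streamSourceChunks <- function(n, chunkBudget) {
  if (is.character(n)) n <- length(n)
  if (chunkBudget < 1) stop("chunkBudget must be >= 1")
  if (n == 0L) return(list())
  if (!is.finite(chunkBudget)) chunkBudget <- n
  starts <- seq.int(1L, n, by = chunkBudget)
  lapply(starts, function(s) s:min(n, s + chunkBudget - 1L))
}

#' Assign a source chunk to the stored groups
#'
#' Each source pattern joins every stored group whose key lies in its
#' segment-wise Hamming balls; keys absent from the candidate index are
#' skipped, so candidate-free groups cost nothing.
#'
#' @param index a group index from \code{\link{buildCandidateIndex}}
#'   (modified in place).
#' @param chunk character vector of source patterns.
#' @param chunkIdx positions of the chunk members in the full source
#'   (defaults to \code{seq_along(chunk)}).
#' @inheritParams buildCandidateIndex
#' @return the index, invisibly.
#' @export
assignChunkToGroups <- function(index, chunk, scheme, condition,
                                chunkIdx = seq_along(chunk)) {
  for (j in seq_along(chunk)) {
    keys <- sourceGroupKeys(chunk[j], scheme, condition)
    ks <- groupKeyStrings(keys)
    for (r in seq_along(ks)) {
      if (!exists(ks[r], envir = index, inherits = FALSE)) next
      g <- get(ks[r], envir = index)
      g$src <- c(g$src, chunkIdx[j])
      g$srcDist <- c(g$srcDist, keys$dist[r])
      assign(ks[r], g, envir = index)
    }
  }
  invisible(index)
}

#' Compare one populated group
#'
#' Scans the group's candidate members against its source members and
#' returns the candidates proven non-unique, i.e. those with an
#' (l,d)-similar source member. In self mode a candidate is never compared
#' against its own occurrence (same occurrence id); two distinct occurrences
#' of an identical string do eliminate each other.
#'
#' @param group a group record (list with \code{cand} and \code{src}).
#' @param candidates,source the full candidate/source pattern vectors.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param selfMode logical; when \code{TRUE}, pairs with equal occurrence
#'   ids are skipped.
#' @param candIds,srcIds occurrence ids (defaults: positions).
#' @param stats optional environment with counters \code{stringComparisons},
#'   \code{characterComparisons}, \code{groupsProcessed}, updated in place.
#' @return integer vector of candidate positions proven non-unique.
#' @export
processGroup <- function(group, candidates, source, condition,
                         selfMode = FALSE,
                         candIds = seq_along(candidates),
                         srcIds = seq_along(source), stats = NULL) {
  killed <- integer(0)
  for (c in group$cand) {
    for (s in group$src) {
      if (selfMode && candIds[c] == srcIds[s]) next
      if (!is.null(stats)) {
        stats$stringComparisons <- stats$stringComparisons + 1
        stats$characterComparisons <- stats$characterComparisons +
          condition@l  # R path compares full strings; bound via C++ engine
      }
      if (cpp_hamming(candidates[c], source[s]) <= condition@d) {
        killed <- c(killed, c)
        break
      }
    }
  }
  if (!is.null(stats)) stats$groupsProcessed <- stats$groupsProcessed + 1
  killed
}

#' Discovery routine: unique candidates of Xi in the source Theta
#'
#' The core filtered search. Candidates are indexed by their exact segments;
#' the source is streamed in chunks, each chunk's patterns fan out to the
#' stored groups through their segment Hamming balls, and only group-mates
#' are ever compared. A candidate with an (l,d)-similar source occurrence
#' (other than its own occurrence) is deleted immediately; the survivors are
#' exactly the candidates unique in the source, independent of chunking,
#' worker count and group order.
#'
#' @param candidates,source character vectors of l-patterns.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param scheme a \code{\link{segmentScheme}}; default
#'   \code{segmentScheme(condition)}.
#' @param chunkBudget source patterns ingested per chunk (default: all).
#' @param workers worker slices per chunk (output-invariant).
#' @param candIds,srcIds occurrence ids; when both are \code{NULL}, the
#'   routine runs in self mode if \code{candidates} and \code{source} are
#'   the identical vector, otherwise ids are made disjoint.
#' @param engine \code{"cpp"} (fast path) or \code{"r"} (reference path
#'   composed from the exported group operations); both give identical sets.
#' @return list with \code{unique} (positions into \code{candidates}),
#'   \code{uniquePatterns}, and \code{stats} (string/character comparison
#'   and group counters plus index size).
#' @examples
#' cond <- DiscoveryCondition(4, 1)
#' x <- c("ACGT", "ACGA", "TTTT")
#' discoveryRoutine(x, x, cond)$uniquePatterns
#' @export
discoveryRoutine <- function(candidates, source, condition, scheme = NULL,
                             chunkBudget = Inf, workers = 1L,
                             candIds = NULL, srcIds = NULL,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(scheme)) scheme <- segmentScheme(condition)
  if (scheme@l != condition@l)
    stop("segment scheme does not match the discovery condition")
  if (length(candidates) &&
      any(nchar(candidates) != condition@l) ||
      length(source) && any(nchar(source) != condition@l))
    stop("all patterns must have length l")
  selfMode <- TRUE
  if (is.null(candIds) && is.null(srcIds)) {
    if (identical(candidates, source)) {
      candIds <- seq_along(candidates)
      srcIds <- seq_along(source)
    } else {
      candIds <- seq_along(candidates)
      srcIds <- length(candidates) + seq_along(source)
    }
  } else if (is.null(candIds) || is.null(srcIds)) {
    stop("provide both candIds and srcIds, or neither")
  }
  budgets <- vapply(scheme@segmentLengths, segmentBudget, integer(1),
                    condition = condition)
  if (engine == "cpp") {
    res <- cpp_discover(candidates, source, as.integer(candIds),
                        as.integer(srcIds), condition@l, condition@d,
                        scheme@segmentLengths, budgets,
                        as.numeric(chunkBudget), as.integer(workers),
                        selfMode)
    stats <- list(stringComparisons = res$string_comparisons,
                  characterComparisons = res$character_comparisons,
                  groupsProcessed = res$groups_processed,
                  indexKeys = res$index_keys,
                  chunks = length(streamSourceChunks(length(source),
                                                     chunkBudget)))
    unique_ <- res$unique
  } else {
    stats_env <- new.env()
    stats_env$stringComparisons <- 0
    stats_env$characterComparisons <- 0
    stats_env$groupsProcessed <- 0
    alive <- rep(TRUE, length(candidates))
    index <- buildCandidateIndex(candidates, scheme, condition)
    nkeys <- length(ls(index))
    chunks <- streamSourceChunks(length(source), chunkBudget)
    for (chunk in chunks) {
      # fresh source membership per chunk
      for (k in ls(index)) {
        g <- get(k, envir = index)
        g$src <- integer(0)
        g$srcDist <- integer(0)
        assign(k, g, envir = index)
      }
      assignChunkToGroups(index, source[chunk], scheme, condition,
                          chunkIdx = chunk)
      for (k in sort(ls(index))) {
        g <- get(k, envir = index)
        g$cand <- g$cand[alive[g$cand]]
        if (length(g$cand) == 0L || length(g$src) == 0L) next
        killed <- processGroup(g, candidates, source, condition,
                               selfMode = selfMode, candIds = candIds,
                               srcIds = srcIds, stats = stats_env)
        alive[killed] <- FALSE
      }
    }
    unique_ <- which(alive)
    stats <- list(stringComparisons = stats_env$stringComparisons,
                  characterComparisons = stats_env$characterComparisons,
                  groupsProcessed = stats_env$groupsProcessed,
                  indexKeys = nkeys, chunks = length(chunks))
  }
  list(unique = unique_, uniquePatterns = candidates[unique_], stats = stats)
}
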