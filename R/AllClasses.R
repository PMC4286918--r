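#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SigDiscovery, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Discovery condition (l, d)
#'
#' A discovery condition is the pair of the signature length \code{l} and the
#' number of allowed mismatches \code{d}. A pattern is a signature when no
#' other pattern in the database lies within Hamming distance \code{d} of it.
#'
#' @slot l integer, pattern length in bases.
#' @slot d integer, allowed mismatches, \code{0 <= d < l}.
#' @aliases DiscoveryCondition-class
#' @export
setClass("DiscoveryCondition",
         representation(l = "integer", d = "integer"),
         validity = function(object) {
           if (length(object@l) != 1L || length(object@d) != 1L)
             return("l and d must be single integers")
           if (is.na(object@l) || object@l < 1L)
             return("l must be a positive integer")
           if (is.na(object@d) || object@d < 0L || object@d >= object@l)
             return("d must satisfy 0 <= d < l")
           TRUE
         })

#' @param l pattern length in bases.
#' @param d allowed mismatches.
#' @return A \code{DiscoveryCondition} object.
#' @examples
#' DiscoveryCondition(8, 1)
#' @rdname DiscoveryCondition-class
#' @export
DiscoveryCondition <- function(l, d) {
  new("DiscoveryCondition", l = as.integer(l), d = as.integer(d))
}

#' @param x,object a \code{DiscoveryCondition}.
#' @rdname DiscoveryCondition-class
#' @export
patternLength <- function(x) x@l

#' @rdname DiscoveryCondition-class
#' @export
mismatchTolerance <- function(x) x@d

setMethod("show", "DiscoveryCondition", function(object) {
  cat(sprintf("DiscoveryCondition (l = %d, d = %d)\n", object@l, object@d))
})

#' Segmentation scheme for the pigeonhole filter
#'
#' An l-pattern is cut into \code{beta = ceiling(l / gamma)} non-overlapping
#' segments: the first \code{beta - 1} of length \code{gamma} and a final
#' segment holding the remainder. Each segment \code{i} carries a mismatch
#' budget \code{floor(len_i * d / l)}; any two (l,d)-similar patterns must
#' agree within budget on at least one segment, which is what makes
#' group-restricted comparison lossless.
#'
#' @slot l integer, pattern length.
#' @slot gamma integer, nominal segment length.
#' @slot beta integer, number of segments, \code{ceiling(l / gamma)}.
#' @slot segmentLengths integer vector of the \code{beta} segment lengths,
#'   summing to \code{l}.
#' @aliases SegmentScheme-class
#' @export
setClass("SegmentScheme",
         representation(l = "integer", gamma = "integer", beta = "integer",
                        segmentLengths = "integer"),
         validity = function(object) {
           if (object@gamma < 1L || object@gamma > object@l)
             return("gamma must be in [1, l]")
           if (object@beta != ceiling(object@l / object@gamma))
             return("beta must equal ceiling(l / gamma)")
           if (sum(object@segmentLengths) != object@l)
             return("segment lengths must sum to l")
           if (any(object@segmentLengths < 1L))
             return("segment lengths must be positive")
           TRUE
         })

#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param gamma segment length; defaults to \code{ceiling(l / 2)}, the choice
#'   with maximal filtering power. Any value in \code{[1, l]} is accepted;
#'   see \code{\link{recommendedGammaRange}} for the memory/speed trade-off
#'   range.
#' @param strict if \code{TRUE}, error when \code{gamma} lies outside
#'   \code{recommendedGammaRange(condition)}.
#' @return A \code{SegmentScheme}.
#' @examples
#' segmentScheme(DiscoveryCondition(12, 2), gamma = 5)
#' @rdname SegmentScheme-class
#' @export
segmentScheme <- function(condition, gamma = NULL, strict = FALSE) {
  l <- condition@l
  if (is.null(gamma)) gamma <- ceiling(l / 2)
  gamma <- as.integer(gamma)
  if (length(gamma) != 1L || is.na(gamma) || gamma < 1L || gamma > l)
    stop("gamma must be a single integer in [1, l]")
  if (strict) {
    rng <- recommendedGammaRange(condition)
    if (gamma < rng[1L] || gamma > rng[2L])
      stop(sprintf("gamma = %d outside the recommended range [%d, %d] for (l = %d, d = %d)",
                   gamma, rng[1L], rng[2L], l, condition@d))
  }
  beta <- as.integer(ceiling(l / gamma))
  lens <- rep.int(gamma, beta)
  lens[beta] <- l - (beta - 1L) * gamma
  new("SegmentScheme", l = l, gamma = gamma, beta = beta,
      segmentLengths = as.integer(lens))
}

#' @rdname SegmentScheme-class
#' @export
segmentCount <- function(x) x@beta

#' @rdname SegmentScheme-class
#' @export
segmentLengths <- function(x) x@segmentLengths

#' Recommended segment-length range
#'
#' The trade-off range for \code{gamma}: larger values compare fewer strings
#' but need more group memory. The nominal lower bound
#' \code{ceiling(l / (d + 1))} can exceed the upper bound
#' \code{ceiling(l / 2)} when \code{d} is very small (for \code{d = 0} the
#' nominal range is empty); the range is clamped so it always contains
#' \code{ceiling(l / 2)}. Completeness of the filter holds for any
#' \code{gamma} in \code{[1, l]} thanks to the length-proportional segment
#' budgets.
#'
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @return integer vector \code{c(lower, upper)}.
#' @export
recommendedGammaRange <- function(condition) {
  hi <- as.integer(ceiling(condition@l / 2))
  lo <- as.integer(ceiling(condition@l / (condition@d + 1)))
  c(min(lo, hi), hi)
}

setMethod("show", "SegmentScheme", function(object) {
  cat(sprintf("SegmentScheme: l = %d, gamma = %d, beta = %d (segment lengths %s)\n",
              object@l, object@gamma, object@beta,
              paste(object@segmentLengths, collapse = ",")))
})

#' Ordered dataset of fixed-length DNA patterns with provenance
#'
#' The pattern dataset Lambda: every pattern has length \code{l} and carries
#' its origin (source sequence id and 0-based offset). Index ranges into the
#' dataset are addressed through lightweight \code{\link{PatternView}}s so
#' that the recursive partitioning never copies pattern data.
#'
#' @slot patterns character vector of l-mers over A/C/G/T.
#' @slot seqId character vector, source sequence id per pattern.
#' @slot offset integer vector, 0-based start offset per pattern.
#' @slot condition the \code{\link{DiscoveryCondition}}.
#' @aliases PatternDataset-class
#' @export
setClass("PatternDataset",
         representation(patterns = "character", seqId = "character",
                        offset = "integer", condition = "DiscoveryCondition"),
         validity = function(object) {
           n <- length(object@patterns)
           if (length(object@seqId) != n || length(object@offset) != n)
             return("patterns, seqId and offset must have equal length")
           if (n > 0L) {
             w <- unique(nchar(object@patterns))
             if (length(w) > 1L || w != object@condition@l)
               return("all patterns must have length l")
             if (any(grepl("[^ACGT]", object@patterns)))
               return("patterns must be over {A,C,G,T}")
           }
           TRUE
         })

#' @param patterns character vector of l-mers.
#' @param condition a \code{\link{DiscoveryCondition}}; inferred from the
#'   first pattern's width (with \code{d = 0}) when missing.
#' @param seqId,offset provenance; default \code{"synthetic"} ids and the
#'   0-based position in the vector.
#' @return A \code{PatternDataset}.
#' @examples
#' PatternDataset(c("ACGT", "ACGA", "TTTT"), DiscoveryCondition(4, 1))
#' @rdname PatternDataset-class
#' @export
PatternDataset <- function(patterns, condition = NULL,
                           seqId = NULL, offset = NULL) {
  patterns <- as.character(patterns)
  if (is.null(condition)) {
    if (length(patterns) == 0L)
      stop("condition is required for an empty dataset")
    condition <- DiscoveryCondition(nchar(patterns[1L]), 0L)
  }
  if (is.null(seqId)) seqId <- rep.int("synthetic", length(patterns))
  if (is.null(offset)) offset <- seq_along(patterns) - 1L
  new("PatternDataset", patterns = patterns, seqId = as.character(seqId),
      offset = as.integer(offset), condition = condition)
}

#' @param x,object a \code{PatternDataset}.
#' @rdname PatternDataset-class
#' @export
setMethod("length", "PatternDataset", function(x) length(x@patterns))

#' @rdname PatternDataset-class
#' @export
patterns <- function(x) x@patterns

#' @rdname PatternDataset-class
#' @export
provenance <- function(x) {
  data.frame(seqId = x@seqId, offset = x@offset, stringsAsFactors = FALSE)
}

#' @rdname PatternDataset-class
#' @export
condition <- function(x) x@condition

setMethod("show", "PatternDataset", function(object) {
  cat(sprintf("PatternDataset: %d pattern(s) of length %d (d = %d)\n",
              length(object@patterns), object@condition@l,
              object@condition@d))
  if (length(object@patterns) > 0L) {
    k <- min(5L, length(object@patterns))
    cat(sprintf("  [%d] %s @ %s:%d\n", seq_len(k),
                object@patterns[seq_len(k)], object@seqId[seq_len(k)],
                object@offset[seq_len(k)]), sep = "")
    if (length(object@patterns) > k) cat("  ...\n")
  }
})

#' Half-open index range into a pattern dataset
#'
#' A view is the pair (begin, end) of 0-based half-open dataset indices; the
#' recursive main routine only manipulates views ("the beginning and ending
#' position") and materializes pattern data per discovery task.
#'
#' @slot begin,end 0-based half-open bounds.
#' @aliases PatternView-class
#' @export
setClass("PatternView",
         representation(begin = "integer", end = "integer"),
         validity = function(object) {
           if (object@begin < 0L || object@end < object@begin)
             return("need 0 <= begin <= end")
           TRUE
         })

#' @param begin,end 0-based half-open bounds.
#' @rdname PatternView-class
#' @export
patternView <- function(begin, end) {
  new("PatternView", begin = as.integer(begin), end = as.integer(end))
}

#' @param x,object a \code{PatternView} (or \code{PatternDataset} for
#'   \code{fullView}).
#' @rdname PatternView-class
#' @export
viewSize <- function(x) x@end - x@begin

#' @rdname PatternView-class
#' @export
fullView <- function(x) patternView(0L, length(x))

#' @param dataset a \code{\link{PatternDataset}}.
#' @return \code{viewIndices} returns the 1-based dataset indices covered by
#'   the view.
#' @rdname PatternView-class
#' @export
viewIndices <- function(dataset, x) {
  if (x@end > length(dataset)) stop("view exceeds dataset size")
  if (x@end == x@begin) integer(0) else (x@begin + 1L):x@end
}

setMethod("show", "PatternView", function(object) {
  cat(sprintf("PatternView [%d, %d) size %d\n", object@begin, object@end,
              viewSize(object)))
})

#' Set of discovered signatures with provenance
#'
#' The output Omega of a discovery run: the patterns of a dataset (or view)
#' that have no other (l,d)-similar occurrence in the searched source.
#' \code{index} keeps the 1-based position of each signature occurrence in
#' the originating dataset, which makes occurrence-disjointness of partial
#' results checkable when they are combined.
#'
#' @slot patterns,seqId,offset as in \code{\link{PatternDataset}}.
#' @slot index integer, 1-based occurrence index in the source dataset.
#' @slot condition the \code{\link{DiscoveryCondition}} used.
#' @slot metadata list, run report (task table, comparison counters) when the
#'   set was produced by \code{\link{mainRoutine}}.
#' @aliases SignatureSet-class
#' @export
setClass("SignatureSet",
         representation(patterns = "character", seqId = "character",
                        offset = "integer", index = "integer",
                        condition = "DiscoveryCondition", metadata = "list"),
         validity = function(object) {
           n <- length(object@patterns)
           if (length(object@seqId) != n || length(object@offset) != n ||
               length(object@index) != n)
             return("parallel slots must have equal length")
           if (anyDuplicated(object@index))
             return("duplicate occurrence indices in a signature set")
           TRUE
         })

SignatureSet <- function(patterns, seqId, offset, index, condition,
                         metadata = list()) {
  new("SignatureSet", patterns = as.character(patterns),
      seqId = as.character(seqId), offset = as.integer(offset),
      index = as.integer(index), condition = condition, metadata = metadata)
}

#' @param x,object a \code{SignatureSet}.
#' @rdname SignatureSet-class
#' @export
setMethod("length", "SignatureSet", function(x) length(x@patterns))

#' @rdname SignatureSet-class
#' @export
signatures <- function(x) x@patterns

#' @rdname SignatureSet-class
#' @export
runReport <- function(x) x@metadata

#' @param dataset the originating \code{\link{PatternDataset}}.
#' @param idx 1-based occurrence indices of the signatures in \code{dataset}.
#' @param metadata optional run report list.
#' @return \code{signatureSetFromIndices} assembles a \code{SignatureSet}
#'   from dataset occurrence indices.
#' @rdname SignatureSet-class
#' @export
signatureSetFromIndices <- function(dataset, idx, metadata = list()) {
  idx <- sort(as.integer(idx))
  SignatureSet(dataset@patterns[idx], dataset@seqId[idx],
               dataset@offset[idx], idx, dataset@condition, metadata)
}

#' @rdname SignatureSet-class
#' @export
as.data.frame.SignatureSet <- function(x, ...) {
  data.frame(signature = x@patterns, sequence_id = x@seqId,
             offset = x@offset, stringsAsFactors = FALSE)
}

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d signature(s) under (l = %d, d = %d)\n",
              length(object@patterns), object@condition@l,
              object@condition@d))
  k <- min(5L, length(object@patterns))
  if (k > 0L)
    cat(sprintf("  %s @ %s:%d\n", object@patterns[seq_len(k)],
                object@seqId[seq_len(k)], object@offset[seq_len(k)]),
        sep = "")
  if (length(object@patterns) > k) cat("  ...\n")
})

#' Discovery-task DAG
#'
#' The main routine's recursion is materialized as an explicit list of
#' discovery tasks. A self task DR(view, view) finds the signatures of a
#' partition directly; a cross task DR(result-of(tasks), view) filters a
#' previously discovered signature set against the sibling partition. Cross
#' tasks depend on the tasks producing their candidate set; task order is
#' creation order and doubles as scheduling priority.
#'
#' @slot tasks list of task records (id, type, candidate/source references,
#'   dependency ids).
#' @slot ids character vector of task ids in creation (priority) order.
#' @aliases TaskDAG-class
#' @export
setClass("TaskDAG",
         representation(tasks = "list", ids = "character"),
         validity = function(object) {
           if (length(object@tasks) != length(object@ids))
             return("ids must parallel tasks")
           if (anyDuplicated(object@ids)) return("duplicate task ids")
           seen <- character(0)
           for (t in object@tasks) {
             if (!all(t$deps %in% seen))
               return("dependency on a later or unknown task (cycle)")
             seen <- c(seen, t$id)
           }
           TRUE
         })

#' @param x,object a \code{TaskDAG}.
#' @rdname TaskDAG-class
#' @export
taskIds <- function(x) x@ids

#' @rdname TaskDAG-class
#' @export
taskCount <- function(x) length(x@ids)

#' @return \code{taskTable} returns one row per task: id, type (self/cross),
#'   candidate and source descriptions, and comma-separated dependencies.
#' @rdname TaskDAG-class
#' @export
taskTable <- function(x) {
  do.call(rbind, lapply(x@tasks, function(t) {
    cand <- if (t$type == "self")
      sprintf("[%d,%d)", t$candView@begin, t$candView@end)
    else sprintf("result(%s)", paste(t$candTasks, collapse = "+"))
    data.frame(id = t$id, type = t$type, candidate = cand,
               source = sprintf("[%d,%d)", t$srcView@begin, t$srcView@end),
               depends_on = paste(t$deps, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "TaskDAG", function(object) {
  cat(sprintf("TaskDAG with %d task(s)\n", length(object@ids)))
  print(taskTable(object), row.names = FALSE)
})

#' Schedule of discovery tasks on worker nodes
#'
#' @slot entries data.frame with columns task, node, start, finish.
#' @slot makespan numeric, finish time of the last task (seconds).
#' @slot nodeCount integer.
#' @aliases Schedule-class
#' @export
setClass("Schedule",
         representation(entries = "data.frame", makespan = "numeric",
                        nodeCount = "integer"))

#' @param x,object a \code{Schedule}.
#' @rdname Schedule-class
#' @export
makespan <- function(x) x@makespan

#' @rdname Schedule-class
#' @export
scheduleEntries <- function(x) x@entries

setMethod("show", "Schedule", function(object) {
  cat(sprintf("Schedule on %d node(s), makespan %g s\n", object@nodeCount,
              object@makespan))
  print(object@entries, row.names = FALSE)
})

#' Run configuration for the main routine
#'
#' @slot condition a \code{\link{DiscoveryCondition}}.
#' @slot thresholdN numeric, direct-discovery threshold in patterns (may be
#'   \code{Inf}): a partition of at most N patterns becomes a single
#'   discovery task; larger partitions are halved recursively. In the
#'   original setting N is chosen so one partition fits a worker's memory.
#' @slot scheme a \code{\link{SegmentScheme}}.
#' @slot chunkBudget numeric, source patterns loaded per chunk in the
#'   discovery routine (defaults to \code{thresholdN}).
#' @slot nodeCount integer, concurrent discovery workers.
#' @slot seed integer.
#' @aliases RunConfig-class
#' @export
setClass("RunConfig",
         representation(condition = "DiscoveryCondition",
                        thresholdN = "numeric", scheme = "SegmentScheme",
                        chunkBudget = "numeric", nodeCount = "integer",
                        seed = "integer"),
         validity = function(object) {
           if (is.na(object@thresholdN) || object@thresholdN < 1)
             return("thresholdN must be >= 1")
           if (object@chunkBudget < 1) return("chunkBudget must be >= 1")
           if (object@nodeCount < 1L) return("nodeCount must be >= 1")
           TRUE
         })

#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param thresholdN direct-discovery threshold, in patterns; \code{Inf}
#'   disables partitioning.
#' @param scheme a \code{\link{SegmentScheme}}; default
#'   \code{segmentScheme(condition)}.
#' @param chunkBudget source chunk size in patterns; default
#'   \code{thresholdN}.
#' @param nodeCount number of discovery workers.
#' @param seed integer seed recorded with the run.
#' @rdname RunConfig-class
#' @export
runConfig <- function(condition, thresholdN = Inf, scheme = NULL,
                      chunkBudget = NULL, nodeCount = 1L, seed = 1L) {
  if (is.null(scheme)) scheme <- segmentScheme(condition)
  if (is.null(chunkBudget)) chunkBudget <- thresholdN
  new("RunConfig", condition = condition, thresholdN = as.numeric(thresholdN),
      scheme = scheme, chunkBudget = as.numeric(chunkBudget),
      nodeCount = as.integer(nodeCount), seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig: (l = %d, d = %d), N = %s, gamma = %d, chunk = %s, nodes = %d, seed = %d\n",
              object@condition@l, object@condition@d,
              format(object@thresholdN), object@scheme@gamma,
              format(object@chunkBudget), object@nodeCount, object@seed))
})
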