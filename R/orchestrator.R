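taskLabel <- function(k) {
  if (k <= length(LETTERS)) LETTERS[k] else paste0("T", k)
}

#' Build the discovery-task DAG for a dataset view
#'
#' Realizes the divide-and-conquer main routine as an explicit task list. A
#' view of at most N patterns yields one self-discovery task DR(view, view).
#' A larger view is halved; the left then the right half are expanded
#' depth-first, after which two cross tasks are appended: the left result
#' filtered against the right half and the right result against the left
#' half. Cross tasks depend on the tasks producing their candidate set.
#' Labels A, B, C, ... follow creation order, which is also scheduling
#' priority. A view of size \code{2^k * N} yields \code{3 * 2^k - 2} tasks.
#'
#' @param view a non-empty \code{\link{patternView}} over the dataset.
#' @param config a \code{\link{runConfig}} (only \code{thresholdN} is used
#'   here).
#' @return a \code{\link{TaskDAG-class}} whose final two tasks (or single
#'   task) produce the view's signature set.
#' @examples
#' dag <- buildTaskDag(patternView(0, 100), runConfig(DiscoveryCondition(8, 1),
#'                     thresholdN = 25))
#' taskTable(dag)
#' @export
buildTaskDag <- function(view, config) {
  if (viewSize(view) < 1L) stop("empty view")
  tasks <- list()
  counter <- 0L
  emit <- function(task) {
    counter <<- counter + 1L
    task$id <- taskLabel(counter)
    tasks[[counter]] <<- task
    task$id
  }
  # returns the ids of the tasks whose union is the view's signature set
  build <- function(v) {
    if (viewSize(v) <= config@thresholdN) {
      id <- emit(list(type = "self", candView = v, candTasks = character(0),
                      srcView = v, deps = character(0)))
      return(id)
    }
    halves <- splitView(v)
    leftProducers <- build(halves$left)
    rightProducers <- build(halves$right)
    crossL <- emit(list(type = "cross", candView = NULL,
                        candTasks = leftProducers, srcView = halves$right,
                        deps = leftProducers))
    crossR <- emit(list(type = "cross", candView = NULL,
                        candTasks = rightProducers, srcView = halves$left,
                        deps = rightProducers))
    c(crossL, crossR)
  }
  build(view)
  new("TaskDAG", tasks = tasks,
      ids = vapply(tasks, `[[`, character(1), "id"))
}

#' Combine two occurrence-disjoint signature sets
#'
#' The union step of the main routine: the two cross-filtered partial sets
#' cover disjoint partitions, so their union needs no deduplication; an
#' occurrence overlap indicates an internal error and is rejected.
#'
#' @param left,right \code{\link{SignatureSet-class}} objects over the same
#'   dataset.
#' @return the combined \code{SignatureSet}, ordered by occurrence index.
#' @export
combineSignatures <- function(left, right) {
  if (length(intersect(left@index, right@index)) > 0L)
    stop("internal consistency error: overlapping occurrences in combine")
  ord <- order(c(left@index, right@index))
  SignatureSet(c(left@patterns, right@patterns)[ord],
               c(left@seqId, right@seqId)[ord],
               c(left@offset, right@offset)[ord],
               c(left@index, right@index)[ord],
               left@condition)
}

# materialize a task's candidate occurrence indices (global, 1-based)
taskCandidateIndices <- function(task, dataset, results) {
  if (task$type == "self") viewIndices(dataset, task$candView)
  else sort(unlist(lapply(task$deps, function(id) results[[id]]$indices),
                   use.names = FALSE))
}

# run one discovery task; returns list(indices, stats)
runTask <- function(task, dataset, config) {
  candIdx <- task$candIdx
  srcIdx <- viewIndices(dataset, task$srcView)
  res <- discoveryRoutine(dataset@patterns[candIdx],
                          dataset@patterns[srcIdx],
                          config@condition, config@scheme,
                          chunkBudget = config@chunkBudget,
                          candIds = candIdx, srcIds = srcIdx)
  list(indices = candIdx[res$unique], stats = res$stats,
       candIn = length(candIdx), srcSize = length(srcIdx))
}

#' Discover all signatures of a pattern dataset
#'
#' The divide-and-conquer main routine: builds the task DAG for the full
#' dataset, executes it under the dependency-respecting scheduler with up to
#' \code{nodeCount} concurrent workers, and unions the final partial sets.
#' The result is exactly the set of patterns with no other (l,d)-similar
#' occurrence in the dataset, for any threshold N, worker count and source
#' chunking.
#'
#' @param dataset a \code{\link{PatternDataset}}.
#' @param config a \code{\link{runConfig}}; its condition must match the
#'   dataset's pattern length.
#' @return a \code{\link{SignatureSet-class}}; \code{runReport()} on it
#'   gives the task table with per-task comparison counters and totals.
#' @examples
#' d <- PatternDataset(c("ACGT", "ACGA", "TTTT"), DiscoveryCondition(4, 1))
#' signatures(mainRoutine(d, runConfig(DiscoveryCondition(4, 1))))
#' @export
mainRoutine <- function(dataset, config) {
  if (length(dataset) == 0L)
    return(SignatureSet(character(0), character(0), integer(0), integer(0),
                        config@condition))
  if (dataset@condition@l != config@condition@l)
    stop("dataset pattern length does not match the configured condition")
  dag <- buildTaskDag(fullView(dataset), config)
  exec <- executeDag(dag, dataset, config)
  finalIds <- finalTaskIds(dag)
  idx <- sort(unlist(lapply(finalIds, function(id) exec$results[[id]]$indices),
                     use.names = FALSE))
  perTask <- exec$perTask
  report <- list(
    condition = list(l = config@condition@l, d = config@condition@d),
    gamma = config@scheme@gamma,
    thresholdN = config@thresholdN,
    chunkBudget = config@chunkBudget,
    nodeCount = config@nodeCount,
    seed = config@seed,
    tasks = perTask,
    totals = list(
      stringComparisons = sum(perTask$string_comparisons),
      characterComparisons = sum(perTask$character_comparisons),
      groupsProcessed = sum(perTask$groups_processed),
      patternsMoved = sum(perTask$candidates_in + perTask$source_size),
      taskCount = taskCount(dag),
      signatures = length(idx)))
  signatureSetFromIndices(dataset, idx, metadata = report)
}

# ids of the tasks whose union is the root result (last 2 tasks, or the
# single task of an unsplit dataset)
finalTaskIds <- function(dag) {
  n <- taskCount(dag)
  if (n == 1L) dag@ids else dag@ids[c(n - 1L, n)]
}
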