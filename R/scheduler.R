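#' Ready tasks of a DAG
#'
#' Tasks not yet assigned whose dependencies are all completed, in priority
#' (creation) order.
#'
#' @param dag a \code{\link{TaskDAG-class}}.
#' @param completed character vector of completed task ids.
#' @param assigned character vector of ids already assigned (running or
#'   completed).
#' @return character vector of ready task ids.
#' @export
readyTasks <- function(dag, completed = character(0),
                       assigned = character(0)) {
  done <- unique(c(assigned, completed))
  ok <- vapply(dag@tasks, function(t)
    !(t$id %in% done) && all(t$deps %in% completed), logical(1))
  dag@ids[ok]
}

#' Simulate the greedy list schedule of a task DAG
#'
#' Event-driven simulation of the cluster dispatch discipline: whenever a
#' node is free, it immediately takes the highest-priority ready task; ties
#' between simultaneously free nodes go to the lowest node index. No
#' preemption, no transfer costs. The result is deterministic.
#'
#' @param dag a \code{\link{TaskDAG-class}}.
#' @param durations named numeric vector of per-task durations in seconds;
#'   names must cover exactly the DAG's task ids.
#' @param nodeCount number of discovery nodes.
#' @return a \code{\link{Schedule-class}} with per-task node assignment,
#'   start/finish times and the makespan.
#' @examples
#' dag <- buildTaskDag(patternView(0, 100), runConfig(DiscoveryCondition(8, 1),
#'                     thresholdN = 25))
#' durs <- c(A = 1, B = 3, C = 4, D = 6, E = 2, F = 1, G = 4, H = 2, I = 4,
#'           J = 3)
#' makespan(simulateSchedule(dag, durs, 2))
#' @export
simulateSchedule <- function(dag, durations, nodeCount) {
  ids <- dag@ids
  if (!all(ids %in% names(durations)))
    stop(sprintf("missing durations for task(s): %s",
                 paste(setdiff(ids, names(durations)), collapse = ", ")))
  extra <- setdiff(names(durations), ids)
  if (length(extra) > 0L)
    stop(sprintf("durations given for unknown task(s): %s",
                 paste(extra, collapse = ", ")))
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be positive and finite")
  nodeCount <- as.integer(nodeCount)

  nodeFree <- rep(TRUE, nodeCount)
  nodeFinish <- rep(NA_real_, nodeCount)
  nodeTask <- rep(NA_character_, nodeCount)
  completed <- character(0)
  assigned <- character(0)
  entries <- data.frame(task = character(0), node = integer(0),
                        start = numeric(0), finish = numeric(0),
                        stringsAsFactors = FALSE)
  t <- 0
  repeat {
    # fill free nodes (lowest index first) with ready tasks by priority
    ready <- readyTasks(dag, completed, assigned)
    for (nd in which(nodeFree)) {
      if (length(ready) == 0L) break
      task <- ready[1L]
      ready <- ready[-1L]
      assigned <- c(assigned, task)
      nodeFree[nd] <- FALSE
      nodeTask[nd] <- task
      nodeFinish[nd] <- t + durations[[task]]
      entries <- rbind(entries,
                       data.frame(task = task, node = nd, start = t,
                                  finish = nodeFinish[nd],
                                  stringsAsFactors = FALSE))
    }
    if (length(completed) == length(ids)) break
    busy <- which(!nodeFree)
    if (length(busy) == 0L)
      stop("scheduler stalled: no running task but work remains")
    t <- min(nodeFinish[busy])
    for (nd in busy[nodeFinish[busy] <= t]) {
      completed <- c(completed, nodeTask[nd])
      nodeFree[nd] <- TRUE
      nodeTask[nd] <- NA_character_
      nodeFinish[nd] <- NA_real_
    }
  }
  new("Schedule", entries = entries, makespan = max(entries$finish),
      nodeCount = nodeCount)
}

#' Execute a task DAG on a local worker pool
#'
#' Runs the discovery tasks under the same dispatch discipline as the
#' simulator: no task starts before its dependencies' results are available;
#' up to \code{nodeCount} ready tasks run concurrently (forked workers on
#' Unix when \code{nodeCount > 1}); results are merged by task id, so the
#' outcome is identical to serial execution.
#'
#' @param dag a \code{\link{TaskDAG-class}}.
#' @param dataset the \code{\link{PatternDataset}} the views refer to.
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{results} (per task id: occurrence indices and
#'   engine stats) and \code{perTask} (a data.frame of per-task counters).
#' @export
executeDag <- function(dag, dataset, config) {
  results <- list()
  completed <- character(0)
  useFork <- config@nodeCount > 1L && .Platform$OS.type == "unix"
  while (length(completed) < taskCount(dag)) {
    ready <- readyTasks(dag, completed, completed)
    if (length(ready) == 0L)
      stop("DAG execution stalled: unsatisfiable dependencies")
    batch <- utils::head(ready, config@nodeCount)
    taskRecs <- lapply(batch, function(id) {
      task <- dag@tasks[[match(id, dag@ids)]]
      task$candIdx <- taskCandidateIndices(task, dataset, results)
      task
    })
    out <- if (useFork) {
      parallel::mclapply(taskRecs, runTask, dataset = dataset,
                         config = config, mc.cores = config@nodeCount)
    } else {
      lapply(taskRecs, runTask, dataset = dataset, config = config)
    }
    for (k in seq_along(batch)) {
      r <- out[[k]]
      if (inherits(r, "try-error") || !is.list(r))
        stop(sprintf("worker failure in task %s", batch[k]))
      results[[batch[k]]] <- r
    }
    completed <- c(completed, batch)
  }
  perTask <- do.call(rbind, lapply(dag@ids, function(id) {
    r <- results[[id]]
    data.frame(task = id,
               candidates_in = r$candIn,
               candidates_out = length(r$indices),
               source_size = r$srcSize,
               chunks = r$stats$chunks,
               string_comparisons = r$stats$stringComparisons,
               character_comparisons = r$stats$characterComparisons,
               groups_processed = r$stats$groupsProcessed,
               stringsAsFactors = FALSE)
  }))
  list(results = results, perTask = perTask)
}
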