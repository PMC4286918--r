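#' Brute-force uniqueness oracle
#'
#' All-pairs Hamming scan with no filtering: the independent reference the
#' segment-group engine is validated against. A candidate is unique when no
#' source occurrence (other than its own occurrence, in self mode) lies
#' within distance d. Intended for small instances.
#'
#' @param candidates,source character vectors of l-patterns.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param candIds,srcIds occurrence ids; defaulting as in
#'   \code{\link{discoveryRoutine}} (self mode when the two vectors are
#'   identical).
#' @return integer positions of the unique candidates.
#' @examples
#' x <- c("ACGT", "ACGA", "TTTT")
#' x[bruteForceUnique(x, x, DiscoveryCondition(4, 1))]
#' @export
bruteForceUnique <- function(candidates, source, condition,
                             candIds = NULL, srcIds = NULL) {
  if (is.null(candIds) && is.null(srcIds)) {
    if (identical(candidates, source)) {
      candIds <- seq_along(candidates)
      srcIds <- seq_along(source)
    } else {
      candIds <- seq_along(candidates)
      srcIds <- length(candidates) + seq_along(source)
    }
  }
  cpp_brute_unique(candidates, source, as.integer(candIds),
                   as.integer(srcIds), condition@l, condition@d, TRUE)
}

#' Brute-force signature oracle
#'
#' The ground truth for equivalence tests: signatures of a dataset are the
#' patterns unique in the dataset itself (own occurrence excluded).
#'
#' @param dataset a \code{\link{PatternDataset}} or character vector.
#' @param condition required when \code{dataset} is a character vector.
#' @return a \code{\link{SignatureSet-class}} when given a dataset, else the
#'   character vector of signature patterns.
#' @export
bruteForceSignatures <- function(dataset, condition = NULL) {
  if (is(dataset, "PatternDataset")) {
    cond <- if (is.null(condition)) dataset@condition else condition
    idx <- cpp_brute_unique(dataset@patterns, dataset@patterns,
                            seq_along(dataset@patterns),
                            seq_along(dataset@patterns),
                            cond@l, cond@d, TRUE)
    signatureSetFromIndices(dataset, idx)
  } else {
    if (is.null(condition)) stop("condition required for a plain vector")
    idx <- cpp_brute_unique(dataset, dataset, seq_along(dataset),
                            seq_along(dataset), condition@l, condition@d,
                            TRUE)
    dataset[idx]
  }
}

#' Generate a uniform random pattern dataset
#'
#' I.i.d. uniform bases, the distribution under which the group index is
#' expected to spread patterns over about \code{4^gamma * beta} groups.
#' Byte-identical for a fixed seed.
#'
#' @param n number of patterns.
#' @param condition a \code{\link{DiscoveryCondition}}.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return a \code{\link{PatternDataset}} with synthetic provenance.
#' @export
generateUniform <- function(n, condition, seed = 1L) {
  stopifnot(n >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  if (n == 0L)
    return(PatternDataset(character(0), condition))
  m <- matrix(sample(DNA_BASES, n * condition@l, replace = TRUE),
              nrow = n)
  PatternDataset(apply(m, 1L, paste, collapse = ""), condition)
}

#' Generate a dataset together with its signature truth
#'
#' Draws a uniform dataset and labels its signatures with the brute-force
#' oracle, giving an exact ground truth for end-to-end tests. (Guaranteeing
#' planted signatures a priori under Hamming balls is a covering problem;
#' generate-then-label is exact and sufficient.)
#'
#' @inheritParams generateUniform
#' @return list with elements \code{dataset} and \code{truth} (a
#'   \code{\link{SignatureSet-class}}).
#' @export
generateWithTruth <- function(n, condition, seed = 1L) {
  dataset <- generateUniform(n, condition, seed)
  list(dataset = dataset, truth = bruteForceSignatures(dataset))
}
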