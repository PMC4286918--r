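cond42 <- DiscoveryCondition(4, 2)
sch42 <- segmentScheme(cond42, 2)

test_that("buildCandidateIndex stores only occupied exact-segment groups", {
  idx <- buildCandidateIndex("ACGT", sch42, cond42)
  expect_setequal(ls(idx), c("1:AC", "2:GT"))
  expect_identical(get("1:AC", envir = idx)$cand, 1L)
  expect_identical(length(ls(buildCandidateIndex(character(0), sch42,
                                                 cond42))), 0L)
  idx2 <- buildCandidateIndex(c("AAAA", "AAAC"), sch42, cond42)
  expect_identical(get("1:AA", envir = idx2)$cand, c(1L, 2L))
})

test_that("streamSourceChunks partitions the source in order", {
  ch <- streamSourceChunks(10, 4)
  expect_identical(lengths(ch), c(4L, 4L, 2L))
  expect_identical(unlist(ch), 1:10)
  expect_identical(length(streamSourceChunks(10, 100)), 1L)
  expect_identical(streamSourceChunks(0, 4), list())
  expect_identical(length(streamSourceChunks(10, Inf)), 1L)
  expect_error(streamSourceChunks(10, 0), ">= 1")
})

test_that("assignChunkToGroups funnels sources through Hamming balls", {
  # 'TGCA' shares no segment ball with the exact segments of 'ACGT'
  idx <- buildCandidateIndex("ACGT", sch42, cond42)
  assignChunkToGroups(idx, "TGCA", sch42, cond42)
  expect_identical(get("1:AC", envir = idx)$src, integer(0))
  expect_identical(get("2:GT", envir = idx)$src, integer(0))
  # an identical pattern joins all beta exact groups
  idx <- buildCandidateIndex("ACGT", sch42, cond42)
  assignChunkToGroups(idx, "ACGT", sch42, cond42)
  expect_identical(get("1:AC", envir = idx)$src, 1L)
  expect_identical(get("2:GT", envir = idx)$src, 1L)
  expect_identical(get("2:GT", envir = idx)$srcDist, 0L)
  # d = 0: membership iff segments match exactly
  cond0 <- DiscoveryCondition(4, 0)
  sch0 <- segmentScheme(cond0, 2)
  idx <- buildCandidateIndex("ACGT", sch0, cond0)
  assignChunkToGroups(idx, c("ACTT", "AGGT"), sch0, cond0)
  expect_identical(get("1:AC", envir = idx)$src, 1L)  # 'ACTT' matches seg 1
  expect_identical(get("2:GT", envir = idx)$src, 2L)  # 'AGGT' matches seg 2
})

test_that("processGroup flags similar members and respects occurrences", {
  stats <- new.env()
  stats$stringComparisons <- 0; stats$characterComparisons <- 0
  stats$groupsProcessed <- 0
  g <- list(cand = 1L, src = 1L)
  killed <- processGroup(g, "ACGT", "ACGA", cond42, selfMode = FALSE,
                         stats = stats)
  expect_identical(killed, 1L)
  expect_identical(stats$stringComparisons, 1)
  # self mode: the candidate's own occurrence never eliminates it
  expect_identical(
    processGroup(list(cand = 1L, src = 1L), "ACGT", "ACGT", cond42,
                 selfMode = TRUE, candIds = 5L, srcIds = 5L),
    integer(0))
  # but a distinct occurrence of the same string kills both
  killed <- processGroup(list(cand = 1:2, src = 1:2), c("ACGT", "ACGT"),
                         c("ACGT", "ACGT"), cond42, selfMode = TRUE,
                         candIds = 1:2, srcIds = 1:2)
  expect_identical(killed, 1:2)
})

test_that("discoveryRoutine matches the brute-force oracle on toy input", {
  cond <- DiscoveryCondition(4, 1)
  x <- c("ACGT", "ACGA", "TTTT")
  expect_identical(discoveryRoutine(x, x, cond)$uniquePatterns, "TTTT")
  same <- rep("ACGT", 5)
  expect_identical(discoveryRoutine(same, same, cond)$unique, integer(0))
  # candidate against an empty source is vacuously unique
  expect_identical(discoveryRoutine("ACGT", character(0), cond)$unique, 1L)
})

test_that("both engines equal the oracle across (l, d, gamma) and chunkings", {
  set.seed(31)
  for (l in c(6L, 8L)) for (d in 0:2) {
    cond <- DiscoveryCondition(l, d)
    for (g in gammaGrid(cond)) {
      sch <- segmentScheme(cond, g)
      n <- sample(80:160, 1)
      xi <- patterns(generateUniform(n, cond, seed = l * 100 + d * 10 + g))
      theta <- patterns(generateUniform(n + 50, cond,
                                        seed = l * 100 + d * 10 + g + 1))
      want <- bruteForceUnique(xi, theta, cond)
      for (budget in c(7, Inf)) {
        got <- discoveryRoutine(xi, theta, cond, sch, chunkBudget = budget,
                                workers = sample(c(1L, 4L), 1))
        expect_identical(got$unique, want)
      }
      gotR <- discoveryRoutine(xi, theta, cond, sch, chunkBudget = 23,
                               engine = "r")
      expect_identical(gotR$unique, want)
      # self mode on a single dataset
      wantSelf <- bruteForceUnique(xi, xi, cond)
      expect_identical(discoveryRoutine(xi, xi, cond, sch)$unique, wantSelf)
    }
  }
})

test_that("comparison counters respect the work and character bounds", {
  cond <- DiscoveryCondition(8, 1)
  xi <- patterns(generateUniform(300, cond, seed = 42))
  for (g in gammaGrid(cond)) {
    sch <- segmentScheme(cond, g)
    res <- discoveryRoutine(xi, xi, cond, sch)
    expect_lte(res$stats$stringComparisons, 300 * 300)
    # the matched segment is never re-compared: at most l - min(len_i)
    # characters per string comparison
    expect_lte(res$stats$characterComparisons,
               res$stats$stringComparisons * (8 - min(segmentLengths(sch))))
    expect_lte(res$stats$indexKeys,
               min(segmentCount(sch) * 300, 4^g * segmentCount(sch)))
  }
})

test_that("output is invariant to chunking and worker count", {
  cond <- DiscoveryCondition(8, 1)
  xi <- patterns(generateUniform(400, cond, seed = 13))
  base <- discoveryRoutine(xi, xi, cond)$unique
  for (budget in c(1, 7, Inf)) for (w in c(1L, 2L, 4L)) {
    expect_identical(
      discoveryRoutine(xi, xi, cond, chunkBudget = budget,
                       workers = w)$unique,
      base)
  }
})

test_that("every brute-force-similar pair is compared in some group", {
  # filter soundness by instrumentation on a small self-discovery
  cond <- DiscoveryCondition(6, 2)
  sch <- segmentScheme(cond, 3)
  set.seed(8)
  xi <- c(replicate(30, randomPattern(6)))
  res <- discoveryRoutine(xi, xi, cond, sch)
  want <- bruteForceUnique(xi, xi, cond)
  expect_identical(res$unique, want)
  # any pair the oracle deems similar must share a key, hence be reachable
  for (i in seq_along(xi)) for (j in seq_along(xi)) {
    if (i == j || hammingDistance(xi[i], xi[j]) > 2) next
    ck <- candidateGroupKeys(xi[i], sch)
    sk <- sourceGroupKeys(xi[j], sch, cond)
    expect_gt(nrow(merge(ck, sk[c("upsilon", "segment")])), 0)
  }
})

test_that("the fast engine rejects unencodable input and bad schemes", {
  cond <- DiscoveryCondition(4, 1)
  expect_error(discoveryRoutine("ACGN", "ACGN", cond), "non-ACGT")
  schBad <- segmentScheme(DiscoveryCondition(6, 1), 3)
  expect_error(discoveryRoutine("ACGT", "ACGT", cond, schBad),
               "does not match")
})
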