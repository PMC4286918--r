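test_that("hammingDistance counts mismatching positions and is a metric", {
  expect_identical(hammingDistance("ACGT", "ACGT"), 0L)
  expect_identical(hammingDistance("ACGT", "TGCA"), 4L)
  expect_identical(hammingDistance("AC", "AG"), 1L)
  expect_error(hammingDistance("AC", "ACG"), "length mismatch")

  set.seed(11)
  for (rep in 1:50) {
    p <- randomPattern(6); q <- randomPattern(6); r <- randomPattern(6)
    expect_identical(hammingDistance(p, q), hammingDistance(q, p))
    expect_identical(hammingDistance(p, p), 0L)
    expect_lte(hammingDistance(p, r),
               hammingDistance(p, q) + hammingDistance(q, r))
  }
})

test_that("isSimilar thresholds the distance at d", {
  expect_true(isSimilar("ACGT", "ACGT", DiscoveryCondition(4, 0)))
  expect_false(isSimilar("ACGT", "TGCA", DiscoveryCondition(4, 2)))
  expect_true(isSimilar("ACGT", "ACGA", DiscoveryCondition(4, 2)))
  expect_error(isSimilar("ACG", "ACGT", DiscoveryCondition(4, 1)),
               "length l")
})

test_that("condition and scheme validity rules hold", {
  expect_error(DiscoveryCondition(4, 4), "d must satisfy")
  expect_error(DiscoveryCondition(0, 0), "positive")
  expect_silent(DiscoveryCondition(4, 0))
  cond <- DiscoveryCondition(12, 2)
  expect_identical(recommendedGammaRange(cond), c(4L, 6L))
  # for d = 0 the nominal lower bound exceeds ceiling(l/2); range collapses
  expect_identical(recommendedGammaRange(DiscoveryCondition(12, 0)),
                   c(6L, 6L))
  expect_error(segmentScheme(cond, 13), "in \\[1, l\\]")
  expect_error(segmentScheme(cond, 3, strict = TRUE), "recommended range")
  s <- segmentScheme(cond, 5)
  expect_identical(segmentCount(s), 3L)
  expect_identical(segmentLengths(s), c(5L, 5L, 2L))
})

test_that("splitSegments cuts in order and concatenation is the identity", {
  expect_identical(
    splitSegments("ACGT", segmentScheme(DiscoveryCondition(4, 2), 2)),
    c("AC", "GT"))
  expect_identical(
    splitSegments("ACGTA", segmentScheme(DiscoveryCondition(5, 2), 2)),
    c("AC", "GT", "A"))
  expect_identical(
    splitSegments("AAAA", segmentScheme(DiscoveryCondition(4, 1), 4)),
    "AAAA")
  set.seed(3)
  for (rep in 1:20) {
    l <- sample(4:12, 1)
    g <- sample(seq_len(l), 1)
    p <- randomPattern(l)
    segs <- splitSegments(p, segmentScheme(DiscoveryCondition(l, 0), g))
    expect_identical(paste(segs, collapse = ""), p)
  }
})

test_that("segmentBudget is the length-proportional mismatch allowance", {
  expect_identical(segmentBudget(2, DiscoveryCondition(4, 2)), 1L)
  # a single full-length segment receives the whole budget
  for (d in 0:3) expect_identical(segmentBudget(7, DiscoveryCondition(7, d)),
                                  as.integer(d))
  expect_identical(segmentBudget(3, DiscoveryCondition(7, 2)), 0L)
})

test_that("hammingNeighborhood enumerates the exact Hamming ball", {
  expect_setequal(hammingNeighborhood("TG", 1),
                  c("TG", "GG", "CG", "AG", "TT", "TC", "TA"))
  expect_setequal(hammingNeighborhood("CA", 1),
                  c("CA", "AA", "GA", "TA", "CC", "CG", "CT"))
  expect_identical(hammingNeighborhood("AC", 0), "AC")
  set.seed(5)
  for (len in 2:6) for (delta in 0:2) {
    u <- randomPattern(len)
    ball <- hammingNeighborhood(u, delta)
    expect_identical(length(ball), length(unique(ball)))
    expect_identical(length(ball),
                     as.integer(sum(choose(len, 0:delta) * 3^(0:delta))))
    expect_true(all(vapply(ball, hammingDistance, integer(1), q = u) <= delta))
  }
})

test_that("candidate keys are the beta exact-segment keys", {
  k <- candidateGroupKeys("ACGT", segmentScheme(DiscoveryCondition(4, 2), 2))
  expect_identical(k$upsilon, c("AC", "GT"))
  expect_identical(k$segment, 1:2)
  k <- candidateGroupKeys("AAAA", segmentScheme(DiscoveryCondition(4, 1), 4))
  expect_identical(k, data.frame(upsilon = "AAAA", segment = 1L))
  k <- candidateGroupKeys("ACGTAC", segmentScheme(DiscoveryCondition(6, 2), 3))
  expect_identical(k$upsilon, c("ACG", "TAC"))
  # key count is always beta
  set.seed(9)
  for (rep in 1:10) {
    l <- sample(4:10, 1); g <- sample(seq_len(l), 1)
    sch <- segmentScheme(DiscoveryCondition(l, 1), g)
    expect_identical(nrow(candidateGroupKeys(randomPattern(l), sch)),
                     as.integer(segmentCount(sch)))
  }
})

test_that("source keys are the per-segment Hamming balls within budget", {
  cond <- DiscoveryCondition(4, 2)
  sch <- segmentScheme(cond, 2)
  k <- sourceGroupKeys("TGCA", sch, cond)
  expect_identical(nrow(k), 14L)
  expect_setequal(k$upsilon[k$segment == 1],
                  c("TG", "GG", "CG", "AG", "TT", "TC", "TA"))
  expect_setequal(k$upsilon[k$segment == 2],
                  c("CA", "AA", "GA", "TA", "CC", "CG", "CT"))
  # budget 0 collapses to the exact segment keys
  cond0 <- DiscoveryCondition(4, 0)
  k0 <- sourceGroupKeys("TGCA", segmentScheme(cond0, 2), cond0)
  expect_identical(k0$upsilon, c("TG", "CA"))
  expect_identical(k0$dist, c(0L, 0L))
  k2 <- sourceGroupKeys("AAAA", sch, cond)
  expect_identical(sum(k2$segment == 1), 7L)
  expect_setequal(k2$upsilon[k2$segment == 2], hammingNeighborhood("AA", 1))
})

test_that("every similar pair shares a group key (pigeonhole, small grid)", {
  set.seed(21)
  for (l in c(4L, 6L)) for (g in 2:3) for (d in 0:2) {
    cond <- DiscoveryCondition(l, d)
    sch <- segmentScheme(cond, g)
    for (rep in 1:40) {
      p <- randomPattern(l)
      q <- mutatePattern(p, sample(0:d, 1))
      ckdf <- candidateGroupKeys(p, sch)
      ck <- paste0(ckdf$segment, ":", ckdf$upsilon)
      skdf <- sourceGroupKeys(q, sch, cond)
      sk <- paste0(skdf$segment, ":", skdf$upsilon)
      expect_gt(length(intersect(ck, sk)), 0)
    }
  }
})
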