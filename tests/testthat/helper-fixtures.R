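# shared fixtures: everything is generated in code at test time

writeTempFasta <- function(seqs, path = tempfile(fileext = ".fa"),
                           width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(nchar(s), starts + width - 1L)), con)
  }
  path
}

randomPattern <- function(l) paste(sample(c("A", "C", "G", "T"), l,
                                          replace = TRUE), collapse = "")

# mutate exactly k positions of p (guaranteed Hamming distance == k)
mutatePattern <- function(p, k) {
  chars <- strsplit(p, "")[[1L]]
  pos <- sample(length(chars), k)
  for (i in pos)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

# all gammas in the recommended trade-off range, plus one below it when the
# range excludes small values (exercises non-divisor segmentations too)
gammaGrid <- function(cond) {
  rng <- recommendedGammaRange(cond)
  gs <- seq.int(rng[1L], rng[2L])
  if (rng[1L] > 2L && cond@d > 0L) gs <- c(2L, gs)
  gs
}

# the worked 10-task example: a view of 4N patterns
exampleDag <- function(N = 25L) {
  buildTaskDag(patternView(0L, 4L * N),
               runConfig(DiscoveryCondition(8, 1), thresholdN = N))
}

exampleDurations <- c(A = 1, B = 3, C = 4, D = 6, E = 2, F = 1, G = 4,
                      H = 2, I = 4, J = 3)
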