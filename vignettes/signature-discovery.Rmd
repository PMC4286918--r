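---
title: "Divide-and-conquer discovery of DNA signatures"
author: "SigDiscovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divide-and-conquer discovery of DNA signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigDiscovery)
```

## The problem

A *DNA signature* under a discovery condition $(l, d)$ is an $l$-base pattern
that occurs in a sequence database with no other occurrence within Hamming
distance $d$. Signatures are the raw material of species identification,
probe and primer specificity screening, and contamination checks: a pattern
that is unique even up to $d$ mismatches will not cross-hybridize with
anything else in the database. Formally, two $l$-patterns $P$ and $Q$ are
$(l,d)$-similar when their Hamming distance is at most $d$; a pattern of the
dataset $\Lambda$ is a signature when no *other* occurrence in $\Lambda$ is
$(l,d)$-similar to it. Finding **all** signatures of a large database is
quadratic in the worst case and, done naively, also requires the whole
database in memory. This package implements a signature-discovery algorithm
built from three ideas:

1. **Divide and conquer.** If $\Lambda$ is split into halves $\Lambda_i,
   \Lambda_j$, every signature of $\Lambda$ is a signature of its own half
   *and* unique in the other half. So the main routine recursively halves
   $\Lambda$ until a partition has at most $N$ patterns (the
   direct-discovery threshold, chosen to fit a worker's memory), discovers
   each small partition directly, and then filters each partial result
   against the sibling partition before taking unions. Memory per worker is
   $O(N)$, independent of $|\Lambda|$.
2. **Pigeonhole segment filtering.** Inside one discovery task ("find the
   candidates $\Xi$ unique in the source $\Theta$"), each pattern is cut
   into $\beta = \lceil l/\gamma \rceil$ non-overlapping segments. If $P$
   and $Q$ are $(l,d)$-similar, at least one segment of $P$ must be within
   the segment's proportional share of the mismatch budget of the matching
   segment of $Q$. Candidates are therefore indexed by their exact
   segments, sources fan out to the Hamming balls of their segments, and
   only patterns sharing a group are ever compared.
3. **Dependency-aware list scheduling.** The recursion is materialized as
   an explicit task DAG (self tasks and cross tasks); a greedy scheduler
   hands the highest-priority ready task to the first free worker node.

## The discovery routine in detail

Under a scheme with segment lengths $len_1, \dots, len_\beta$ (the first
$\beta - 1$ equal to $\gamma$, the last holding the remainder), segment $i$
receives the mismatch budget $\delta_i = \lfloor len_i \cdot d / l \rfloor$.
If every segment of a pair disagreed in more than $\delta_i$ positions, the
total distance would exceed $\sum_i len_i \cdot d / l = d$ — so any
$(l,d)$-similar pair shares at least one group, for **any** $\gamma \in [1,
l]$. This is the lossless-filter guarantee the tests verify exhaustively.

```{r}
cond <- DiscoveryCondition(4, 2)
sch <- segmentScheme(cond, gamma = 2)
candidateGroupKeys("ACGT", sch)
head(sourceGroupKeys("TGCA", sch, cond))
```

Because a candidate's segment equals its group key exactly, and the
source's distance to the key is known from the ball enumeration, each
in-group string comparison only needs the remaining $\alpha = l - len_i$
characters (with early exit once the running mismatch count passes $d$).
On uniform data the index spreads patterns over up to $4^\gamma \beta$
groups, so group-restricted comparison eliminates the vast majority of the
$|\Xi| \cdot |\Theta|$ naive comparisons; the engine counts string and
character comparisons so this is measurable rather than assumed.

The source $\Theta$ is streamed in chunks of at most `chunkBudget` patterns
(defaulting to $N$): group membership of sources is rebuilt per chunk, so
arbitrarily large sources run in bounded memory. A candidate proven
non-unique is deleted immediately and never compared again; this is a pure
optimization — the surviving set is invariant to chunk size, worker count
and group processing order, which the test suite asserts.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `l` | signature length (bases) | — | set by the assay |
| `d` | allowed mismatches (bases) | — | set by the specificity requirement |
| `gamma` | segment length (bases) | $\lceil l/2 \rceil$ | maximal filtering power; the published experiments use two segments per pattern |
| `thresholdN` | direct-discovery threshold (patterns) | `Inf` | bound worker memory; the published EST runs used a 125 M-base budget |
| `chunkBudget` | source patterns per chunk | `thresholdN` | same memory envelope as the candidate side |
| `nodeCount` | concurrent discovery workers | 1 | local stand-in for cluster discovery nodes |

The trade-off range for $\gamma$ is $\lceil l/(d+1) \rceil \le \gamma \le
\lceil l/2 \rceil$: larger $\gamma$ means fewer comparisons but up to
$4^\gamma \beta$ groups in memory. Two deliberate design choices here:

* **$\gamma$ range for small $d$.** For $d = 0$ the nominal lower bound
  ($l$) exceeds the upper bound ($\lceil l/2 \rceil$), so
  `recommendedGammaRange()` clamps the range to always contain
  $\lceil l/2 \rceil$, and `segmentScheme()` accepts any $\gamma \in [1,l]$
  (the proportional budgets keep the filter lossless there); only the CLI
  enforces the recommended range, as a guard against accidental
  memory blow-ups.
* **Short last segment.** When $\gamma \nmid l$ the last segment is shorter
  and gets the length-proportional budget
  $\lfloor len_\beta \cdot d/l \rfloor$. The published description only
  covers equal segments ($\gamma = l/2$); the proportional rule is the
  natural extension that preserves the pigeonhole proof above, and the
  suite tests non-divisor $\gamma$ explicitly.

Other numerical conventions: coordinates are 0-based half-open; an odd
split favors the left partition ($\lceil\cdot\rceil$ left); patterns are
extracted as overlapping stride-1 windows that never span records (stride
is configurable); occurrences are identified by dataset position, so two
occurrences of the same string eliminate each other while a pattern never
matches its own occurrence; task priority is creation order (left subtree
first) and scheduler ties go to the lowest free node index — the tie rules
that reproduce the published two-node worked schedule exactly.

## Scheduling

```{r}
dag <- buildTaskDag(patternView(0, 100),
                    runConfig(DiscoveryCondition(8, 1), thresholdN = 25))
taskTable(dag)
simulateSchedule(dag, c(A = 1, B = 3, C = 4, D = 6, E = 2, F = 1, G = 4,
                        H = 2, I = 4, J = 3), nodeCount = 2)
```

A dataset of $2^k N$ patterns yields $3 \cdot 2^k - 2$ tasks. Cross tasks
are sequentially interdependent with the self tasks producing their
candidate sets, so a slow self task can stall its dependent cross task even
while other nodes idle — the simulator makes that cost visible, and
`executeDag()` runs real discovery tasks under exactly the same discipline
on a local fork-based worker pool (a true multi-host transport is out of
scope; the dispatch contract is host-agnostic). The simulator ignores data
transfer costs: the published transmission constants are not recoverable,
and on a single host they do not exist.

## Synthetic data: what a green test establishes

`generateUniform()` draws i.i.d. uniform bases — the regime in which the
group-count bound $4^\gamma \beta$ and the efficiency of the filter are
derived — and `generateWithTruth()` labels its signatures with the
brute-force oracle (all-pairs Hamming scan, no filtering, a separate code
path). Planted-truth generation is deliberately generate-then-label:
guaranteeing planted uniqueness a priori under Hamming balls is itself a
hard covering problem, while labeling is exact. Uniform data has no repeat
structure, no splice isoforms, no base-composition skew; green equivalence
tests therefore establish algorithmic correctness (set equality with the
definition, invariance to all execution knobs) — not performance on
repeat-rich genomic data, where group occupancy is skewed and the filter
prunes less. Correctness on real data still follows from the oracle
equivalence, which is distribution-free; only the efficiency claims are
distribution-bound. Reproducing the published wall-clock timings on the
2.46 G-base human EST database would require that database and the original
eleven-machine cluster, and is out of scope; the suite instead asserts the
directional trends (smaller $N$: more tasks, more data movement; more
workers: identical output).

## Limitations

* Hamming distance only: no indels, no IUPAC-aware matching, no
  reverse-complement folding.
* The fast engine packs segments into 64-bit keys and so requires segment
  length $\le 28$; the reference R engine has no such limit.
* `nodeCount` parallelism uses process forks and degrades gracefully to
  serial execution elsewhere; results are identical either way.
* Memory of the R-level containers is not tuned for multi-gigabase inputs
  in a single session; the algorithmic memory bound $O(N)$ per task holds,
  but R object overhead is unoptimized.
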