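Package: SigDiscovery
Title: Divide-and-Conquer Discovery of DNA Signatures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers DNA signatures, i.e. fixed-length patterns that occur
    exactly once in a sequence database with no other pattern within a given
    Hamming distance. Implements a divide-and-conquer main routine that
    recursively halves the pattern dataset down to a direct-discovery
    threshold, a segment-group (pigeonhole) filtered discovery routine with
    chunked source streaming, and a dependency-aware greedy list scheduler
    that dispatches discovery tasks to worker nodes. Includes synthetic data
    generators and brute-force oracles for validation, FASTA input with
    cleaning rules for expressed sequence tag style databases, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    Biostrings,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
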