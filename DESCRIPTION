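Package: kresolve
Title: Repeat Resolution in Unitig Assembly Graphs Using Read-Length k-mers
Version: 0.1.0
Authors@R:
    person("Ash", "Moran", email = "ash.moran@example.org", role = c("aut", "cre"))
Description: Resolves short interspersed repeats in de Bruijn unitig assembly
    graphs by exploiting k-mers substantially longer than the assembly k.
    Long k-mers extracted from the 5' ends of sequencing reads are stored in
    a Bloom filter; a sliding window of the same length is moved along every
    three-node junction path through a candidate repeat node and the filter
    is queried at each step. Paths with insufficient k-mer support are
    removed, the repeat sequence is duplicated once per supported path, and
    unambiguous chains are merged. Includes GFA1/FASTA/FASTQ input and
    output, a coverage-adaptive test planner, complex-repeat flank
    expansion, and a synthetic genome/read/unitig-graph simulator for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
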