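Package: cnescan
Title: Conserved Non-Coding Element Profiling and Genome Scanning for Alphabaculoviruses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Comparative-genomics toolkit for the 154-157 bp conserved
    non-protein-coding element (CNE) shared by alphabaculovirus genomes.
    Provides multiple alignment of CNE-scale sequence families with pairwise
    identity summaries, per-column conservation profiling (consensus calling,
    information content, conserved-cluster segmentation), detection of
    dyad-symmetry elements with degenerate IUPAC cores and maximal arm
    extension, AT-content enrichment statistics, six-frame ORF finding and
    overlap classification, an architecture model assembled from a profiled
    family, a both-strand genome scanner for CNE-like loci, and a synthetic
    family/genome simulator with known truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
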