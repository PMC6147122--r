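Package: markerMiner
Title: Marker-Gene Mining from Metagenomic Reads with BLAST-Score-Ratio
    Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained toolkit for mining metagenomic read sets for a
    marker protein family. Curates a non-redundant marker reference database
    by self-hit BLAST score ratio (BSR) and greedy 90%-identity centroid
    clustering, screens nucleotide reads by six-frame translated local
    alignment, removes false positives by outgroup BSR, reconstructs
    near-full-length genes from retained reads with a greedy overlap-consensus
    assembler, predicts (possibly edge-open) reading frames, profiles read
    recruitment and sequence novelty at an amino-acid identity floor, assigns
    sequences to clades by BSR, and checks stoichiometric balance and standard
    free-energy bookkeeping of proposed catabolic reactions. Includes a
    truth-labelled synthetic data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
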