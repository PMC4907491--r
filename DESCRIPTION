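Package: startbias
Title: Recognition and Quantification of Sequence-Composition Bias in
    Read-Start Positioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies the dependence of next-generation
    sequencing read-start placement on local sequence composition.
    Builds stratified pools of fixed-width windows around genomic
    positions, extracts normalized mono- to tetra-nucleotide
    distribution features, measures Euclidean distances between local
    and global nucleotide distributions, classifies read presence with
    a balanced 3-nearest-neighbor classifier, and summarizes the
    strength of the recognized pattern as the Pattern Effect Index
    (PEI).  Includes genetic-algorithm feature selection, a
    transition/entropy sequence-complexity score, and a synthetic read
    simulator with controllable bias strength so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    Rsamtools,
    class,
    yaml,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
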