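Package: phyin
Title: Trim Noisy Alignment Regions by Phylogenetic Incompatibility Among Neighbouring Sites
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Trims nucleotide multiple sequence alignments by locating regions
    in which a high proportion of neighbouring sites are pairwise
    phylogenetically incompatible (the PhyIN criterion). Two columns are
    incompatible when no tree exists on which both could evolve without
    homoplasy, decided by a cycle test on the bipartite graph of observed
    state combinations. Conflicted sites are found by pairwise comparison of
    columns up to a fixed distance apart, blocks with a high proportion of
    conflicted sites are marked, and the marked span is deleted. Internal
    gaps may be treated as a fifth character state while terminal gaps are
    always treated as missing data. Includes the companion site-occupancy
    filter, a brute-force tree-enumeration oracle for verifying the
    compatibility test, a seeded generator of synthetic alignments with
    tree-consistent and randomized regions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
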