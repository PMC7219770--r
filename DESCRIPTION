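Package: codonpair
Title: Codon-Pairing Phylogenomics: Alignment-Free Distances and Parsimony Characters from Codon Pairing Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects identical, co-tRNA and combined codon pairing in coding
    sequences using a sliding ribosome-footprint window, and turns the binary
    pairing profiles into phylogenetic signal two ways: an alignment-free
    species distance (one minus relative motif-set similarity, with a small-
    profile ratio guard) fed to neighbor-joining, and a parsimony-informative
    binary character matrix exported for TNT. Includes tree evaluation tools
    (bipartition edge overlap, Fitch parsimony retention index with a leaf-
    label permutation null, distance saturation diagnostics), descriptive
    motif statistics, and a simulator that evolves binary pairing states along
    a known tree and realizes them as coding sequences so every stage can be
    tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
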