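Package: boolscape
Title: Boolean Attractor-Landscape Analysis for Tumor Transition States and
    Reversion Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tumor transition states from single-cell copy-number
    phylogenies by clade mixture entropy, infers executable Boolean gene
    regulatory networks from pseudotime-ordered binarized expression, quantifies
    the resulting attractor landscape with a scalar cancer score built from
    basin sizes, perturbation-based attractor entropies and projections onto
    the normal-cancer axis, and screens single and double gene fixations for
    candidate cancer-reversion switches. Ships a synthetic-data generator that
    emulates the assumed data structure (bistable toggle-switch networks, driven
    normal-to-cancer trajectories, two-clade copy-number matrices with a mixed
    intermediate clade) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
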