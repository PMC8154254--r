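Package: etpaths
Title: Electron-Tunneling Pathway Analysis for Heme Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts long-range electron transfer (LRET) routes from a heme
    cofactor to candidate tyrosine/tryptophan radical sites in peroxidases.
    Atoms of a structure are assembled into a typed graph (covalent bonds,
    hydrogen bonds, through-space jumps), each edge is scored with an
    exponential tunneling decay factor, and the pathway maximizing the
    product of decay factors is found with Dijkstra's algorithm on
    negative-log weights.  Ensemble utilities repeat the search over
    trajectory frames and summarize per-atom path participation, hydrogen
    bond occupancy, and water structure (radial distribution and minimum
    distance) around a target atom.  Synthetic-structure generators with
    closed-form path scores support end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
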