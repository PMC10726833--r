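Package: ppicrosstalk
Title: Protein-Protein Interaction Network Crosstalk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of protein-protein interaction (PPI)
    networks built from seed gene sets, aimed at studying crosstalk between
    biological subsystems (for example the circadian clock and autism
    susceptibility genes). Provides confidence-based interaction filtering of
    BioGRID/STRING-style edge lists, seed-driven network construction with
    first-neighbor expansion and network merging, Cytoscape-convention
    topological statistics (closeness, radiality, heterogeneity), a from-scratch
    implementation of the MCODE molecular-complex detection algorithm,
    hypergeometric GO-term over-representation analysis with Bonferroni
    correction, exhaustive bounded-length linear-path enumeration with
    per-protein participation statistics, and seeded synthetic-data generators
    with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
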