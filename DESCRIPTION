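Package: coseda
Title: Differential Analysis of Microtubule Co-Sedimentation Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of label-free microtubule co-sedimentation
    proteomics under 14-3-3 inhibition. Reads MaxQuant-style protein-groups
    tables, applies decoy/contaminant filtering and per-gene collapsing,
    performs paired (or unpaired) log-ratio t-tests with explicit handling of
    zero (not-detected) intensities, and classifies proteins on a volcano
    plot. Downstream modules annotate predicted 14-3-3 binding phospho-sites,
    test directional enrichment of motif-bearing proteins, compute positional
    amino-acid composition around predicted sites, assess protein-interaction
    edge enrichment against a permutation null, and implement
    background-subtracted densitometry with rank-sum and Fisher exact
    summaries. A seeded synthetic-data generator emulates the paired spike-in
    design so the whole pipeline is testable without any download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    readxl,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
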