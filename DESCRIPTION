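Package: tadremodel
Title: Comparative Hi-C Analysis of TAD Border Remodelling, Chromatin Loops
    and Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing chromatin architecture between Hi-C
    experiments: binned contact-matrix input/output with iterative
    balancing, down-sampling and observed/expected transforms;
    multi-scale insulation scoring with two-tier (strong/weak) TAD border
    calling and cross-condition classification into maintained, weakened,
    fuzzy, lost and new borders; focal-enrichment chromatin loop calling
    with aggregate peak analysis and functional annotation; A/B
    compartment eigenvectors, saddle plots and compartmentalisation
    strength; permutation tests linking differential gene expression to
    TAD reorganisation; border-centred occupancy heat maps, occupancy
    clustering, Pol II pausing indices and PWM site counting; and a
    synthetic-data generator that plants TADs, loops, compartments and
    expression effects with machine-readable ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
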