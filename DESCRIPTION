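Package: rhythmlayers
Title: Multi-Layer Diurnal Rhythm Detection and Cross-Layer Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects diurnal rhythms in multi-omics time courses and classifies
    how rhythmicity propagates across regulatory layers (nascent transcription,
    mature RNA, protein, DNA-binding-protein activity). Implements the JTK_CYCLE
    rank-based periodicity test with an exact tie-aware permutation null,
    layer-specific quantification rules for run-on sequencing (gene-body windows,
    RPKTM), enhancer-RNA locus filtering, ribosome-profiling translation rate,
    cross-layer conserved/disrupted/enhanced classification with mechanism
    attribution, and a seeded multi-layer synthetic time-course generator with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
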