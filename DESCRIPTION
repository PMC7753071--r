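Package: panomix
Title: Pan-Omics Integration on a Multi-Layer Human Meta-Interactome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps single- or multi-omics differential data (mRNA, miRNA,
    proteomics, phosphoproteomics, genomics, epigenomics, metabolomics)
    onto a multi-layer meta-interactome of protein-protein, miRNA-target,
    TF-target and enzyme-metabolite relations, extracts context-specific
    subnetworks around deregulated or altered nodes, ranks topologically
    important nodes (hubs, central nodes, bottlenecks) by z-scored
    topology indices, enriches them against classed pathway gene sets via
    the hypergeometric test, and enumerates and scores cross-pathway
    paths linking signaling proteins, transcription factors or miRNAs to
    metabolic enzymes with an HMM-style log-likelihood path score.
    Includes a seeded synthetic-data generator so the full pipeline is
    testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
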