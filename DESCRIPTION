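Package: exoprio
Title: Prioritization of Exosome-Surface Tumor Antigens from Multi-Compartment Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing candidate tumor antigens
    displayed on the surface of cancer-derived exosomes. Starting from
    label-free spectral-count and MS1 ion-intensity proteomics across cellular
    and vesicular compartments, the package quantile-normalizes count matrices,
    applies the detection, case/control ratio, surface-enrichment and
    particle-normalized plasma-elevation filter cascades used in
    immunoglobulin-bound antigen discovery, scores gene-set overlaps with
    hypergeometric statistics and representation factors, filters eluted HLA
    class II peptides by length and predicted binding affinity, standardizes
    and merges multi-set autoantibody microarray data for ROC analysis, and
    quantifies the exosome decoy effect on complement-dependent cytotoxicity
    dose-response data. A seeded synthetic-study generator with planted ground
    truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    jsonlite,
    yaml,
    pROC,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
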