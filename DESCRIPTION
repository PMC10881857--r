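Package: omicnets
Title: Multi-Omic Integration and Regulatory Network Inference for Cancer Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated construction of functional regulatory network models from
    matched DNA methylation, transcript and miRNA profiles of tumour cohorts. Implements
    sparse generalized canonical correlation analysis (SGCCA, centroid scheme) with
    cross-validated sparsity selection and subsampling stability selection;
    over-representation, Fisher category and GSEA enrichment; mutual-information network
    inference with data-processing-inequality pruning and regulatory-prior-calibrated
    edge thresholds; NetworkAnalyzer-convention topology summaries; CpG
    promoter/enhancer classification; and Cox proportional-hazards interaction
    screening. Ships a synthetic multi-omic data generator with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    tools,
    edgeR,
    survival,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
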