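Package: methseg
Title: Fused-Lasso Segmentation of Whole-Genome CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments whole-genome bisulfite-sequencing methylomes with an
    exact weighted one-dimensional fused lasso and calls low-methylated
    regions (LMRs), unmethylated regions (UMRs), DNA methylation valleys
    (DMVs) and partially methylated domains (PMDs) in a single condition,
    as well as differentially methylated regions (DMRs) between two
    conditions via a coupled two-condition fit, Wilcoxon testing and
    Benjamini-Hochberg FDR control. Includes a synthetic-methylome
    generator with planted truth regions and a benchmark scorer
    (sensitivity, precision, F1 with confidence intervals), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
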