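Package: netmark
Title: Network-Based MicroRNA Biomarker Screening from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for screening candidate microRNA
    biomarkers from two-group (case/control) expression studies. Differentially
    expressed miRNAs and mRNAs are called with an empirical-Bayes moderated
    t-statistic and Benjamini-Hochberg correction, mapped onto a reference
    miRNA-mRNA interaction network to obtain a condition-specific bipartite
    network, and each miRNA is scored by two structural indices: the number of
    uniquely targeted genes (NOG) and the transcription-factor percentage of
    its targets (TFP). A Wilcoxon signed-rank screen against the network-wide
    background calls candidate biomarkers, and pooled candidate targets are
    tested for gene-set over-representation with the hypergeometric test under
    FDR control. A synthetic-data generator with planted ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
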