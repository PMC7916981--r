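Package: miRtaq
Title: miRNA Target-Site Prioritization and Efficiency-Corrected qPCR
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing candidate miRNA-target gene pairs and
    quantifying their expression by qPCR. Locates seed-complementary
    binding sites on 3'-UTR sequences (with G:U wobble and mismatch
    budgets), scores miRNA:mRNA heteroduplexes with an embedded
    nearest-neighbor stacking parameter table, folds flanking windows with
    a self-contained minimum-free-energy dynamic program, decomposes
    secondary structures into loops and stems, and classifies
    destabilising (DSE) and stabilising (SE) elements around each site.
    Site, structure and externally supplied database evidence are
    aggregated into a per-pair prioritization decision. A companion qPCR
    module performs standard-curve efficiency estimation, reference-gene
    normalized delta-Cq / delta-delta-Cq relative quantification with
    nonparametric group comparisons and Spearman correlation analysis.
    A synthetic-data generator plants binding sites and group effects with
    known ground truth so every stage can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
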