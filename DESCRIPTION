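Package: elncScout
Title: Discovery and Characterization of Enhancer-Associated lncRNAs from
    Flow-Regulated Expression and Chromatin-Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing enhancer-associated long
    non-coding RNAs (elncRNAs) that regulate a target gene in trans. Combines a
    two-condition time-course expression screen (per-timepoint log2 fold changes,
    endpoint differential-expression filtering, temporal correlation with a
    designated target), integration of sparse 5-kb inter-chromosomal Hi-C contact
    matrices with gene annotation and chromatin-state tracks into a staged
    prioritization funnel, 4C-style restriction-fragment processing (in-silico
    double digestion with two 4-bp cutters, 5'-end read assignment,
    reads-per-million normalization, bait-centric trans-interaction tables),
    IUPAC consensus motif scanning of promoter/enhancer windows, affine-gap
    Smith-Waterman local alignment for cross-species homology, and small bench
    assay calculators (absolute qPCR copy number, DNA-FISH proximity fractions,
    two-sample t-test power, parallel-plate shear stress, subcellular fraction
    percentages). Seeded synthetic-data generators produce every input with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
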