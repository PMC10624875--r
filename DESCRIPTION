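Package: cryomethyl
Title: Differential DNA Methylation Analysis of Cryopreserved Fish Sperm
    from RRBS Cytosine Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for reduced representation bisulfite
    sequencing (RRBS) of paired fresh and cryopreserved sperm samples:
    reads Bismark-style per-cytosine count reports, quantifies genome
    representation of the sequenced CpG cytosines, summarises global
    methylation, calls differentially methylated cytosines (DMCs) with a
    paired arcsine-link Wald test across males, classifies their
    hyper/hypomethylation trend by a majority rule, aggregates DMCs into
    differentially methylated regions and cryopreservation-sensitive
    regions, annotates them against gene features, and correlates per-male
    DMC burden with sperm quality metrics. Includes a synthetic RRBS
    generator (MspI-digested toy genome, bimodal sperm methylome, paired
    design with injected differentially methylated cytosines of known
    direction) for validating the whole chain against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
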