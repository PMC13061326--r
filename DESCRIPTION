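Package: pmdomains
Title: Segmentation and Analysis of Partially Methylated Domains in Cancer Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Domain-level analysis of whole-genome bisulfite sequencing data from
    cancer cells. Segments window-level CpG methylation into partially methylated
    domains (PMDs) and highly methylated domains (HMDs) with a two-state Gaussian
    hidden Markov model and bedtools-style post-processing; normalises ChIP-seq
    tracks against input and computes loess-smoothed replication timing from
    repli-seq fractions; classifies PMDs by heterochromatic histone mark
    (H3K9me3 versus H3K27me3) via k-means; calls PMDs that gain methylation under
    maintenance-methyltransferase (DNMT1) loss; builds scale-regions pileup
    matrices; and models per-domain DNA-methylation decay kinetics with
    domain-specific de novo methyltransferase activity. A synthetic-data
    generator with planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'genome-model.R'
    'tracks-io.R'
    'chip-repli.R'
    'domain-analysis.R'
    'hmm.R'
    'kinetics.R'
    'segmentation.R'
    'simulate.R'
    'pipeline.R'
    'pmdomains-package.R'
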