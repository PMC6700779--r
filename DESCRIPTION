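Package: MBDmodel
Title: Modeling MBD-Seq Pulldown Coverage from Fully Methylated DNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generative model of methyl-CpG binding domain (MBD) protein
    pulldown sequencing coverage from fully methylated (SssI-treated) DNA.
    Computes the expected per-position read density from genome sequence
    alone, using a fragment-length distribution, a steric-exclusion rule for
    accessible CpGs, and CpG-count enrichment coefficients, and aggregates it
    into window coverage tracks usable as a calculated SssI control.  Includes
    estimators that calibrate the model from paired pulldown/input alignments
    (fragment-length fit from single-CpG profiles, enrichment coefficients
    with subsample standard deviations), an evaluation harness scoring window
    methylation calls against bisulfite data (ROC/AUC, operating points,
    coverage-percentile sweeps), and a simulator generating read sets under
    the model's own enrichment rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, Coverage, Software
RoxygenNote: 7.3.3
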