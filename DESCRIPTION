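Package: hifreg
Title: Linking Renal Cancer Risk Loci to the HIF Cis-Acting Apparatus
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether disease-associated haplotype blocks
    colocalize with hypoxia-inducible factor (HIF) binding sites and for
    dissecting candidate regulatory variants. Provides linkage-disequilibrium
    haplotype-block expansion from phased panels, a bidirectional
    structure-preserving Monte-Carlo permutation test of GWAS-block /
    ChIP-seq-peak overlap, allele-specific ChIP/FAIRE/expression
    quantification with input-dilution calibration, hypoxia response element
    (RCGTG) gain/loss annotation of variants, negative-binomial
    likelihood-ratio eQTL tests stratified by metagene-derived HIF pathway
    activity, and distance-decay significance calling for Capture-C
    viewpoint profiles. A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Rsamtools,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    DESeq2,
    vcfR,
    rtracklayer,
    optparse
Config/testthat/edition: 3
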