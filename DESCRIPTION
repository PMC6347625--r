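Package: ampliconBE
Title: Quantification of CRISPR Base-Editing Outcomes from Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify cytidine base-editor outcomes from amplicon
    deep-sequencing reads: exact flank-anchored extraction of fixed-length
    editing regions, per-position substitution (conversion) matrices,
    PAM-relative C-to-T editing profiles, edited-product (haplotype)
    distributions, product purity, length-based indel classification,
    editing-window width and positional-selectivity metrics, and
    canavanine-selection colony statistics for diploid yeast (mutation
    frequencies and homozygous/heterozygous genotype tables). Includes a
    parametric read and colony simulator with recorded ground truth so the
    whole pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
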