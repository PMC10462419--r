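Package: codonevol
Title: Base Composition, Codon Usage Bias, and GC-Biased Gene Conversion
    in Coding-Sequence Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how nucleotide composition, codon usage
    bias, and GC-biased gene conversion (gBGC) shape coding-sequence
    evolution in multi-species data sets such as Lepidoptera gene sets.
    Provides codon-aware alignment hygiene filters; codon-position GC
    statistics; codon usage tables with relative synonymous codon usage
    (RSCU) and observed, composition-expected, and normalized-difference
    effective number of codons (ENC); parsimony-based substitution
    counting partitioned into strong-to-weak, weak-to-strong, and
    GC-conservative classes at synonymous and nonsynonymous sites;
    unfolded site-frequency spectra at 0-fold and 4-fold degenerate
    sites with maximum-likelihood estimation of the population-scaled
    conversion coefficient B = 4*Ne*b and the S-to-W/W-to-S mutation
    bias ratio under a gBGC-mutation-drift equilibrium model, with
    bootstrap confidence intervals; tRNA-gene repertoire summaries
    (anticodon copy number, relative abundance of isoacceptor tRNAs);
    and synthetic-data generators with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite,
    pracma,
    vcfR
Suggests:
    rtracklayer,
    GenomicRanges,
    phangorn,
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
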