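Package: readmask
Title: Privacy-Preserving Masking of SNV Alleles in Aligned Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reversible masking of personal single-nucleotide-variant alleles
    in coordinate-sorted aligned reads (SAM/BAM). Personal alleles at sites of
    a public population allele-frequency table are replaced by alleles drawn
    from the population allele distribution; every replaced base and quality is
    preserved in a range-sliceable diff document that is stored in a hybrid
    (AES + RSA) encrypted container, so the holder of the matching private key
    can restore the original alignments fully or within chosen genomic ranges,
    or re-encrypt a sub-range for another recipient. Includes a synthetic
    read/population simulator with known ground truth, a minimal threshold
    variant caller, and evaluation utilities (five-category variant-position
    classification, masked-ratio-by-frequency curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    stats,
    utils
Suggests:
    Rsamtools,
    Biostrings,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
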