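Package: sigrefit
Title: Comparative Mutational Signature Refitting from Somatic Variant Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds SBS-96 trinucleotide-context mutation catalogues from
    somatic variant tables or VCF files, refits them against reference
    signature catalogues by non-negative least squares with cosine-similarity
    reconstruction quality control, and aggregates fits across annotated
    cohorts into group-discrimination statistics (median set-contribution
    deltas with Wilcoxon rank-sum tests). Includes region-stratified
    (exonic/intronic/extragenic) contribution analysis, position-blacklist
    filtering of artefact-prone sites, downsampling-based inference of the
    minimum mutation count needed for reliable signature assignment, and a
    fully seeded synthetic-cohort simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    vcfR,
    rtracklayer,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
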