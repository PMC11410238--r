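Package: intertaxon
Title: Integrative Taxonomy for Microbial Species Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Species delineation for yeasts and other microbes by integrative
    taxonomy: average nucleotide identity by fragment orthology (OANI) with a
    95-96% decision band, population-genetic divergence (pi, Watterson's
    theta, Hudson Fst) and mutation-rate-based divergence-time estimation,
    windowed introgression scanning from SNP density and read coverage,
    structural-variant classification from whole-genome alignment blocks
    (reciprocal and non-reciprocal translocations, inversions, deletions),
    spore-viability statistics for postzygotic reproductive isolation, and
    growth-curve phenotyping. A synthetic-lineage generator with truth sets
    supports end-to-end validation, and a rule-based report combines all
    evidence into a per-lineage-pair delineation verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    ape,
    data.table,
    jsonlite,
    methods,
    minpack.lm,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
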