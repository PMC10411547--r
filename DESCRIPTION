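Package: traitanchor
Title: Comparative Physical Mapping of Trait Loci on Collinear Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds physical maps of agronomic trait loci on a pair of
    collinear reference genomes. Marker and gene sequences (or primer pairs)
    are anchored on each genome with a built-in seed-and-extend matcher and
    an in-silico PCR engine, anchors are joined into cross-genome matched
    pairs, chromosome rearrangements (inversions and intra-chromosomal
    translocations) are called from collinear chaining of anchor order, and
    trait loci reported by independent mapping studies are projected into
    physical intervals from linked and flanking markers, merged across
    studies under a uniform nomenclature, and screened for colocalization,
    cross-species synteny and resistance hotspots. Includes a synthetic-data
    generator with full ground truth, publication-style SVG chromosome maps,
    and BED/GFF3 interval export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
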