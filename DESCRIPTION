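Package: ptrfkit
Title: Identification and Classification of tRNA-Derived Fragments from Small RNA Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds per-species references of mature tRNAs (spliced, CCA-appended)
    and precursor tRNAs (gene plus 40 nt flanks) from a genome and tRNA gene
    annotations, ingests small RNA data as unique-fragment tables or FASTQ reads,
    applies quality, length and clonal-frequency filters, maps fragments by exact
    full-length plus-strand substring search, resolves mature-versus-precursor
    hits, and classifies 15-28 nt fragments anchored at tRNA termini into tRF-5,
    tRF-3 and tRF-1 catalogs with per-species summary statistics. Includes a
    synthetic fixture generator that plants tRNA genes in toy genomes and spikes
    sequencing libraries with ground-truth fragments and decoys for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
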