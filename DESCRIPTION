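Package: taxmapr
Title: Reference-Based Taxonomic Classification of Metagenomic Reads
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing core for reference-based taxonomic annotation of
    metagenomic sequence reads. Filters SAM/BAM alignments on alignment score
    and matched fraction, resolves best hits for each read or read pair across
    multiple reference databases by summed alignment score with database
    priority tie-breaking, computes per-reference read count statistics
    including size-normalized abundance, coverage and depth, aggregates them
    by taxid at eight clade levels, and applies a four-criterion acceptance
    procedure to separate confident taxonomy annotations from likely false
    positives. Includes a seeded synthetic-community generator producing
    FASTA, taxonomy tables and SAM files with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
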