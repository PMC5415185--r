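---
title: "Reference-based read classification and abundance post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based read classification and abundance post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmapr)
```

## The problem and the method

Mapping shotgun metagenomic reads against large reference databases
produces many spurious hits: the larger the database, the more reads land
on references that are not in the sample. taxmapr implements the
classification core of a reference-mapping workflow that addresses this
with (i) per-alignment quality filters, (ii) a deterministic best-hit
resolution across databases, and (iii) a post-processing step that accepts
a taxonomy annotation only when several independent lines of evidence
agree. Alignments themselves are produced externally (any aligner that
emits an alignment score `AS` and an edit distance `NM` will do; the
pipeline was designed around `bwa mem -M` output); taxmapr consumes the
SAM/BAM files, one per reference database.

### Alignment filtering

Candidate records follow the standard flag masks: paired mode keeps
primary, properly paired records (`-F 256 -f 2`), single-end mode keeps
primary mapped records (`-F 260`). Supplementary records (flag 0x800) are
dropped before candidate selection; split alignments are represented by
their primary record only. Two per-record thresholds then apply:

* **MAS** (minimum alignment score, default 30): the aligner's `AS` value
  must be at least MAS.
* **FMM** (minimum matched fraction, default 0.8): the fraction of the
  *full* read length covered by CIGAR `M`/`=`/`X` operations must be at
  least FMM. Soft- and hard-clipped bases count in the denominator (the
  hard-clipped length is recovered from the CIGAR), so a heavily clipped
  read cannot pass on its aligned remainder alone. `=`/`X` count like `M`
  because the fraction is about aligned state, not identity.

Both thresholds are stated as minima, so both comparisons are inclusive
(`>=`). In paired mode a fragment is removed from a reference if *either*
mate fails, and a fragment whose two mates are not both present on that
reference is likewise dropped (counted in the diagnostics, not an error).
Records missing `AS` or `NM` never pass: the method is undefined without
them.

### Best-hit resolution

Each fragment's candidate hit on a reference is scored by **SAS**, the sum
of its mate alignment scores (single-end: the one score). Databases are
declared *bestmode* or *fullmode*:

* In **bestmode** scope a fragment is assigned to exactly one reference —
  the highest SAS across all bestmode databases. Ties go first to the
  database the user specified first, then to the reference encountered
  first in that database's alignment file. The file-order tie-break mirrors
  the arbitrary-but-fixed choice aligners make among equally good
  placements, and makes resolution a pure function of the inputs.
* Each **fullmode** database independently receives the fragment's best
  hit within that database, regardless of better hits elsewhere. This is
  intended for gene catalogues (e.g. resistance genes) that are subsets of
  genome databases: a read should be assigned both its genome and its
  gene.

A fragment is **unique** when its chosen SAS strictly exceeds the SAS of
every other reference in scope. Strictness is deliberate: an exact tie
leaves the fragment's origin genuinely ambiguous, and unique reads are the
strongest evidence that a specific reference is present.

### Per-reference statistics

For every reference with at least one assigned fragment the pipeline
reports the 14-column statistics row: size-normalized abundance,
read-count abundance, reference size, sequence count, mapped nucleotides,
covered positions, coverage, depth, read counts (total and unique) and
summed edit distance. Two conventions matter:

* **ReadCount counts mates**, not fragments. The paired form of the
  size-normalized abundance,
  `S_Abundance = 100 * ReadCount / (2 * Size)` (single-end:
  `100 * ReadCount / Size`), divides by two precisely to convert mate
  counts back to fragment equivalents, which is only coherent if mates are
  counted individually. `R_Abundance` is `100 * ReadCount /
  total_clean_reads`, with the cleaned read set (post-trimming,
  post-control-removal) counted in the same unit.
* **Nucleotides and covered positions follow pileup semantics**: only
  `M`/`=`/`X` bases are placed on the reference; insertions exist in the
  read but not the reference, and deletions/skips advance the reference
  without adding bases or coverage.

### Clade aggregation

Each reference carries a taxonomy path over eight ranks: strain (the
reference header itself), species, genus, family, order, class, phylum,
superkingdom. Aggregation at a rank groups rows by that rank's taxid;
rows lacking the taxid are grouped by the rank's name string, and rows
lacking both fall into a single "unclassified" group, so read counts are
conserved no matter how incomplete the annotation is. Every statistics
column is summed over group members — including Coverage and Depth, which
are ratios, so an aggregated Coverage can exceed 1. Because summed ratios
are easy to misread, the collapsed tables also carry `coverage_ratio` and
`depth_ratio`, recomputed from the summed covered positions, nucleotides
and sizes; these derived columns are clearly named and never fed into the
acceptance criteria.

The eight-rank choice itself was a design decision: the source material
for this pipeline family lists the ranks ambiguously (one rank duplicated,
and a nonstandard "superfamily" as the top rank), so taxmapr uses the
standard strain→superkingdom lineage, which is also what NCBI-style
taxonomies provide.

### Acceptance criteria

Four criteria identify a confident annotation (defaults in parentheses):

| Criterion | Quantity | Test |
|---|---|---|
| I | ReadCount | `>= 10` (inclusive: a stated minimum) |
| II | Mismatches / Nucleotides | `< 0.01` (strict) |
| III | S_Abundance | `> 0.01` (strict) |
| IV | ReadCount uniq / ReadCount | `> 0.005` (strict) |

At strain level all four are imposed. At genus level and above only I–III
are used (uniqueness is a strain/species-scale signal). Species level is
a two-pass procedure: a pre-cycle selects species and takes `T`, the
lowest S_Abundance among them; the second pass accepts species satisfying
I, II and `S_Abundance >= T`, with criterion IV omitted. Two readings of
the pre-cycle are defensible — selection by all four criteria (IV being
the one later dropped) or by IV alone. taxmapr defaults to the former: a
pre-cycle on IV alone would let any high-uniqueness noise row set `T`
arbitrarily low. The alternative is available as
`criteria_config(species_precycle = "uniq_only")`. The comparison against
`T` is inclusive because `T` is itself the abundance of a selected
species, which must stay accepted. When the pre-cycle selects nothing,
`T` falls back to the configured abundance floor rather than accepting
everything. "0.5%" in criterion IV is the dimensionless fraction 0.005 of
ReadCount.

Rows with zero nucleotides get mismatch ratio 0 when they also have zero
mismatches, and fail criterion II otherwise. Every level's partition
reports the rejected rows alongside the accepted ones, with the violated
criteria listed, so thresholds can be revisited from the saved tables
(`reprocess_strain_tables()`) without re-parsing any alignments.

Aggregation and post-processing run per database: bestmode genome tables
and fullmode gene tables must not be mixed, and the species pre-cycle
threshold is meaningful only within one database's rows.

## The synthetic community generator

`community_spec()`/`generate_community()` produce a complete, seeded
fixture bundle: per-database SAM files with correct flags, CIGARs, `AS`
and `NM` tags, a taxonomy TSV, a size table, and optionally a FASTA. The
generator is exact where the method is sensitive and simple where it is
not:

* Fragments are placed uniformly over each reference; mismatch positions
  are never materialized (only counts matter to the method), and read
  bases are placeholders — no stage re-aligns sequence.
* Alignment scores are synthesized as
  `read_length - 5 * mismatches` (slope configurable); only the relative
  order of scores matters to resolution.
* Mismatch totals, multi-mapped fragment counts and score offsets against
  a designated decoy reference are exact, so acceptance-criterion
  violations can be planted precisely (an offset-0 decoy plants a tie that
  removes uniqueness; the decoy's records are emitted after the true
  reference's, so the tie resolves back to the true reference).
* `n_lowscore` and `n_clip` plant reads that fail MAS and FMM
  respectively.

`community_truth()` computes the expected per-reference counts, abundances
and strain verdicts in closed form from the spec alone — deliberately
re-deriving the threshold arithmetic rather than calling the evaluators —
and serves as the oracle for end-to-end tests.

What the generator does **not** emulate: positional coverage bias, indel
CIGARs in planted reads (indels are exercised separately in the pileup
property tests), sequencing-error score distributions, chimeric or
discordant pairs, and real inter-genome homology (multi-mapping is planted
onto designated decoys, not discovered). Passing the planted-recovery
tests therefore demonstrates the correctness of the filtering, resolution
and criteria arithmetic — not robustness to real-data artifacts like
uneven coverage or database redundancy.

`planted_community()` is the package's standing study design: 8 species
(two of them two-strain; 10 strains) at size-normalized abundances
0.12–0.2 per strain, ~0.2% per-base mismatch, plus four contaminants each
violating exactly one criterion at strain level (ReadCount 9; mismatch
ratio 0.015; S_Abundance 0.009; unique fraction 1/250 = 0.004). It is
generated single-end because an odd ReadCount of exactly 9 is not
realizable in paired mode, where mates are counted in twos. The
uniqueness contaminant deserves a note: species-level evaluation omits
criterion IV, so it cannot be rejected there *by* IV — its abundance
(0.02) is instead planted below the lowest planted-species abundance
(0.15), and the pre-cycle threshold removes it at species level, while
the strain-level partition flags its criterion IV as planted. The genus
level, which uses only I–III, accepts its genus by design; genus-level
claims of this pipeline family rest on criteria I–III alone.

## Numerical and engineering choices

* SAM/BAM ingestion goes through Rsamtools (text SAM is converted to BAM
  in a temporary location without sorting, preserving file order for the
  tie-break); CIGAR arithmetic and reference-space projection use
  GenomicAlignments and IRanges. Pileup tallies are interval unions, not
  per-base arrays, so references of any size cost memory proportional to
  read count.
* Output tables print reals with 6 significant digits and sort by
  descending S_Abundance (ties by reference name): deterministic,
  byte-stable files.
* Unknown reference names degrade to an "unclassified" taxonomy path
  (warned once per lookup batch) instead of dropping rows, preserving
  read conservation.
* Degenerate inputs: empty SAM files yield empty tables and a zero-tallied
  summary with exit 0; missing files, duplicate taxonomy keys, malformed
  taxids, sizes missing for assigned references, and alignments running
  past the reference end are hard errors naming the offending input.

The test suite exercises the oracle-equivalence properties at fixed sizes
chosen to keep the default run fast while covering every code path: ~220
random pileup fixtures (references up to 10 kb, up to 500 reads), ~520
random fragments against 5 databases for resolution, 2000 random flag
fields, and the planted community (~21 000 reads) end to end. These sizes
are the package's own choice of a thorough-but-quick default; all
generators scale by argument if heavier runs are wanted.

## Known limitations

* Assignment is per reference sequence, not lowest-common-ancestor: a
  fragment tying across references is assigned deterministically, not
  promoted to a higher clade.
* `Seq_count` at aggregated levels counts member strain rows with
  assignments, not the number of database sequences in the clade.
* The read trimming / control-read removal stage is out of scope; the
  cleaned read count is an input (`total_clean_reads`), and R_Abundance
  is only as meaningful as that number.
* Spreadsheet export is not provided; the TSV outputs are the interface.
* Taxonomy ingestion expects the flat 17-column TSV; the
  `taxdump_to_taxonomy()` converter builds it from NCBI-style `nodes.dmp`
  / `names.dmp` offline.
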