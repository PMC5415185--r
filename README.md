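# taxmapr

Reference-based taxonomic classification of metagenomic sequence reads,
with false-positive-aware post-processing.

## What it does, and for whom

Shotgun metagenomics assigns millions of short reads to reference genomes
by alignment. Against large databases this vastly over-predicts the
species present unless the raw hits are filtered: random hits accumulate
with database size, reads from large genomes dominate naive read-count
abundances, and closely related references soak up each other's reads.
taxmapr is for bioinformaticians who already have per-database alignments
(any aligner emitting `AS` alignment-score and `NM` edit-distance tags;
one SAM/BAM per database) and want reliable strain / species / genus
calls plus honest reporting of everything that was rejected and why.

The core quantities:

* Per-record filters **MAS** (alignment score ≥ 30) and **FMM** (fraction
  of the full read length in CIGAR `M`/`=`/`X` state ≥ 0.8); in paired
  mode one failing mate removes the pair.
* Best-hit resolution by **SAS** (sum of mate alignment scores): in
  *bestmode* a fragment goes to its single best reference across
  databases (ties → first-specified database, then file order); each
  *fullmode* database independently keeps its own best hit (for gene
  catalogues nested inside genome databases). A fragment is **unique**
  when its SAS strictly beats every rival reference.
* Size-normalized abundance
  `S_Abundance = 100·ReadCount/Size` (single-end) or
  `100·ReadCount/(2·Size)` (paired-end), and
  `R_Abundance(%) = 100·ReadCount/cleaned-reads`.
* Acceptance criteria: **I** ReadCount ≥ 10, **II** Mismatches/Nucleotides
  < 0.01, **III** S_Abundance > 0.01, **IV** unique-read fraction > 0.5%.
  All four at strain level; I–III at genus and above; at species level a
  pre-cycle sets an adaptive S_Abundance threshold and criterion IV is
  dropped in the second pass. Accepted *and* rejected annotations are
  reported, so post-processing can be redone in seconds from the saved
  tables.

Statistics are aggregated at eight clade levels (strain → superkingdom)
by summing every column over references sharing a taxid — including the
ratio columns, as this table format prescribes, with recomputed
`coverage_ratio`/`depth_ratio` columns alongside for sanity.

## Worked example

The package ships a seeded synthetic-community generator, so a complete
run needs no external data. Two databases: a bestmode genome database and
a fullmode plasmid database.

```r
library(taxmapr)

refs <- data.frame(
  ref = c("EcoliK12_chr", "SentLT2_chr", "pResX"),
  db = c("bacteria", "bacteria", "plasmids"),
  size_bp = c(400000L, 300000L, 5000L),
  n_fragments = c(800L, 500L, 60L),
  total_mismatches = c(160L, 100L, 0L),
  species = c("Escherichia coli", "Salmonella enterica", "Plasmid X"),
  genus = c("Escherichia", "Salmonella", "PlasmidX"))

spec <- community_spec(refs,
  db_modes = c(bacteria = "bestmode", plasmids = "fullmode"),
  paired = TRUE, seed = 7)
bundle <- generate_community(spec, "example_fixture")

res <- run_classification(bundle$db_spec, bundle$taxonomy, bundle$sizes,
                          bundle$total_clean_reads, paired = TRUE)
res$strain[, c("db", "ref", "s_abundance", "r_abundance", "coverage",
               "depth", "read_count", "read_count_uniq", "mismatches")]
```

```
        db          ref s_abundance r_abundance coverage  depth read_count read_count_uniq mismatches
1 plasmids        pResX      1.2000       4.202   0.9262 2.4000        120             120          0
2 bacteria EcoliK12_chr      0.2000      56.022   0.3344 0.4000       1600            1600        160
3 bacteria  SentLT2_chr      0.1667      35.014   0.2791 0.3333       1000            1000        100
```

Reading the rows: each planted pair contributes 2 to `ReadCount`, so the
800 E. coli pairs give `read_count` 1600 and
`S_Abundance = 100·1600/(2·400000) = 0.2`. The 5 kb plasmid reaches a
far higher size-normalized abundance (1.2) from only 60 pairs — that is
exactly the size bias the measure corrects — and `depth` 2.4 with
`coverage` 0.93. The planted 160 mismatches give mismatch ratio
160/160000 = 0.001, well under criterion II.

```r
res$partitions$species$accepted[, c("db", "name", "s_abundance",
                                    "read_count", "read_count_uniq")]
```

```
        db                name s_abundance read_count read_count_uniq
1 bacteria    Escherichia coli      0.2000       1600            1600
2 bacteria Salmonella enterica      0.1667       1000            1000
3 plasmids           Plasmid X      1.2000        120             120
```

All three planted species are accepted; `res$partitions$species$rejected`
is empty. With `out_dir =` set, `run_classification()` also writes the
per-database strain tables (14 statistics + 16 taxonomy columns),
per-level accepted/rejected TSVs and a run summary;
`reprocess_strain_tables()` re-runs only the post-processing from those
files under different thresholds.

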