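#' Specify a synthetic community for fixture generation
#'
#' Describes a planted metagenomic sample: which reference sequences exist,
#' which database each lives in, and how many read fragments each receives,
#' with exact control over mismatch totals, multi-mapping and deliberately
#' filter-failing reads. Every random draw is fixed by `seed`, so the
#' generated bundle is byte-stable.
#'
#' @param refs Data.frame with one row per reference sequence. Required
#'   columns: `ref`, `db`, `size_bp`, `n_fragments`, `species`, `genus`.
#'   Optional columns (default 0 / absent): `total_mismatches` (substitution
#'   count distributed as evenly as possible over the reference's mates),
#'   `n_multimap` (how many of the fragments also hit `decoy_ref` with an
#'   alignment score offset of `decoy_offset`; offset 0 plants an exact
#'   score tie, making those fragments non-unique), `decoy_ref`, `decoy_db`
#'   (defaults to the reference's own database), `decoy_offset`,
#'   `n_lowscore` (extra fragments whose mismatch load pushes the alignment
#'   score below the default minimum of 30), `n_clip` (extra fragments with
#'   30% of the read soft-clipped, failing the default matched-fraction
#'   threshold of 0.8).
#' @param db_modes Named character vector mapping database name to
#'   `"bestmode"`/`"fullmode"`; names give the priority order. Defaults to
#'   every database in `refs` in first-appearance order, all bestmode.
#' @param read_length Read length in bp (default 100).
#' @param paired Paired-end fragments (default `TRUE`); mates are separated
#'   by a fixed fragment span of `2 * read_length + 50`.
#' @param seed Integer seed fixing every random draw.
#' @param score_per_mismatch Alignment scores are synthesized as
#'   `read_length - score_per_mismatch * mismatches` (default 5), emulating
#'   aligner scoring monotone in edit distance; only relative order matters.
#' @param total_clean_reads Cleaned read-set size for the sample context;
#'   default 5% above the total planted mates (the surplus plays the role of
#'   reads that map nowhere).
#' @return A `community_spec` list.
#' @export
community_spec <- function(refs, db_modes = NULL, read_length = 100L,
                           paired = TRUE, seed = 1L,
                           score_per_mismatch = 5L,
                           total_clean_reads = NULL) {
  need <- c("ref", "db", "size_bp", "n_fragments", "species", "genus")
  missing <- setdiff(need, names(refs))
  if (length(missing) > 0) {
    stop("refs lacks column(s): ", paste(missing, collapse = ", "))
  }
  defaults <- list(total_mismatches = 0L, n_multimap = 0L,
                   decoy_ref = NA_character_, decoy_db = NA_character_,
                   decoy_offset = 0L, n_lowscore = 0L, n_clip = 0L)
  for (nm in names(defaults)) {
    if (!nm %in% names(refs)) refs[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(refs$ref)) stop("reference names must be unique")
  span <- if (isTRUE(paired)) 2L * read_length + 50L else read_length
  if (any(refs$size_bp < span)) {
    stop("fragment span (", span, " bp) exceeds genome length for: ",
         paste(refs$ref[refs$size_bp < span], collapse = ", "))
  }
  if (any(refs$n_multimap > refs$n_fragments)) {
    stop("n_multimap cannot exceed n_fragments")
  }
  mm_needed <- !is.na(refs$decoy_ref) & refs$n_multimap > 0
  if (any(mm_needed & !(refs$decoy_ref %in% refs$ref))) {
    stop("decoy_ref must name another reference in the spec")
  }
  refs$decoy_db[mm_needed & is.na(refs$decoy_db)] <-
    refs$db[mm_needed & is.na(refs$decoy_db)]
  if (is.null(db_modes)) {
    db_modes <- stats::setNames(rep("bestmode", length(unique(refs$db))),
                                unique(refs$db))
  }
  stopifnot(all(refs$db %in% names(db_modes)),
            all(db_modes %in% c("bestmode", "fullmode")))
  mates <- if (isTRUE(paired)) 2L else 1L
  total_mates <- sum((refs$n_fragments + refs$n_lowscore + refs$n_clip) * mates)
  if (is.null(total_clean_reads)) {
    total_clean_reads <- as.integer(ceiling(total_mates * 1.05))
  }
  structure(list(refs = refs, db_modes = db_modes,
                 read_length = as.integer(read_length),
                 paired = isTRUE(paired), seed = as.integer(seed),
                 score_per_mismatch = as.integer(score_per_mismatch),
                 fragment_span = span,
                 total_clean_reads = as.integer(total_clean_reads)),
            class = "community_spec")
}

# Distribute a mismatch total over n mates as evenly as possible:
# the first (total mod n) mates get one extra.
split_mismatches <- function(total, n) {
  if (n == 0) return(integer())
  base <- total %/% n
  extra <- total %% n
  as.integer(base + (seq_len(n) <= extra))
}

# Synthetic taxids: deterministic per-level enumeration of the distinct
# names appearing in the spec, offset per level so ids never collide.
assign_taxids <- function(values, offset) {
  offset + match(values, unique(values))
}

#' Taxonomy table for a community spec
#'
#' Strain and species/genus names come from the spec; family through
#' superkingdom are filled with a single synthetic lineage, and all taxids
#' are synthetic (deterministic enumeration), which is sufficient for
#' taxid-keyed clade aggregation.
#'
#' @param spec A [community_spec()].
#' @return Data.frame in the 17-column taxonomy layout of [read_taxonomy()].
#' @export
community_taxonomy <- function(spec) {
  r <- spec$refs
  out <- data.frame(ref_name = r$ref, stringsAsFactors = FALSE)
  out$strain_taxid <- assign_taxids(r$ref, 100000L)
  out$strain_name <- r$ref
  out$species_taxid <- assign_taxids(r$species, 200000L)
  out$species_name <- r$species
  out$genus_taxid <- assign_taxids(r$genus, 300000L)
  out$genus_name <- r$genus
  fillers <- c(family = "Syntheticaceae", order = "Syntheticales",
               class = "Synthetia", phylum = "Synthetica",
               superkingdom = "Bacteria")
  for (i in seq_along(fillers)) {
    lev <- names(fillers)[i]
    out[[paste0(lev, "_taxid")]] <- 400000L + i
    out[[paste0(lev, "_name")]] <- unname(fillers[i])
  }
  out
}

# One SAM line. seq is a run of A's: the reads are never re-aligned, only
# their CIGAR/tags matter to the method.
sam_line <- function(qname, flag, ref, pos, cigar, rnext, pnext, tlen,
                     seqlen, score, nm) {
  paste(qname, flag, ref, pos, 60L, cigar, rnext, pnext, tlen,
        strrep("A", seqlen), strrep("I", seqlen),
        paste0("AS:i:", score), paste0("NM:i:", nm), sep = "\t")
}

#' Generate a fixture bundle from a community spec
#'
#' Writes, under `dir`: one SAM file per database (`<db>.sam`, with `@SQ`
#' headers), the taxonomy TSV (`taxonomy.tsv`), the reference size table
#' (`sizes.tsv`) and optionally a reference FASTA (`refs.fasta`, random
#' sequence — fixture reads carry placeholder bases and are never
#' re-aligned, so only the lengths are meaningful). Fragment placement is
#' uniform over each reference; a fragment's records on its decoy reference
#' are emitted after the records on its true reference, so an exact score
#' tie resolves to the true reference under file-order tie-breaking.
#'
#' @param spec A [community_spec()].
#' @param dir Output directory (created if needed).
#' @param write_fasta Whether to write the reference FASTA (default `FALSE`;
#'   enable when genomes are small enough that the file is wanted).
#' @return A list: `sam` (named paths per database), `taxonomy`, `sizes`,
#'   `fasta` (or `NULL`), `db_spec` (a [db_spec()] with paths filled in),
#'   `total_clean_reads`, `paired`, `truth` (the [community_truth()] table).
#' @export
generate_community <- function(spec, dir, write_fasta = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  L <- spec$read_length
  span <- spec$fragment_span
  k <- spec$score_per_mismatch
  r <- spec$refs
  chunks <- stats::setNames(
    vector("list", length(spec$db_modes)), names(spec$db_modes))
  emit <- function(db, lines) {
    if (length(lines) > 0) chunks[[db]][[length(chunks[[db]]) + 1L]] <<- lines
  }
  # Vectorized emission of n fragments on one reference. mm holds each
  # fragment's mismatch count; paired mode splits it between the mates.
  # Returns the SAM lines, mate-interleaved in fragment order.
  fragment_lines <- function(qnames, ref, size, mm, cigar_kept = L,
                             score_offset = 0L) {
    n <- length(qnames)
    if (n == 0) return(character())
    clip <- L - cigar_kept
    cg <- if (clip > 0) paste0(cigar_kept, "M", clip, "S") else paste0(L, "M")
    if (spec$paired) {
      p1 <- sample.int(size - span + 1L, n, replace = TRUE)
      p2 <- p1 + span - cigar_kept
      mm1 <- (mm + 1L) %/% 2L
      mm2 <- mm %/% 2L
      l1 <- sam_line(qnames, 99L, ref, p1, cg, "=", p2, span, L,
                     L - k * mm1 + score_offset, mm1)
      l2 <- sam_line(qnames, 147L, ref, p2, cg, "=", p1, -span, L,
                     L - k * mm2 + score_offset, mm2)
      as.vector(rbind(l1, l2))
    } else {
      p <- sample.int(size - cigar_kept + 1L, n, replace = TRUE)
      sam_line(qnames, 0L, ref, p, cg, "*", 0L, 0L, L,
               L - k * mm + score_offset, mm)
    }
  }

  for (i in seq_len(nrow(r))) {
    ri <- r[i, ]
    n <- ri$n_fragments
    mm_frag <- split_mismatches(ri$total_mismatches, n)
    qn <- sprintf("frag_%s_%05d", ri$ref, seq_len(n))
    emit(ri$db, fragment_lines(qn, ri$ref, ri$size_bp, mm_frag))
    if (ri$n_multimap > 0) {
      # decoy records are emitted after the true-reference block, so an
      # exact score tie resolves to the true reference by file order
      # (within one database) or by database priority (across databases)
      m <- seq_len(ri$n_multimap)
      decoy_size <- r$size_bp[match(ri$decoy_ref, r$ref)]
      emit(ri$decoy_db,
           fragment_lines(qn[m], ri$decoy_ref, decoy_size, mm_frag[m],
                          score_offset = as.integer(ri$decoy_offset)))
    }
    # Reads built to fail the default quality filters: enough mismatches to
    # sink the alignment score below 30, or a 30% soft clip to sink the
    # matched fraction below 0.8. They never reach the statistics stage.
    if (ri$n_lowscore > 0) {
      low_mm <- rep(as.integer(ceiling((L - 29L) / k)) *
                      (if (spec$paired) 2L else 1L), ri$n_lowscore)
      qn_low <- sprintf("low_%s_%05d", ri$ref, seq_len(ri$n_lowscore))
      emit(ri$db, fragment_lines(qn_low, ri$ref, ri$size_bp, low_mm))
    }
    if (ri$n_clip > 0) {
      kept <- L - as.integer(ceiling(0.3 * L))
      qn_clip <- sprintf("clip_%s_%05d", ri$ref, seq_len(ri$n_clip))
      emit(ri$db, fragment_lines(qn_clip, ri$ref, ri$size_bp,
                                 rep(0L, ri$n_clip), cigar_kept = kept))
    }
  }

  sam_paths <- character()
  for (d in names(spec$db_modes)) {
    # @SQ lines cover every reference a record of this file can name:
    # the database's own references plus decoys targeted into it
    decoys <- r$decoy_ref[!is.na(r$decoy_db) & r$decoy_db == d &
                            r$n_multimap > 0]
    sq <- r[r$db == d | r$ref %in% decoys, ]
    sq <- sq[!duplicated(sq$ref), ]
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", sq$ref, sq$size_bp))
    path <- file.path(dir, paste0(d, ".sam"))
    writeLines(c(header, unlist(chunks[[d]])), path)
    sam_paths[d] <- path
  }

  tax <- community_taxonomy(spec)
  tax_path <- file.path(dir, "taxonomy.tsv")
  write_tsv_na(tax, tax_path)

  sizes <- data.frame(ref_name = r$ref, size_bp = r$size_bp,
                      description = paste(r$species, "strain", r$ref),
                      stringsAsFactors = FALSE)
  sizes_path <- file.path(dir, "sizes.tsv")
  write_tsv_na(sizes, sizes_path)

  fasta_path <- NULL
  if (isTRUE(write_fasta)) {
    fasta_path <- file.path(dir, "refs.fasta")
    seqs <- vapply(r$size_bp, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
    writeLines(paste0(">", r$ref, " ", sizes$description, "\n", seqs),
               fasta_path)
  }

  specs <- db_spec(names(spec$db_modes), mode = unname(spec$db_modes),
                   path = unname(sam_paths[names(spec$db_modes)]))
  list(sam = sam_paths, taxonomy = tax_path, sizes = sizes_path,
       fasta = fasta_path, db_spec = specs,
       total_clean_reads = spec$total_clean_reads, paired = spec$paired,
       truth = community_truth(spec))
}

#' Expected per-reference outcomes for a community spec
#'
#' Closed-form truth table computed from the spec parameters alone, without
#' running any pipeline stage: planted read counts (mates), unique counts
#' (fragments whose decoy score offset is nonzero or absent remain unique),
#' mismatch totals, nucleotides, the two abundance measures and the
#' strain-level verdict under the default acceptance criteria. The
#' threshold arithmetic here is written out directly so the table serves as
#' an independent oracle for end-to-end tests.
#'
#' @param spec A [community_spec()].
#' @return Data.frame, one row per reference with `n_fragments > 0`.
#' @export
community_truth <- function(spec) {
  r <- spec$refs[spec$refs$n_fragments > 0, , drop = FALSE]
  mates <- if (spec$paired) 2L else 1L
  rc <- r$n_fragments * mates
  # an exact score tie (offset 0) on a decoy removes uniqueness; a worse
  # decoy score (offset < 0) leaves the fragment unique
  tied <- ifelse(r$n_multimap > 0 & r$decoy_offset == 0, r$n_multimap, 0L)
  uniq <- (r$n_fragments - tied) * mates
  nt <- rc * spec$read_length
  s_ab <- 100 * rc / (mates * r$size_bp)
  r_ab <- 100 * rc / spec$total_clean_reads
  mm_ratio <- ifelse(nt > 0, r$total_mismatches / nt, 0)
  uniq_frac <- ifelse(rc > 0, uniq / rc, 0)
  pass_I <- rc >= 10
  pass_II <- mm_ratio < 0.01
  pass_III <- s_ab > 0.01
  pass_IV <- uniq_frac > 0.005
  failed <- mapply(function(a, b, c, d) {
    paste(c("I", "II", "III", "IV")[!c(a, b, c, d)], collapse = ",")
  }, pass_I, pass_II, pass_III, pass_IV)
  data.frame(ref = r$ref, db = r$db, species = r$species, genus = r$genus,
             size_bp = r$size_bp, read_count = rc, read_count_uniq = uniq,
             mismatches = r$total_mismatches, nucleotides = nt,
             s_abundance = s_ab, r_abundance = r_ab,
             mismatch_ratio = mm_ratio, unique_fraction = uniq_frac,
             strain_accepted = pass_I & pass_II & pass_III & pass_IV,
             strain_failed = failed, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' A planted benchmark community with contaminants
#'
#' The package's standing end-to-end study design: a single-end sample over
#' one bestmode bacterial database containing 8 planted species (two of
#' them with two strains, 10 strains in all) at size-normalized abundances
#' comfortably above every threshold, plus four low-level contaminants each
#' violating exactly one acceptance criterion at strain level:
#' \itemize{
#'   \item `contam_lowcount`: 9 reads (criterion I, ReadCount below 10);
#'   \item `contam_mismatch`: mismatch ratio 0.015 (criterion II);
#'   \item `contam_lowabund`: size-normalized abundance 0.009 (criterion III);
#'   \item `contam_nonuniq`: unique read fraction 1/250 = 0.004
#'     (criterion IV), planted by score-tied multi-mapping of 249 of its 250
#'     reads onto a decoy reference; its abundance (0.02) also sits below
#'     every planted species' abundance, so the species-level pre-cycle
#'     threshold removes it there.
#' }
#' Single-end reads are used so that an odd read count of exactly 9 is
#' realizable (paired mode counts mates in twos).
#'
#' @param seed Integer seed passed to [community_spec()].
#' @return A [community_spec()].
#' @export
planted_community <- function(seed = 1L) {
  refs <- data.frame(
    ref = c("Eco_K12", "Bam_DSM7", "Bce_ATCC14579", "Pae_PAO1", "Pae_PA14",
            "Ppu_KT2440", "Mlu_NCTC2665", "Rca_SB1003", "Sco_A32",
            "Sco_M145",
            "contam_lowcount", "contam_mismatch", "contam_lowabund",
            "contam_nonuniq", "decoy_ref"),
    db = "bacteria",
    size_bp = c(1500000L, 1200000L, 1600000L, 1400000L, 1300000L,
                1000000L, 800000L, 900000L, 2000000L, 1800000L,
                20000L, 30000L, 200000L, 1250000L, 1250000L),
    n_fragments = c(3000L, 2400L, 2400L, 2100L, 1950L,
                    1500L, 1200L, 1350L, 2400L, 2160L,
                    9L, 30L, 18L, 250L, 0L),
    total_mismatches = c(600L, 480L, 480L, 420L, 390L,
                         300L, 240L, 270L, 480L, 432L,
                         0L, 45L, 0L, 0L, 0L),
    n_multimap = c(rep(0L, 13), 249L, 0L),
    decoy_ref = c(rep(NA_character_, 13), "decoy_ref", NA),
    decoy_db = NA_character_,
    decoy_offset = 0L,
    n_lowscore = 0L,
    n_clip = 0L,
    species = c("Escherichia coli", "Bacillus amyloliquefaciens",
                "Bacillus cereus", "Pseudomonas aeruginosa",
                "Pseudomonas aeruginosa", "Pseudomonas putida",
                "Micrococcus luteus", "Rhodobacter capsulatus",
                "Streptomyces coelicolor", "Streptomyces coelicolor",
                "Contaminantia lowcount", "Contaminantia mismatchia",
                "Contaminantia lowabunda", "Contaminantia nonuniqua",
                "Decoyella synthetica"),
    genus = c("Escherichia", "Bacillus", "Bacillus", "Pseudomonas",
              "Pseudomonas", "Pseudomonas", "Micrococcus", "Rhodobacter",
              "Streptomyces", "Streptomyces",
              "Contaminantia", "Contaminantia", "Contaminantia",
              "Contaminantia", "Decoyella"),
    stringsAsFactors = FALSE
  )
  community_spec(refs, read_length = 100L, paired = FALSE, seed = seed)
}
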