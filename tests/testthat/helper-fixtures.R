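# In-code fixture builders and independent oracles shared by the tests.

# Alignment record data.frame with sensible defaults, as produced by
# read_alignments().
make_records <- function(qname = "q1", flag = 0L, ref = "r1", pos = 1L,
                         cigar = "100M", read_length = 100L, score = 60L,
                         edit_dist = 0L, mate = 0L, db = "d1") {
  df <- data.frame(qname = qname, flag = as.integer(flag), ref = ref,
                   pos = as.integer(pos), cigar = cigar,
                   read_length = as.integer(read_length),
                   score = as.integer(score),
                   edit_dist = as.integer(edit_dist),
                   mate = as.integer(mate), db = db,
                   stringsAsFactors = FALSE)
  df$rec <- seq_len(nrow(df))
  df
}

# Serialize records to a SAM file so the Rsamtools-backed reader can be
# round-tripped against in-memory fixtures.
write_sam <- function(records, path, ref_sizes) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_sizes),
                      as.integer(ref_sizes)))
  seq <- strrep("A", records$read_length)
  lines <- paste(records$qname, records$flag, records$ref, records$pos, 60L,
                 records$cigar, "*", 0L, 0L, seq,
                 strrep("I", records$read_length),
                 paste0("AS:i:", records$score),
                 paste0("NM:i:", records$edit_dist), sep = "\t")
  writeLines(c(header, lines), path)
  path
}

# --- independent oracles -------------------------------------------------

# Brute-force pileup: walk each CIGAR with a regex parser (independent of
# the GenomicAlignments machinery used by the implementation) and tally a
# per-position depth array.
oracle_pileup <- function(pos, cigar, size_bp) {
  depth <- integer(size_bp)
  nt <- 0L
  for (i in seq_along(pos)) {
    ops <- regmatches(cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", cigar[i]))[[1]]
    at <- pos[i]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        depth[at:(at + len - 1L)] <- depth[at:(at + len - 1L)] + 1L
        nt <- nt + len
        at <- at + len
      } else if (type %in% c("D", "N")) {
        at <- at + len
      }
      # I, S, H, P consume no reference
    }
  }
  list(covered_positions = sum(depth > 0L), nucleotides = nt)
}

# Random CIGAR over ops S/M/I/D whose query-consuming lengths sum to
# read_length, for property tests.
random_cigar <- function(read_length) {
  rem <- read_length
  parts <- character()
  lead <- sample(0:min(10L, rem - 1L), 1L)
  if (lead > 0) {
    parts <- c(parts, paste0(lead, "S"))
    rem <- rem - lead
  }
  first <- TRUE
  while (rem > 0) {
    m <- sample(seq_len(rem), 1L)
    parts <- c(parts, paste0(m, "M"))
    rem <- rem - m
    first <- FALSE
    if (rem > 1 && stats::runif(1) < 0.4) {
      if (stats::runif(1) < 0.5) {
        i <- sample(seq_len(min(3L, rem - 1L)), 1L)
        parts <- c(parts, paste0(i, "I"))
        rem <- rem - i
      } else {
        parts <- c(parts, paste0(sample(1:5, 1L), "D"))
      }
    }
  }
  paste(parts, collapse = "")
}

# Exhaustive best-hit resolution: straight loops over a fragment's hits,
# re-deriving argmax, tie-breaks and uniqueness from first principles.
oracle_resolve_scope <- function(h, prio) {
  stopifnot(nrow(h) > 0)
  best <- NULL
  for (i in seq_len(nrow(h))) {
    if (is.null(best)) {
      best <- i
      next
    }
    if (h$sas[i] > h$sas[best]) best <- i
    else if (h$sas[i] == h$sas[best]) {
      if (prio[i] < prio[best]) best <- i
      else if (prio[i] == prio[best] && h$first_rec[i] < h$first_rec[best]) {
        best <- i
      }
    }
  }
  other <- h$sas[!(h$ref == h$ref[best] & h$db == h$db[best])]
  list(idx = best, unique = length(other) == 0 || h$sas[best] > max(other))
}

# Reference flag-mask semantics computed without bitwAnd: -F 256 -f 2 in
# paired mode, -F 260 single-end.
oracle_keep <- function(flag, paired) {
  bit <- function(f, b) (f %/% b) %% 2L == 1L
  if (paired) !bit(flag, 256L) & bit(flag, 2L)
  else !bit(flag, 256L) & !bit(flag, 4L)
}

# A small two-database paired-end community reused by several tests.
small_community <- function(seed = 11L, paired = TRUE) {
  refs <- data.frame(
    ref = c("refA1", "refA2", "refB", "gene1", "decoyX"),
    db = c("bact", "bact", "bact", "genes", "bact"),
    size_bp = c(60000L, 50000L, 40000L, 2000L, 60000L),
    n_fragments = c(150L, 120L, 100L, 40L, 0L),
    total_mismatches = c(30L, 0L, 20L, 0L, 0L),
    n_multimap = c(20L, 0L, 0L, 0L, 0L),
    decoy_ref = c("decoyX", NA, NA, NA, NA),
    n_lowscore = c(4L, 0L, 0L, 0L, 0L),
    n_clip = c(0L, 3L, 0L, 0L, 0L),
    species = c("Species alpha", "Species alpha", "Species beta",
                "Resistance gene one", "Decoy species"),
    genus = c("Alphagenus", "Alphagenus", "Betagenus", "Genegenus",
              "Decoygenus"),
    stringsAsFactors = FALSE)
  community_spec(refs,
                 db_modes = c(bact = "bestmode", genes = "fullmode"),
                 paired = paired, seed = seed)
}
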