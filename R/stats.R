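#' Size-normalized read count abundance
#'
#' `100 * read_count / size_bp` for single-end reads and
#' `100 * read_count / (2 * size_bp)` for paired-end reads. ReadCount counts
#' individual mates, so the paired form's division by 2 converts mate counts
#' to fragment equivalents; the factor 100 is for convenience of scale.
#'
#' @param read_count Non-negative integer vector (mates mapped).
#' @param size_bp Positive integer vector of reference lengths.
#' @param paired Logical; paired-end mode.
#' @return Numeric vector of abundances.
#' @export
s_abundance <- function(read_count, size_bp, paired = TRUE) {
  if (any(is.na(size_bp) | size_bp <= 0)) {
    stop("size_bp must be positive for every reference")
  }
  denom <- if (isTRUE(paired)) 2 * size_bp else size_bp
  100 * read_count / denom
}

#' Read count abundance as a percentage of the cleaned read set
#'
#' The number of reads mapped to a reference or clade relative to the number
#' of reads remaining after trimming and control-read removal (that cleaned
#' set is 100%). Numerator and denominator are in the same unit: individual
#' mates in paired mode, reads in single-end mode.
#'
#' @param read_count Non-negative integer vector.
#' @param total_clean_reads Positive scalar: size of the cleaned read set.
#' @return Numeric vector of percentages.
#' @export
r_abundance <- function(read_count, total_clean_reads) {
  if (length(total_clean_reads) != 1 || is.na(total_clean_reads) ||
      total_clean_reads <= 0) {
    stop("total_clean_reads must be a single positive count")
  }
  100 * read_count / total_clean_reads
}

#' Covered positions and mapped nucleotides for one reference
#'
#' Pileup-style tallies from the alignment records assigned to one
#' reference: `nucleotides` is the total number of read bases placed on the
#' reference (summed CIGAR `M`/`=`/`X` lengths over all records);
#' `covered_positions` is the number of distinct reference positions under
#' at least one such base. Deletions (`D`) and skips (`N`) advance the
#' reference without contributing bases or coverage; insertions and clips
#' contribute nothing.
#'
#' @param pos Integer vector of 1-based leftmost mapped positions.
#' @param cigar Character vector of CIGAR strings (same length as `pos`).
#' @param size_bp Reference length; an alignment extending past it is a hard
#'   error naming the record.
#' @return Named list with `covered_positions` and `nucleotides`.
#' @export
pileup_stats <- function(pos, cigar, size_bp) {
  stopifnot(length(pos) == length(cigar), size_bp > 0)
  if (length(pos) == 0) {
    return(list(covered_positions = 0L, nucleotides = 0L))
  }
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  flat <- unlist(rl, use.names = FALSE)
  ends <- vapply(seq_along(pos), function(i) {
    if (length(rl[[i]]) == 0) 0L else max(IRanges::end(rl[[i]]))
  }, 0L)
  if (any(ends > size_bp)) {
    bad <- which(ends > size_bp)[1]
    stop("alignment record ", bad, " (pos ", pos[bad], ", cigar ", cigar[bad],
         ") extends past reference end (", size_bp, " bp)")
  }
  list(
    covered_positions = sum(IRanges::width(IRanges::reduce(flat))),
    nucleotides = sum(IRanges::width(flat))
  )
}

#' Per-reference read count statistics from resolved assignments
#'
#' Builds the strain-level statistics table: one row per reference sequence
#' with at least one assigned fragment in its database. ReadCount counts
#' individual mates (a properly paired fragment contributes 2); ReadCount
#' uniq counts the mates of uniquely assigned fragments; Mismatches is the
#' summed edit distance (NM) over counted records; Nucleotides and Covered
#' positions come from [pileup_stats()]; Coverage and Depth are the ratios
#' to reference size; abundances follow [s_abundance()] and [r_abundance()].
#'
#' @param assignments Assignment table from [resolve_hits()] (or one of the
#'   per-scope resolvers), typically restricted to one scope.
#' @param records Surviving alignment records from [filter_alignments()].
#' @param ref_sizes Data.frame with columns `ref_name`, `size_bp` and
#'   optionally `description`.
#' @param total_clean_reads Cleaned read-set size for [r_abundance()].
#' @param paired Logical; paired-end mode.
#' @return A data.frame with columns `db`, `ref`, `s_abundance`,
#'   `r_abundance`, `size_bp`, `seq_count` (always 1 at strain level),
#'   `nucleotides`, `covered_positions`, `coverage`, `depth`, `read_count`,
#'   `read_count_uniq`, `mismatches`, `description`.
#' @export
reference_stats <- function(assignments, records, ref_sizes,
                            total_clean_reads, paired = TRUE) {
  stopifnot(all(c("ref_name", "size_bp") %in% names(ref_sizes)))
  empty <- data.frame(db = character(), ref = character(),
                      s_abundance = numeric(), r_abundance = numeric(),
                      size_bp = integer(), seq_count = integer(),
                      nucleotides = integer(), covered_positions = integer(),
                      coverage = numeric(), depth = numeric(),
                      read_count = integer(), read_count_uniq = integer(),
                      mismatches = integer(), description = character(),
                      stringsAsFactors = FALSE)
  if (nrow(assignments) == 0) return(empty)
  missing <- setdiff(unique(assignments$ref), ref_sizes$ref_name)
  if (length(missing) > 0) {
    stop("reference(s) missing from the size table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  adt <- data.table::as.data.table(
    assignments[, c("qname", "db", "ref", "unique")])
  rdt <- data.table::as.data.table(records)
  j <- rdt[adt, on = c("qname", "db", "ref"), nomatch = NULL]
  per <- j[, {
    ps <- pileup_stats(pos, cigar,
                       ref_sizes$size_bp[match(ref[1], ref_sizes$ref_name)])
    list(read_count = .N,
         read_count_uniq = sum(unique),
         mismatches = sum(edit_dist),
         nucleotides = ps$nucleotides,
         covered_positions = ps$covered_positions)
  }, by = list(db, ref)]
  out <- as.data.frame(per)
  idx <- match(out$ref, ref_sizes$ref_name)
  out$size_bp <- as.integer(ref_sizes$size_bp[idx])
  out$description <- if ("description" %in% names(ref_sizes)) {
    as.character(ref_sizes$description[idx])
  } else {
    out$ref
  }
  out$seq_count <- 1L
  out$coverage <- out$covered_positions / out$size_bp
  out$depth <- out$nucleotides / out$size_bp
  out$s_abundance <- s_abundance(out$read_count, out$size_bp, paired)
  out$r_abundance <- r_abundance(out$read_count, total_clean_reads)
  out <- out[, names(empty)]
  out <- out[order(-out$s_abundance, out$ref), ]
  rownames(out) <- NULL
  out
}

#' Read a reference size table from TSV or FASTA
#'
#' @param path Either a TSV with header columns `ref_name`, `size_bp` and
#'   optionally `description`, or a FASTA file (detected by a leading `>`),
#'   in which case sequence lengths are taken from the headers' first
#'   whitespace-delimited token and descriptions from the remainder.
#' @return Data.frame with `ref_name`, `size_bp`, `description`.
#' @export
read_ref_sizes <- function(path) {
  if (!file.exists(path)) stop("reference size file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    lens <- Biostrings::fasta.seqlengths(path)
    full <- names(lens)
    tok <- sub("\\s.*$", "", full)
    desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), tok)
    return(data.frame(ref_name = tok, size_bp = as.integer(lens),
                      description = desc, stringsAsFactors = FALSE,
                      row.names = NULL))
  }
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        quote = "", encoding = "UTF-8"))
  stopifnot(all(c("ref_name", "size_bp") %in% names(df)))
  df$size_bp <- as.integer(df$size_bp)
  if (!"description" %in% names(df)) df$description <- df$ref_name
  df[, c("ref_name", "size_bp", "description")]
}
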