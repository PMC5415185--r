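# SAM flag bits used by the acceptance rules.
FLAG_PAIRED <- 0x1L
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE1 <- 0x40L
FLAG_MATE2 <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Filtering thresholds for individual alignments
#'
#' @param mas Minimum alignment score: an alignment is kept only if its
#'   aligner-reported score (AS tag) is at least `mas`. Default 30.
#' @param fmm Minimum matched fraction: the fraction of the read's full
#'   length (clipped bases included in the denominator) covered by CIGAR
#'   match/mismatch operations (`M`, `=`, `X`) must be at least `fmm`.
#'   Default 0.8.
#' @param paired Whether the sample is paired-end. In paired mode a fragment
#'   is kept only if both mates pass; a single failing mate removes the pair.
#' @return A `filter_config` list.
#' @export
filter_config <- function(mas = 30L, fmm = 0.8, paired = TRUE) {
  stopifnot(length(mas) == 1, length(fmm) == 1, fmm >= 0, fmm <= 1)
  structure(list(mas = as.integer(mas), fmm = as.numeric(fmm),
                 paired = isTRUE(paired)),
            class = "filter_config")
}

#' Read alignment records from a SAM or BAM file
#'
#' Parses one alignment file produced against one reference database. Plain
#' text SAM is converted to BAM internally (the format is auto-detected from
#' the BAM magic bytes); records are returned for all reads including
#' unmapped and secondary ones, so that candidate selection can be applied
#' explicitly downstream.
#'
#' @param path SAM or BAM file. SAM input must carry `@SQ` header lines.
#' @param db Database name attached to every record.
#' @return A data.frame with one row per alignment record: `qname`, `flag`,
#'   `ref`, `pos`, `cigar`, `read_length` (query length including soft- and
#'   hard-clipped bases where recoverable), `score` (AS tag, `NA` if
#'   missing), `edit_dist` (NM tag, `NA` if missing), `mate` (1 or 2 for
#'   paired records, 0 for single-end), `db`, and `rec` (record index in
#'   file order, used for deterministic tie-breaking).
#' @export
read_alignments <- function(path, db = "db") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  magic <- readBin(path, "raw", n = 4)
  is_bam <- length(magic) == 4 &&
    (identical(magic[1:2], as.raw(c(0x1f, 0x8b))) ||
       identical(rawToChar(magic), "BAM\1"))
  if (!is_bam) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "pos", "cigar", "qwidth")
  p <- Rsamtools::ScanBamParam(what = what, tag = c("AS", "NM"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  cigar <- res$cigar
  read_length <- res$qwidth
  if (n > 0) {
    # qwidth excludes hard-clipped bases; add them back where the CIGAR
    # records them so the matched-fraction denominator is the full read.
    has_cigar <- !is.na(cigar)
    if (any(has_cigar)) {
      hard <- integer(n)
      hl <- GenomicAlignments::explodeCigarOpLengths(cigar[has_cigar], ops = "H")
      hard[has_cigar] <- vapply(hl, sum, 0L)
      read_length <- read_length + hard
    }
  }
  mate <- integer(n)
  if (n > 0) {
    fl <- res$flag
    mate[bitwAnd(fl, FLAG_PAIRED) != 0 & bitwAnd(fl, FLAG_MATE1) != 0] <- 1L
    mate[bitwAnd(fl, FLAG_PAIRED) != 0 & bitwAnd(fl, FLAG_MATE2) != 0] <- 2L
  }
  as_int_tag <- function(x) {
    if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
  }
  data.frame(
    qname = as.character(res$qname),
    flag = as.integer(res$flag),
    ref = as.character(res$rname),
    pos = as.integer(res$pos),
    cigar = as.character(cigar),
    read_length = as.integer(read_length),
    score = as_int_tag(res$tag$AS),
    edit_dist = as_int_tag(res$tag$NM),
    mate = mate,
    db = rep_len(db, n),
    rec = seq_len(n),
    stringsAsFactors = FALSE
  )
}

#' Candidate selection by SAM flag logic
#'
#' Reproduces the flag masks of `samtools view -F 256 -f 2` (paired mode:
#' drop secondary alignments, require properly paired) and
#' `samtools view -F 260` (single-end mode: drop secondary and unmapped).
#'
#' @param flag Integer vector of SAM flag fields.
#' @param paired Logical; paired-end mode.
#' @return Logical vector: `TRUE` for records that remain candidates.
#' @export
keep_candidate <- function(flag, paired = TRUE) {
  flag <- as.integer(flag)
  if (isTRUE(paired)) {
    bitwAnd(flag, FLAG_SECONDARY) == 0L & bitwAnd(flag, FLAG_PROPER_PAIR) != 0L
  } else {
    bitwAnd(flag, bitwOr(FLAG_SECONDARY, FLAG_UNMAPPED)) == 0L
  }
}

#' Fraction of a read aligned in match/mismatch state
#'
#' The summed lengths of CIGAR `M`, `=` and `X` operations divided by the
#' full read length (soft/hard-clipped bases count in the denominator only).
#'
#' @param cigar Character vector of CIGAR strings.
#' @param read_length Integer vector of full read lengths.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
matched_fraction <- function(cigar, read_length) {
  if (any(is.na(read_length) | read_length <= 0)) {
    stop("read_length must be a positive integer for every record")
  }
  if (any(is.na(cigar) | cigar == "*")) {
    stop("matched_fraction requires an alignment CIGAR for every record")
  }
  m <- GenomicAlignments::explodeCigarOpLengths(cigar, ops = c("M", "=", "X"))
  vapply(m, sum, 0L) / read_length
}

#' Per-record alignment quality filter
#'
#' A record passes when its alignment score is at least `cfg$mas` and its
#' matched fraction is at least `cfg$fmm`; both thresholds are inclusive
#' minima. Records with a missing score or edit distance never pass (the
#' method is undefined without them).
#'
#' @param records Data.frame of alignment records (see [read_alignments()]).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per record.
#' @export
pass_read_filter <- function(records, cfg = filter_config()) {
  ok_tags <- !is.na(records$score) & !is.na(records$edit_dist)
  frac <- rep(NA_real_, nrow(records))
  usable <- ok_tags & !is.na(records$cigar) & records$cigar != "*" &
    !is.na(records$read_length) & records$read_length > 0
  if (any(usable)) {
    frac[usable] <- matched_fraction(records$cigar[usable],
                                     records$read_length[usable])
  }
  usable & records$score >= cfg$mas & frac >= cfg$fmm
}

#' Apply candidate selection and quality filters, yielding fragment hits
#'
#' The full alignment-filtering step for one or more databases: drop
#' supplementary records, apply the candidate flag logic ([keep_candidate()]),
#' apply the per-record score and matched-fraction filter
#' ([pass_read_filter()]), and in paired mode remove a fragment's candidate
#' assignment to a reference unless both mates are present and both pass.
#'
#' @param records Data.frame of alignment records from [read_alignments()]
#'   (rows from several databases may be concatenated).
#' @param cfg A [filter_config()].
#' @return A list:
#'   \describe{
#'     \item{hits}{one row per surviving (fragment, database, reference)
#'       combination: `qname`, `db`, `ref`, `sas` (summed mate alignment
#'       scores), `n_mates`, `first_rec` (earliest record index, for
#'       file-order tie-breaking).}
#'     \item{records}{the surviving alignment records backing those hits.}
#'     \item{diagnostics}{named counts: `total`, `supplementary`,
#'       `not_candidate`, `missing_tags`, `failed_quality`,
#'       `incomplete_pair`, `passed_records`.}
#'   }
#' @export
filter_alignments <- function(records, cfg = filter_config()) {
  stopifnot(is.data.frame(records))
  diag <- c(total = nrow(records), supplementary = 0L, not_candidate = 0L,
            missing_tags = 0L, failed_quality = 0L, incomplete_pair = 0L,
            incomplete_pair_records = 0L, passed_records = 0L)
  empty_hits <- data.frame(qname = character(), db = character(),
                           ref = character(), sas = integer(),
                           n_mates = integer(), first_rec = integer(),
                           stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    return(list(hits = empty_hits, records = records, diagnostics = diag))
  }
  supp <- bitwAnd(records$flag, FLAG_SUPPLEMENTARY) != 0L
  diag["supplementary"] <- sum(supp)
  rec <- records[!supp, , drop = FALSE]
  cand <- keep_candidate(rec$flag, cfg$paired)
  diag["not_candidate"] <- sum(!cand)
  rec <- rec[cand, , drop = FALSE]
  if (nrow(rec) > 0) {
    diag["missing_tags"] <- sum(is.na(rec$score) | is.na(rec$edit_dist))
    pass <- pass_read_filter(rec, cfg)
    diag["failed_quality"] <- sum(!pass) - diag[["missing_tags"]]
    rec <- rec[pass, , drop = FALSE]
  }
  if (nrow(rec) == 0) {
    return(list(hits = empty_hits, records = rec, diagnostics = diag))
  }
  dt <- data.table::as.data.table(rec)
  if (cfg$paired) {
    grp <- dt[, list(sas = sum(score), n_mates = .N,
                     mates_ok = (.N == 2L && all(sort(mate) == c(1L, 2L))),
                     first_rec = min(rec)),
              by = list(qname, db, ref)]
    bad <- !grp$mates_ok
    diag["incomplete_pair"] <- sum(bad)
    grp <- grp[!bad]
    before <- nrow(dt)
    dt <- dt[grp[, list(qname, db, ref)], on = c("qname", "db", "ref")]
    diag["incomplete_pair_records"] <- before - nrow(dt)
  } else {
    grp <- dt[, list(sas = sum(score), n_mates = .N, mates_ok = TRUE,
                     first_rec = min(rec)),
              by = list(qname, db, ref)]
  }
  grp[, mates_ok := NULL]
  diag["passed_records"] <- nrow(dt)
  list(hits = as.data.frame(grp), records = as.data.frame(dt),
       diagnostics = diag)
}
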