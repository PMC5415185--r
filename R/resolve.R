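#' Describe the reference databases of a run
#'
#' @param name Character vector of database names, in user-specified order;
#'   that order is the priority order used to break equal-score ties in
#'   bestmode (the first database wins).
#' @param mode `"bestmode"` or `"fullmode"` per database. In bestmode a
#'   fragment is assigned to the single best reference across all bestmode
#'   databases; a fullmode database receives the fragment's best hit within
#'   that database regardless of better hits elsewhere (for gene databases
#'   that are subsets of genome databases).
#' @param path Optional alignment file per database (used by
#'   [run_classification()]).
#' @return A `db_spec` data.frame with columns `name`, `mode`, `priority`,
#'   and `path`.
#' @export
db_spec <- function(name, mode = "bestmode", path = NA_character_) {
  mode <- rep_len(mode, length(name))
  path <- rep_len(path, length(name))
  stopifnot(all(mode %in% c("bestmode", "fullmode")), !anyDuplicated(name))
  structure(data.frame(name = name, mode = mode,
                       priority = seq_along(name), path = path,
                       stringsAsFactors = FALSE),
            class = c("db_spec", "data.frame"))
}

# Order hits so the winner of each fragment group sorts first:
# highest SAS, then highest-priority database, then earliest file record.
hit_order <- function(hits, priority) {
  order(hits$qname, -hits$sas, priority, hits$first_rec)
}

#' Resolve bestmode assignments across databases
#'
#' For every fragment with at least one surviving hit in a bestmode
#' database, picks the hit with the highest summed alignment score (SAS).
#' Equal-score ties go to the database specified first; within one database
#' they go to the reference encountered first in the alignment file, so the
#' result is deterministic. A fragment is flagged unique when its chosen
#' score strictly exceeds the score of every hit to a different reference
#' in the bestmode scope.
#'
#' @param hits Fragment hits (from [filter_alignments()]) restricted or not
#'   to bestmode databases; non-bestmode rows are ignored.
#' @param specs A [db_spec()].
#' @return A data.frame of assignments: `qname`, `db`, `ref`, `sas`,
#'   `unique`, one row per fragment.
#' @export
resolve_bestmode <- function(hits, specs) {
  bdb <- specs$name[specs$mode == "bestmode"]
  h <- hits[hits$db %in% bdb, , drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(qname = character(), db = character(), ref = character(),
                      sas = integer(), unique = logical(),
                      stringsAsFactors = FALSE))
  }
  prio <- specs$priority[match(h$db, specs$name)]
  h <- h[hit_order(h, prio), , drop = FALSE]
  resolve_sorted(h)
}

#' Resolve fullmode assignments within each fullmode database
#'
#' Each fullmode database independently receives, for every fragment with a
#' surviving hit in it, the fragment's best hit within that database only
#' (same tie rules as bestmode, scoped to the one database). These
#' assignments are emitted regardless of any bestmode assignment the same
#' fragment received.
#'
#' @inheritParams resolve_bestmode
#' @return A data.frame of assignments (`qname`, `db`, `ref`, `sas`,
#'   `unique`); at most one row per fragment per fullmode database.
#' @export
resolve_fullmode <- function(hits, specs) {
  fdb <- specs$name[specs$mode == "fullmode"]
  out <- lapply(fdb, function(d) {
    h <- hits[hits$db == d, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h <- h[order(h$qname, -h$sas, h$first_rec), , drop = FALSE]
    resolve_sorted(h)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(qname = character(), db = character(), ref = character(),
                      sas = integer(), unique = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

# hits must be sorted so each fragment's winner comes first within its
# qname block. Uniqueness: the winner's SAS strictly exceeds every other
# hit to a different reference in the block.
resolve_sorted <- function(h) {
  first <- !duplicated(h$qname)
  win <- h[first, , drop = FALSE]
  dt <- data.table::as.data.table(h)
  u <- dt[, {
    top_ref <- ref[1]
    top_db <- db[1]
    others <- sas[!(ref == top_ref & db == top_db)]
    list(unique = length(others) == 0L || sas[1] > max(others))
  }, by = qname]
  stopifnot(identical(u$qname, win$qname))
  data.frame(qname = win$qname, db = win$db, ref = win$ref, sas = win$sas,
             unique = u$unique, stringsAsFactors = FALSE, row.names = NULL)
}

#' Resolve all assignments for a run
#'
#' Runs [resolve_bestmode()] across the bestmode databases and
#' [resolve_fullmode()] within each fullmode database, returning one
#' combined assignment table. Every fragment with at least one bestmode hit
#' receives exactly one bestmode assignment; fullmode assignments are
#' additional and independent.
#'
#' @inheritParams resolve_bestmode
#' @return A data.frame of assignments with a `scope` column:
#'   `"bestmode"` or `"fullmode"`.
#' @export
resolve_hits <- function(hits, specs) {
  b <- resolve_bestmode(hits, specs)
  f <- resolve_fullmode(hits, specs)
  if (nrow(b) > 0) b$scope <- "bestmode"
  else b$scope <- character()
  if (nrow(f) > 0) f$scope <- "fullmode"
  else f$scope <- character()
  rbind(b, f)
}
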