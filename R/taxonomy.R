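#' Clade levels used throughout the package
#'
#' The eight taxonomic ranks a reference sequence is annotated with, ordered
#' from most to least specific. "strain" is the reference sequence itself
#' (named by its FASTA header token); the remaining ranks follow the standard
#' NCBI-style lineage.
#'
#' @format Character vector of length 8.
#' @export
CLADE_LEVELS <- c("strain", "species", "genus", "family",
                  "order", "class", "phylum", "superkingdom")

# Column names of a taxonomy path in flat (wide) form:
# <level>_taxid, <level>_name for each of the 8 levels.
tax_columns <- function() {
  as.vector(rbind(paste0(CLADE_LEVELS, "_taxid"), paste0(CLADE_LEVELS, "_name")))
}

#' Read a reference-to-taxonomy mapping from a tab-separated file
#'
#' Each row maps one reference sequence name (the exact FASTA header token
#' used as `RNAME` in the alignments) to its taxonomy path: a taxid and a
#' clade name for each of the eight levels in [CLADE_LEVELS]. Empty cells
#' denote an absent taxid or name at that level.
#'
#' @param path Path to a UTF-8 TSV with a header row and 17 columns:
#'   `ref_name`, then `<level>_taxid`, `<level>_name` for strain through
#'   superkingdom.
#' @return A `taxonomy_store`: a data.frame with one row per reference,
#'   columns `ref_name` plus the 16 taxonomy columns; taxids are integer
#'   (`NA` when absent), names are character (`NA` when absent).
#' @details Duplicate reference names and non-numeric taxids are hard errors
#'   reporting the offending line, so a malformed mapping fails loudly rather
#'   than silently mis-annotating references.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) {
    stop("taxonomy file not found: ", path)
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "",
                          quote = "", encoding = "UTF-8")
  want <- c("ref_name", tax_columns())
  missing <- setdiff(want, names(dt))
  if (length(missing) > 0) {
    stop("taxonomy file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(dt)[, want]
  dup <- which(duplicated(df$ref_name))
  if (length(dup) > 0) {
    stop("duplicate reference name '", df$ref_name[dup[1]],
         "' in taxonomy file (line ", dup[1] + 1L, ")")
  }
  for (lev in CLADE_LEVELS) {
    col <- paste0(lev, "_taxid")
    raw <- df[[col]]
    ok <- is.na(raw) | grepl("^[0-9]+$", raw)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("malformed taxid '", raw[bad], "' in column ", col,
           " (line ", bad + 1L, ")")
    }
    df[[col]] <- as.integer(raw)
    if (any(!is.na(df[[col]]) & df[[col]] <= 0L)) {
      bad <- which(!is.na(df[[col]]) & df[[col]] <= 0L)[1]
      stop("taxid must be positive in column ", col, " (line ", bad + 1L, ")")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("taxonomy_store", "data.frame")
  df
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat("taxonomy_store:", nrow(x), "reference sequences\n")
  invisible(x)
}

# One "unclassified" path per reference name: strain name is the reference
# name itself, every taxid absent. Keeps unknown references in the output
# instead of dropping their reads.
unclassified_path <- function(ref_names) {
  out <- data.frame(ref_name = ref_names, stringsAsFactors = FALSE)
  n <- length(ref_names)
  for (lev in CLADE_LEVELS) {
    out[[paste0(lev, "_taxid")]] <- rep(NA_integer_, n)
    out[[paste0(lev, "_name")]] <- rep(NA_character_, n)
  }
  out$strain_name <- ref_names
  out[, c("ref_name", tax_columns())]
}

#' Look up taxonomy paths for reference names
#'
#' Vectorized lookup. References absent from the store get a synthetic
#' "unclassified" path (strain name equal to the reference name, all taxids
#' absent) so that downstream read-count conservation holds; each batch of
#' unknown keys is reported once via a warning.
#'
#' @param store A `taxonomy_store` from [read_taxonomy()].
#' @param ref_names Character vector of reference sequence names.
#' @return A data.frame with one row per element of `ref_names`, in input
#'   order, with columns `ref_name` plus the 16 taxonomy columns.
#' @export
lookup_taxonomy <- function(store, ref_names) {
  stopifnot(inherits(store, "taxonomy_store"))
  idx <- match(ref_names, store$ref_name)
  out <- unclassified_path(ref_names)
  hit <- !is.na(idx)
  if (any(hit)) {
    out[hit, ] <- as.data.frame(store)[idx[hit], , drop = FALSE]
  }
  unknown <- unique(ref_names[!hit])
  if (length(unknown) > 0) {
    warning(length(unknown), " reference name(s) missing from taxonomy store",
            " (reported as unclassified): ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Statistics columns that are summed when collapsing strains into clades.
SUMMED_COLUMNS <- c("s_abundance", "r_abundance", "size_bp", "seq_count",
                    "nucleotides", "covered_positions", "coverage", "depth",
                    "read_count", "read_count_uniq", "mismatches")

#' Aggregate per-reference statistics at a clade level
#'
#' Rows sharing the chosen level's taxid are merged into one clade row, and
#' every statistics column (abundances, size, sequence count, nucleotides,
#' covered positions, coverage, depth, read counts, mismatches) is summed
#' over the members. Rows with no taxid at the level are grouped by the
#' level's name string; rows with neither taxid nor name fall into a single
#' "unclassified" group.
#'
#' Coverage and Depth are ratios, but they are summed like every other
#' column, so an aggregated Coverage can exceed 1. Two derived columns,
#' `coverage_ratio` (summed covered positions / summed size) and
#' `depth_ratio` (summed nucleotides / summed size), are recomputed from the
#' sums for sanity checking.
#'
#' @param rows A strain-level statistics table (as built by
#'   [reference_stats()]) carrying the 16 taxonomy columns.
#' @param level One of [CLADE_LEVELS].
#' @return A data.frame with columns `level`, `taxid`, `name`, the summed
#'   statistics columns, `coverage_ratio`, `depth_ratio` and `n_strains`
#'   (number of member rows); sorted by decreasing `s_abundance`, ties by
#'   `name`.
#' @export
collapse_clades <- function(rows, level) {
  level <- match.arg(level, CLADE_LEVELS)
  stopifnot(is.data.frame(rows))
  cols <- intersect(SUMMED_COLUMNS, names(rows))
  need <- setdiff(c(paste0(level, "_taxid"), paste0(level, "_name")), names(rows))
  if (length(need) > 0) {
    stop("input rows lack taxonomy column(s): ", paste(need, collapse = ", "))
  }
  if (nrow(rows) == 0) {
    out <- data.frame(level = character(), taxid = integer(),
                      name = character(), stringsAsFactors = FALSE)
    for (cc in cols) out[[cc]] <- numeric()
    out$coverage_ratio <- numeric()
    out$depth_ratio <- numeric()
    out$n_strains <- integer()
    return(out)
  }
  taxid <- rows[[paste0(level, "_taxid")]]
  name <- rows[[paste0(level, "_name")]]
  name[is.na(name)] <- "unclassified"
  # Group key: taxid when present, else the clade name string.
  key <- ifelse(is.na(taxid), paste0("name:", name), paste0("taxid:", taxid))
  dt <- data.table::as.data.table(rows[, cols, drop = FALSE])
  dt[, `:=`(.key = key, .taxid = taxid, .name = name)]
  agg <- dt[, c(lapply(.SD, sum),
                list(.taxid = .taxid[1], .name = .name[1], n_strains = .N)),
            by = .key, .SDcols = cols]
  out <- as.data.frame(agg)
  out$.key <- NULL
  names(out)[names(out) == ".taxid"] <- "taxid"
  names(out)[names(out) == ".name"] <- "name"
  out <- cbind(level = level, out[, c("taxid", "name", cols, "n_strains")],
               stringsAsFactors = FALSE)
  if (all(c("covered_positions", "size_bp", "nucleotides") %in% cols)) {
    out$coverage_ratio <- out$covered_positions / out$size_bp
    out$depth_ratio <- out$nucleotides / out$size_bp
  }
  ord <- order(-out$s_abundance, out$name)
  out <- out[ord, c("level", "taxid", "name", cols,
                    intersect(c("coverage_ratio", "depth_ratio"), names(out)),
                    "n_strains")]
  rownames(out) <- NULL
  out
}

#' Convert NCBI taxdump files to the flat taxonomy TSV
#'
#' Reads `nodes.dmp` and `names.dmp` (the NCBI taxonomy dump dialect: fields
#' separated by `\t|\t`, lines terminated by `\t|`) and writes the flat
#' 17-column taxonomy TSV used by [read_taxonomy()], one row per requested
#' (reference name, taxid) pair, walking each lineage up to superkingdom.
#' This is an offline converter utility, not a runtime dependency of the
#' pipeline.
#'
#' @param nodes_path Path to `nodes.dmp`.
#' @param names_path Path to `names.dmp`.
#' @param refs A data.frame with columns `ref_name` and `taxid`: the
#'   references to annotate and the taxid each one is keyed to (typically the
#'   strain- or species-level taxid of the assembly).
#' @param out_path Output TSV path.
#' @return Invisibly, the taxonomy data.frame that was written.
#' @export
taxdump_to_taxonomy <- function(nodes_path, names_path, refs, out_path) {
  stopifnot(all(c("ref_name", "taxid") %in% names(refs)))
  parse_dmp <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nodes <- parse_dmp(nodes_path)
  node_id <- as.integer(vapply(nodes, `[`, "", 1L))
  parent <- as.integer(vapply(nodes, `[`, "", 2L))
  rank <- vapply(nodes, `[`, "", 3L)
  parent_of <- stats::setNames(parent, node_id)
  rank_of <- stats::setNames(rank, node_id)

  nm <- parse_dmp(names_path)
  nm_class <- vapply(nm, `[`, "", 4L)
  sci <- nm[nm_class == "scientific name"]
  name_of <- stats::setNames(vapply(sci, `[`, "", 2L),
                             vapply(sci, `[`, "", 1L))

  one_path <- function(taxid) {
    res <- unclassified_path("x")[, -1]
    cur <- taxid
    # the keyed taxid itself fills the strain slot regardless of its rank
    res$strain_taxid <- as.integer(taxid)
    res$strain_name <- unname(name_of[as.character(taxid)])
    for (i in seq_len(64)) {
      r <- rank_of[as.character(cur)]
      if (is.na(r)) break
      if (r %in% CLADE_LEVELS[-1]) {
        res[[paste0(r, "_taxid")]] <- as.integer(cur)
        res[[paste0(r, "_name")]] <- unname(name_of[as.character(cur)])
      }
      nxt <- parent_of[as.character(cur)]
      if (is.na(nxt) || nxt == cur) break
      cur <- nxt
    }
    res
  }
  paths <- do.call(rbind, lapply(refs$taxid, one_path))
  out <- cbind(data.frame(ref_name = refs$ref_name, stringsAsFactors = FALSE),
               paths)
  out$strain_name <- out$ref_name
  write_tsv_na(out, out_path)
  invisible(out)
}

# Shared TSV writer: tabs, no quoting, empty string for NA.
write_tsv_na <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}
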