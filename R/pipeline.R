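# Mapping between internal column names and the published table headers
# (14 statistics columns, then taxid + name for the 8 clades).
STRAIN_TABLE_HEADERS <- c(
  db = "Database", ref = "Ref. seq", s_abundance = "S_Abundance",
  r_abundance = "R_Abundance", size_bp = "Size", seq_count = "Seq_count",
  nucleotides = "Nucleotides", covered_positions = "Covered positions",
  coverage = "Coverage", depth = "Depth", read_count = "ReadCount",
  read_count_uniq = "ReadCount uniq", mismatches = "Mismatches",
  description = "Description")

REAL_COLUMNS <- c("s_abundance", "r_abundance", "coverage", "depth",
                  "coverage_ratio", "depth_ratio")

fmt_real <- function(x) {
  # 6 significant digits, plain notation where reasonable
  ifelse(is.na(x), "",
         trimws(formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write a strain-level statistics table
#'
#' Tab-separated, 14 statistics columns in the published order (Database,
#' Ref. seq, S_Abundance, R_Abundance, Size, Seq_count, Nucleotides,
#' Covered positions, Coverage, Depth, ReadCount, ReadCount uniq,
#' Mismatches, Description) followed by 16 taxonomy columns (taxid and name
#' for the 8 clades). Reals are printed with 6 significant digits; rows are
#' sorted by decreasing S_Abundance with ties broken by reference name, so
#' re-running on identical input is byte-identical.
#'
#' @param rows Strain table from [run_classification()] /
#'   [reference_stats()] joined with taxonomy columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_strain_table <- function(rows, path) {
  cols <- names(STRAIN_TABLE_HEADERS)
  stopifnot(all(cols %in% names(rows)))
  tcols <- tax_columns()
  out <- rows[order(-rows$s_abundance, rows$ref), c(cols, tcols),
              drop = FALSE]
  for (cc in intersect(REAL_COLUMNS, cols)) out[[cc]] <- fmt_real(out[[cc]])
  names(out) <- c(unname(STRAIN_TABLE_HEADERS), tcols)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a strain-level statistics table back
#'
#' Inverse of [write_strain_table()]: restores the internal column names
#' and types, so saved tables can be re-post-processed without redoing any
#' alignment parsing.
#'
#' @param path Path to a TSV written by [write_strain_table()].
#' @return Data.frame with internal column names plus taxonomy columns.
#' @export
read_strain_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = "", quote = "",
                                        encoding = "UTF-8"))
  hdr <- STRAIN_TABLE_HEADERS
  idx <- match(unname(hdr), names(df))
  if (anyNA(idx)) {
    stop("not a strain table (missing column(s): ",
         paste(unname(hdr)[is.na(idx)], collapse = ", "), "): ", path)
  }
  names(df)[idx] <- names(hdr)
  int_cols <- c("size_bp", "seq_count", "nucleotides", "covered_positions",
                "read_count", "read_count_uniq", "mismatches")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  for (cc in intersect(REAL_COLUMNS, names(df))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  for (cc in paste0(CLADE_LEVELS, "_taxid")) {
    if (cc %in% names(df)) df[[cc]] <- as.integer(df[[cc]])
  }
  df
}

#' Write a clade-level table (accepted or rejected rows)
#'
#' @param rows Clade rows from [collapse_clades()] (optionally carrying a
#'   `failed_criteria` column) or strain rows for the strain level.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clade_table <- function(rows, path) {
  out <- rows
  for (cc in intersect(REAL_COLUMNS, names(out))) {
    out[[cc]] <- fmt_real(out[[cc]])
  }
  write_tsv_na(out, path)
  invisible(path)
}

#' Run the classification core end to end
#'
#' Steps: parse the per-database alignment files, apply candidate selection
#' and the alignment-quality filters, resolve bestmode/fullmode
#' assignments, compute per-reference statistics, attach taxonomy, collapse
#' to the requested clade levels (per database) and partition each level
#' into accepted and rejected annotations under the four acceptance
#' criteria.
#'
#' @param dbs A [db_spec()] with `path` set for every database.
#' @param taxonomy A `taxonomy_store` or path to a taxonomy TSV.
#' @param ref_sizes A data.frame (`ref_name`, `size_bp`, optional
#'   `description`) or path to a size TSV / FASTA.
#' @param total_clean_reads Size of the cleaned read set (100% reference
#'   for R_Abundance).
#' @param paired Paired-end mode.
#' @param filter A [filter_config()]; built from `paired` by default.
#' @param criteria A [criteria_config()].
#' @param levels Clade levels to post-process (subset of [CLADE_LEVELS]).
#' @param out_dir Optional output directory; when given, writes per-database
#'   strain tables (`<db>.strain.tsv`), per-level accepted/rejected tables
#'   (`<level>.accepted.tsv` / `<level>.rejected.tsv`) and a `summary.tsv`.
#' @return A list: `strain` (full strain table with taxonomy), `clades`
#'   (per-level collapsed tables), `partitions` (per-level
#'   `accepted`/`rejected`), `assignments`, `diagnostics`, `summary`.
#' @export
run_classification <- function(dbs, taxonomy, ref_sizes, total_clean_reads,
                               paired = TRUE,
                               filter = filter_config(paired = paired),
                               criteria = criteria_config(),
                               levels = c("strain", "species", "genus"),
                               out_dir = NULL) {
  stopifnot(inherits(dbs, "db_spec"))
  levels <- match.arg(levels, CLADE_LEVELS, several.ok = TRUE)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(ref_sizes)) ref_sizes <- read_ref_sizes(ref_sizes)
  filter$paired <- paired

  records <- do.call(rbind, lapply(seq_len(nrow(dbs)), function(i) {
    read_alignments(dbs$path[i], db = dbs$name[i])
  }))
  filt <- filter_alignments(records, filter)
  assignments <- resolve_hits(filt$hits, dbs)

  strain <- reference_stats(assignments, filt$records, ref_sizes,
                            total_clean_reads, paired = paired)
  tax <- lookup_taxonomy(taxonomy, strain$ref)
  strain <- cbind(strain, tax[, tax_columns(), drop = FALSE])

  clades <- list()
  partitions <- list()
  for (lev in levels) {
    if (lev == "strain") {
      rows <- strain
    } else {
      # collapse within each database: bestmode and fullmode tables must
      # not mix, and the species pre-cycle threshold is per database
      rows <- do.call(rbind, lapply(unique(strain$db), function(d) {
        cl <- collapse_clades(strain[strain$db == d, , drop = FALSE], lev)
        if (nrow(cl) > 0) cbind(db = d, cl, stringsAsFactors = FALSE)
        else cbind(db = character(), cl)
      }))
      if (is.null(rows)) rows <- collapse_clades(strain, lev)
    }
    clades[[lev]] <- rows
    parts <- lapply(split_by_db(rows), partition_clades, level = lev,
                    cfg = criteria)
    partitions[[lev]] <- list(
      accepted = do.call(rbind, lapply(parts, `[[`, "accepted")),
      rejected = do.call(rbind, lapply(parts, `[[`, "rejected")))
    rownames(partitions[[lev]]$accepted) <- NULL
    rownames(partitions[[lev]]$rejected) <- NULL
  }

  bm <- assignments[assignments$scope == "bestmode", , drop = FALSE]
  bm_mates <- sum(strain$read_count[strain$db %in%
                                      dbs$name[dbs$mode == "bestmode"]])
  summary <- data.frame(
    metric = c("total_records", "supplementary", "not_candidate",
               "missing_tags", "failed_quality", "incomplete_pair",
               "incomplete_pair_records",
               "passed_records", "fragments_with_hits",
               "bestmode_assignments", "fullmode_assignments",
               "bestmode_assigned_mates", "total_clean_reads"),
    value = c(filt$diagnostics[["total"]],
              filt$diagnostics[["supplementary"]],
              filt$diagnostics[["not_candidate"]],
              filt$diagnostics[["missing_tags"]],
              filt$diagnostics[["failed_quality"]],
              filt$diagnostics[["incomplete_pair"]],
              filt$diagnostics[["incomplete_pair_records"]],
              filt$diagnostics[["passed_records"]],
              length(unique(filt$hits$qname)),
              nrow(bm),
              sum(assignments$scope == "fullmode"),
              bm_mates,
              total_clean_reads),
    stringsAsFactors = FALSE)

  res <- list(strain = strain, clades = clades, partitions = partitions,
              assignments = assignments, diagnostics = filt$diagnostics,
              summary = summary)
  if (!is.null(out_dir)) write_outputs(res, dbs, out_dir)
  res
}

split_by_db <- function(rows) {
  if ("db" %in% names(rows) && nrow(rows) > 0) {
    split(rows, rows$db)
  } else {
    list(all = rows)
  }
}

write_outputs <- function(res, dbs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in dbs$name) {
    write_strain_table(res$strain[res$strain$db == d, , drop = FALSE],
                       file.path(out_dir, paste0(d, ".strain.tsv")))
  }
  for (lev in names(res$partitions)) {
    p <- res$partitions[[lev]]
    acc <- if (lev == "strain") {
      p$accepted[, c(names(STRAIN_TABLE_HEADERS), tax_columns())]
    } else p$accepted
    rej <- p$rejected
    if (lev == "strain") {
      rej <- rej[, c(names(STRAIN_TABLE_HEADERS), tax_columns(),
                     "failed_criteria")]
    }
    write_clade_table(acc, file.path(out_dir, paste0(lev, ".accepted.tsv")))
    write_clade_table(rej, file.path(out_dir, paste0(lev, ".rejected.tsv")))
  }
  write_tsv_na(res$summary, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' Re-run post-processing from saved strain tables
#'
#' Reads one or more strain tables written by [write_strain_table()],
#' re-collapses them at the requested clade levels and re-partitions under
#' (possibly different) acceptance criteria — no alignment parsing is
#' redone.
#'
#' @param paths Strain table TSV paths.
#' @param criteria A [criteria_config()].
#' @param levels Clade levels to evaluate.
#' @param out_dir Optional output directory for the per-level tables.
#' @return As [run_classification()], without `assignments`/`diagnostics`.
#' @export
reprocess_strain_tables <- function(paths, criteria = criteria_config(),
                                    levels = c("strain", "species", "genus"),
                                    out_dir = NULL) {
  levels <- match.arg(levels, CLADE_LEVELS, several.ok = TRUE)
  strain <- do.call(rbind, lapply(paths, read_strain_table))
  clades <- list()
  partitions <- list()
  for (lev in levels) {
    rows <- if (lev == "strain") strain else {
      do.call(rbind, lapply(unique(strain$db), function(d) {
        cl <- collapse_clades(strain[strain$db == d, , drop = FALSE], lev)
        if (nrow(cl) > 0) cbind(db = d, cl, stringsAsFactors = FALSE) else NULL
      }))
    }
    if (is.null(rows)) rows <- collapse_clades(strain, lev)
    clades[[lev]] <- rows
    parts <- lapply(split_by_db(rows), partition_clades, level = lev,
                    cfg = criteria)
    partitions[[lev]] <- list(
      accepted = do.call(rbind, lapply(parts, `[[`, "accepted")),
      rejected = do.call(rbind, lapply(parts, `[[`, "rejected")))
  }
  res <- list(strain = strain, clades = clades, partitions = partitions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lev in levels) {
      write_clade_table(partitions[[lev]]$accepted,
                        file.path(out_dir, paste0(lev, ".accepted.tsv")))
      write_clade_table(partitions[[lev]]$rejected,
                        file.path(out_dir, paste0(lev, ".rejected.tsv")))
    }
  }
  res
}
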