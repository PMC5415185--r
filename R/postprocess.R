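#' Acceptance criteria thresholds
#'
#' Four criteria identify a confident taxonomy annotation:
#' \describe{
#'   \item{I}{ReadCount of at least `min_read_count` (default 10; inclusive,
#'     a stated minimum).}
#'   \item{II}{Mismatch ratio (Mismatches / Nucleotides) strictly below
#'     `max_mismatch_ratio` (default 0.01).}
#'   \item{III}{Size-normalized abundance strictly above `min_s_abundance`
#'     (default 0.01).}
#'   \item{IV}{Unique read count fraction (ReadCount uniq / ReadCount)
#'     strictly above `min_unique_fraction` (default 0.005, i.e. 0.5%).}
#' }
#' At strain level all four criteria are imposed; at species level criterion
#' IV enters only through a pre-cycle (see [evaluate_species()]); at genus
#' level or higher only I, II and III are used.
#'
#' @param min_read_count,max_mismatch_ratio,min_s_abundance,min_unique_fraction
#'   Threshold values as described above.
#' @param species_precycle Which criteria define the species pre-cycle
#'   selection: `"all"` (criteria I-IV; the default) or `"uniq_only"`
#'   (criterion IV alone).
#' @return A `criteria_config` list.
#' @export
criteria_config <- function(min_read_count = 10L, max_mismatch_ratio = 0.01,
                            min_s_abundance = 0.01,
                            min_unique_fraction = 0.005,
                            species_precycle = c("all", "uniq_only")) {
  stopifnot(min_read_count >= 0, max_mismatch_ratio >= 0,
            min_s_abundance >= 0, min_unique_fraction >= 0)
  structure(list(min_read_count = as.integer(min_read_count),
                 max_mismatch_ratio = as.numeric(max_mismatch_ratio),
                 min_s_abundance = as.numeric(min_s_abundance),
                 min_unique_fraction = as.numeric(min_unique_fraction),
                 species_precycle = match.arg(species_precycle)),
            class = "criteria_config")
}

#' Mismatch ratio of a statistics row
#'
#' Mismatches divided by mapped nucleotides. With zero nucleotides the ratio
#' is 0 when there are no mismatches and `Inf` otherwise (such a row can
#' only fail criterion II).
#'
#' @param mismatches,nucleotides Non-negative numeric vectors.
#' @return Numeric vector.
#' @export
mismatch_ratio <- function(mismatches, nucleotides) {
  ifelse(nucleotides > 0, mismatches / nucleotides,
         ifelse(mismatches == 0, 0, Inf))
}

# Individual criterion tests, vectorized over rows.
crit_I <- function(rows, cfg) rows$read_count >= cfg$min_read_count
crit_II <- function(rows, cfg) {
  mismatch_ratio(rows$mismatches, rows$nucleotides) < cfg$max_mismatch_ratio
}
crit_III <- function(rows, cfg) rows$s_abundance > cfg$min_s_abundance
crit_IV <- function(rows, cfg) {
  frac <- ifelse(rows$read_count > 0,
                 rows$read_count_uniq / rows$read_count, 0)
  frac > cfg$min_unique_fraction
}

failed_labels <- function(pass_mat) {
  if (nrow(pass_mat) == 0) return(character())
  apply(pass_mat, 1L, function(p) {
    paste(colnames(pass_mat)[!p], collapse = ",")
  })
}

#' Evaluate strain-level rows against all four criteria
#'
#' @param rows Strain-level statistics rows (see [reference_stats()]).
#' @param cfg A [criteria_config()].
#' @return A data.frame of verdicts: `accepted` (logical) and
#'   `failed_criteria` (comma-separated subset of `I,II,III,IV`; empty when
#'   accepted), one row per input row.
#' @export
evaluate_strain <- function(rows, cfg = criteria_config()) {
  pass <- cbind(I = crit_I(rows, cfg), II = crit_II(rows, cfg),
                III = crit_III(rows, cfg), IV = crit_IV(rows, cfg))
  data.frame(accepted = rowSums(!pass) == 0,
             failed_criteria = failed_labels(pass),
             stringsAsFactors = FALSE)
}

#' Evaluate species-level rows with the abundance pre-cycle
#'
#' Two passes. Pass 1 selects rows satisfying the pre-cycle criteria (all
#' four by default) and takes `T`, the lowest size-normalized abundance
#' among the selected species; when nothing is selected, `T` falls back to
#' `cfg$min_s_abundance`. Pass 2 accepts rows satisfying criteria I and II
#' with abundance at least `T`; criterion IV is omitted. The comparison
#' against `T` is inclusive so that the species defining `T` stays accepted.
#'
#' @param rows Species-level clade rows (see [collapse_clades()]).
#' @param cfg A [criteria_config()].
#' @return Verdict data.frame as in [evaluate_strain()] (pass-2 outcome;
#'   an abundance below `T` is flagged as criterion III).
#' @export
evaluate_species <- function(rows, cfg = criteria_config()) {
  if (nrow(rows) == 0) {
    return(data.frame(accepted = logical(), failed_criteria = character(),
                      stringsAsFactors = FALSE))
  }
  pre <- if (cfg$species_precycle == "uniq_only") {
    crit_IV(rows, cfg)
  } else {
    crit_I(rows, cfg) & crit_II(rows, cfg) & crit_III(rows, cfg) &
      crit_IV(rows, cfg)
  }
  thr <- if (any(pre)) min(rows$s_abundance[pre]) else cfg$min_s_abundance
  pass <- cbind(I = crit_I(rows, cfg), II = crit_II(rows, cfg),
                III = rows$s_abundance >= thr)
  data.frame(accepted = rowSums(!pass) == 0,
             failed_criteria = failed_labels(pass),
             stringsAsFactors = FALSE)
}

#' Evaluate clade rows at genus level or higher
#'
#' Only criteria I, II and III are used.
#'
#' @inheritParams evaluate_strain
#' @return Verdict data.frame as in [evaluate_strain()].
#' @export
evaluate_genus_or_higher <- function(rows, cfg = criteria_config()) {
  pass <- cbind(I = crit_I(rows, cfg), II = crit_II(rows, cfg),
                III = crit_III(rows, cfg))
  data.frame(accepted = rowSums(!pass) == 0,
             failed_criteria = failed_labels(pass),
             stringsAsFactors = FALSE)
}

#' Partition rows into accepted and rejected sets at a clade level
#'
#' Dispatches to the level-appropriate evaluator ([evaluate_strain()],
#' [evaluate_species()], or [evaluate_genus_or_higher()]) and splits the
#' input. Accepted and rejected are disjoint and their union is the input;
#' rejected rows carry the criteria they failed.
#'
#' @param rows Statistics rows at one clade level.
#' @param level One of [CLADE_LEVELS].
#' @param cfg A [criteria_config()].
#' @return List with elements `accepted` and `rejected` (the latter with a
#'   `failed_criteria` column).
#' @export
partition_clades <- function(rows, level, cfg = criteria_config()) {
  level <- match.arg(level, CLADE_LEVELS)
  verdict <- switch(level,
    strain = evaluate_strain(rows, cfg),
    species = evaluate_species(rows, cfg),
    evaluate_genus_or_higher(rows, cfg))
  rejected <- rows[!verdict$accepted, , drop = FALSE]
  if (nrow(rows) > 0) {
    rejected$failed_criteria <- verdict$failed_criteria[!verdict$accepted]
  } else {
    rejected$failed_criteria <- character()
  }
  list(accepted = rows[verdict$accepted, , drop = FALSE],
       rejected = rejected)
}
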