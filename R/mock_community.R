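#' Mock bacterial community composition
#'
#' The composition of a widely used bacterial mock community for
#' benchmarking metagenomic classifiers, available both as a sequenced
#' (in vitro) sample and as simulated (in silico) read sets. The in vitro
#' sample spans 12 strains, 11 species and 8 genera; the in silico sample
#' adds one further strain (13 strains, 12 species, 9 genera). Taxids here
#' are synthetic (deterministic placeholders): clade aggregation only needs
#' them to agree within a clade, and real NCBI identifiers for these
#' assemblies change across taxonomy releases.
#'
#' @param dataset `"in_vitro"` or `"in_silico"`.
#' @return Data.frame with columns `strain`, `species`, `genus`,
#'   `species_taxid`, `genus_taxid`.
#' @export
mock_community <- function(dataset = c("in_vitro", "in_silico")) {
  dataset <- match.arg(dataset)
  df <- data.frame(
    genus = c("Bacillus", "Bacillus", "Burkholderia", "Escherichia",
              "Frankia", "Micrococcus", "Pseudomonas", "Pseudomonas",
              "Pseudomonas", "Pseudomonas", "Rhodobacter", "Streptomyces",
              "Nocardioides"),
    species = c("Bacillus amyloliquefaciens", "Bacillus cereus",
                "Burkholderia cenocepacia", "Escherichia coli",
                "Frankia sp.", "Micrococcus luteus",
                "Pseudomonas aeruginosa", "Pseudomonas aeruginosa",
                "Pseudomonas fluorescens", "Pseudomonas putida",
                "Rhodobacter capsulatus", "Streptomyces coelicolor",
                "Nocardioides sp."),
    strain = c("B.amyloliquefaciens DSM7", "B.cereus ATCC 14579",
               "B.cenocepacia J2315", "E.coli K-12", "Frankia sp. CcI3",
               "M.luteus NCTC 2665", "P.aeruginosa PAO1",
               "P.aeruginosa UCBPP-PA14", "P.fluorescens Pf-5",
               "P.putida KT2440", "R.capsulatus SB 1003",
               "S.coelicolor A3(2)", "Nocardioides sp. JS614"),
    stringsAsFactors = FALSE
  )
  if (dataset == "in_vitro") df <- df[df$strain != "Nocardioides sp. JS614", ]
  df$species_taxid <- 500000L + match(df$species, unique(df$species))
  df$genus_taxid <- 600000L + match(df$genus, unique(df$genus))
  rownames(df) <- NULL
  df
}

#' Strain-level statistics rows for the mock community
#'
#' Expands [mock_community()] into a strain-level statistics table with
#' full taxonomy columns, suitable for exercising clade aggregation. The
#' statistics values are arbitrary but fixed (every strain gets the same
#' deterministic per-row values), since aggregation counts and sum
#' conservation do not depend on them.
#'
#' @inheritParams mock_community
#' @return Strain-level data.frame as produced by the pipeline (statistics
#'   plus 16 taxonomy columns).
#' @export
mock_community_rows <- function(dataset = c("in_vitro", "in_silico")) {
  mc <- mock_community(dataset)
  n <- nrow(mc)
  rows <- data.frame(
    db = "bacteria", ref = mc$strain,
    s_abundance = 0.1, r_abundance = 1.0,
    size_bp = 1000000L, seq_count = 1L,
    nucleotides = 1000000L, covered_positions = 500000L,
    coverage = 0.5, depth = 1.0,
    read_count = 10000L, read_count_uniq = 5000L, mismatches = 2000L,
    description = mc$strain, stringsAsFactors = FALSE
  )
  rows$strain_taxid <- 700000L + seq_len(n)
  rows$strain_name <- mc$strain
  rows$species_taxid <- mc$species_taxid
  rows$species_name <- mc$species
  rows$genus_taxid <- mc$genus_taxid
  rows$genus_name <- mc$genus
  fillers <- list(
    family = c(900001L, "Mockaceae"), order = c(900002L, "Mockales"),
    class = c(900003L, "Mockia"), phylum = c(900004L, "Mockita"),
    superkingdom = c(900005L, "Bacteria"))
  for (lev in names(fillers)) {
    rows[[paste0(lev, "_taxid")]] <- as.integer(fillers[[lev]][1])
    rows[[paste0(lev, "_name")]] <- fillers[[lev]][2]
  }
  rows
}
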