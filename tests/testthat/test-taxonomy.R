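tax_df <- function(refs, species, genus,
                   species_taxid = 200L + match(species, unique(species)),
                   genus_taxid = 300L + match(genus, unique(genus))) {
  df <- data.frame(ref_name = refs, stringsAsFactors = FALSE)
  df$strain_taxid <- seq_along(refs)
  df$strain_name <- refs
  df$species_taxid <- species_taxid
  df$species_name <- species
  df$genus_taxid <- genus_taxid
  df$genus_name <- genus
  for (lev in c("family", "order", "class", "phylum", "superkingdom")) {
    df[[paste0(lev, "_taxid")]] <- 400L
    df[[paste0(lev, "_name")]] <- "Filler"
  }
  df
}

write_tax <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, na = "", row.names = FALSE)
  p
}

test_that("taxonomy TSV loads with row count preserved and typed taxids", {
  df <- tax_df(c("r1", "r2", "r3"), c("s1", "s1", "s2"), c("g1", "g1", "g1"))
  store <- read_taxonomy(write_tax(df))
  expect_s3_class(store, "taxonomy_store")
  expect_equal(nrow(store), 3L)
  expect_type(store$species_taxid, "integer")
})

test_that("duplicate reference names and malformed taxids are hard errors", {
  df <- tax_df(c("r1", "r2", "r1"), c("s1", "s2", "s3"), "g1")
  expect_error(read_taxonomy(write_tax(df)), "duplicate.*r1.*line 4")
  df2 <- tax_df(c("r1", "r2"), c("s1", "s2"), "g1")
  df2$species_taxid <- c("201", "not_a_number")
  expect_error(read_taxonomy(write_tax(df2)), "malformed taxid.*line 3")
})

test_that("absent clade slots load as NA while present ones are kept", {
  df <- tax_df(c("r1", "r2"), c("s1", "s2"), "g1")
  df$strain_taxid <- c(NA, 2L)
  store <- read_taxonomy(write_tax(df))
  expect_true(is.na(store$strain_taxid[1]))
  expect_equal(store$species_taxid[1], 201L)
})

test_that("lookup returns stored paths, is deterministic, and degrades to unclassified", {
  store <- read_taxonomy(write_tax(
    tax_df(c("r1", "r2"), c("s1", "s2"), c("g1", "g2"))))
  hit <- lookup_taxonomy(store, "r2")
  expect_equal(hit$species_name, "s2")
  expect_identical(lookup_taxonomy(store, "r2"), hit)
  miss <- suppressWarnings(lookup_taxonomy(store, "refX"))
  expect_equal(miss$strain_name, "refX")
  expect_true(all(is.na(unlist(miss[paste0(CLADE_LEVELS, "_taxid")]))))
  expect_warning(lookup_taxonomy(store, "refX"), "unclassified")
  # mixed known/unknown keeps input order
  both <- suppressWarnings(lookup_taxonomy(store, c("refX", "r1")))
  expect_equal(both$ref_name, c("refX", "r1"))
  expect_equal(both$species_name, c(NA, "s1"))
})

test_that("clade collapsing groups by taxid with name and unclassified fallbacks", {
  rows <- mock_community_rows("in_vitro")[1:4, ]
  rows$species_taxid[3] <- NA  # grouped by species name
  rows$species_taxid[4] <- NA
  rows$species_name[4] <- NA   # grouped under unclassified
  cl <- collapse_clades(rows, "species")
  expect_setequal(cl$name,
                  c(rows$species_name[1:3], "unclassified"))
  expect_equal(nrow(cl), 4L)
})

test_that("singleton collapse preserves every summed field", {
  rows <- mock_community_rows("in_vitro")[1, ]
  cl <- collapse_clades(rows, "species")
  expect_equal(nrow(cl), 1L)
  for (cc in c("s_abundance", "r_abundance", "size_bp", "seq_count",
               "nucleotides", "covered_positions", "coverage", "depth",
               "read_count", "read_count_uniq", "mismatches")) {
    expect_equal(cl[[cc]], rows[[cc]], info = cc)
  }
})

test_that("collapsing conserves sums, is order-independent, and group counts are monotone", {
  rows <- mock_community_rows("in_silico")
  for (lev in c("species", "genus", "phylum")) {
    cl <- collapse_clades(rows, lev)
    for (cc in c("read_count", "nucleotides", "s_abundance", "mismatches")) {
      expect_equal(sum(cl[[cc]]), sum(rows[[cc]]), info = paste(lev, cc))
    }
  }
  set.seed(5)
  shuffled <- rows[sample(nrow(rows)), ]
  expect_equal(collapse_clades(shuffled, "genus"),
               collapse_clades(rows, "genus"))
  n_groups <- vapply(c("strain", "species", "genus", "family"),
                     function(l) nrow(collapse_clades(rows, l)), 0L)
  expect_true(all(diff(n_groups) <= 0))
})

test_that("derived ratio columns are recomputed from the sums", {
  rows <- mock_community_rows("in_vitro")
  cl <- collapse_clades(rows, "genus")
  expect_equal(cl$coverage_ratio, cl$covered_positions / cl$size_bp)
  expect_equal(cl$depth_ratio, cl$nucleotides / cl$size_bp)
  # summed Coverage of a multi-strain genus exceeds the recomputed ratio
  multi <- cl[cl$n_strains > 1, ]
  expect_true(all(multi$coverage > multi$coverage_ratio))
})

test_that("unknown clade level is rejected", {
  expect_error(collapse_clades(mock_community_rows("in_vitro"), "kingdomx"))
})

test_that("taxdump converter walks lineages into the flat layout", {
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t131567\t|\tsuperkingdom\t|",
             "131567\t|\t1\t|\tno rank\t|",
             "1224\t|\t2\t|\tphylum\t|",
             "1236\t|\t1224\t|\tclass\t|",
             "72274\t|\t1236\t|\torder\t|",
             "135621\t|\t72274\t|\tfamily\t|",
             "286\t|\t135621\t|\tgenus\t|",
             "287\t|\t286\t|\tspecies\t|",
             "208964\t|\t287\t|\tstrain\t|")
  nms <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
           "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
           "1224\t|\tPseudomonadota\t|\t\t|\tscientific name\t|",
           "1236\t|\tGammaproteobacteria\t|\t\t|\tscientific name\t|",
           "72274\t|\tPseudomonadales\t|\t\t|\tscientific name\t|",
           "135621\t|\tPseudomonadaceae\t|\t\t|\tscientific name\t|",
           "286\t|\tPseudomonas\t|\t\t|\tscientific name\t|",
           "287\t|\tPseudomonas aeruginosa\t|\t\t|\tscientific name\t|",
           "208964\t|\tPAO1\t|\t\t|\tscientific name\t|")
  np <- tempfile(); writeLines(nodes, np)
  mp <- tempfile(); writeLines(nms, mp)
  out <- tempfile(fileext = ".tsv")
  refs <- data.frame(ref_name = "PAO1_chr", taxid = 208964L,
                     stringsAsFactors = FALSE)
  taxdump_to_taxonomy(np, mp, refs, out)
  store <- read_taxonomy(out)
  expect_equal(store$strain_name, "PAO1_chr")
  expect_equal(store$species_name, "Pseudomonas aeruginosa")
  expect_equal(store$genus_taxid, 286L)
  expect_equal(store$superkingdom_name, "Bacteria")
  expect_equal(store$phylum_taxid, 1224L)
})
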