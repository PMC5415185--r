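mk_row <- function(read_count = 100L, read_count_uniq = 50L,
                   mismatches = 0L, nucleotides = read_count * 100L,
                   s_abundance = 0.1, name = "rowX") {
  data.frame(name = name, read_count = as.integer(read_count),
             read_count_uniq = as.integer(read_count_uniq),
             mismatches = as.integer(mismatches),
             nucleotides = as.integer(nucleotides),
             s_abundance = s_abundance, stringsAsFactors = FALSE)
}

test_that("mismatch ratio handles zero nucleotides", {
  expect_equal(mismatch_ratio(3, 1000), 0.003)
  expect_equal(mismatch_ratio(0, 0), 0)
  expect_equal(mismatch_ratio(15, 1000), 0.015)
  expect_equal(mismatch_ratio(2, 0), Inf)
})

test_that("strain evaluation imposes all four criteria with printed strictness", {
  cfg <- criteria_config()
  ok <- mk_row(100L, 20L, 30L, 10000L, 0.1)
  v <- evaluate_strain(ok, cfg)
  expect_true(v$accepted)
  expect_equal(v$failed_criteria, "")
  # criterion I is an inclusive minimum of 10
  expect_true(evaluate_strain(mk_row(read_count = 10L), cfg)$accepted)
  low <- evaluate_strain(mk_row(read_count = 9L), cfg)
  expect_false(low$accepted)
  expect_equal(low$failed_criteria, "I")
  # criterion II is strict: ratio exactly 0.01 fails
  at_ii <- evaluate_strain(mk_row(mismatches = 100L, nucleotides = 10000L),
                           cfg)
  expect_equal(at_ii$failed_criteria, "II")
  # criterion III is strict: abundance exactly 0.01 fails
  at_iii <- evaluate_strain(mk_row(s_abundance = 0.01), cfg)
  expect_equal(at_iii$failed_criteria, "III")
  # criterion IV is strict: fraction 0.005 fails, 0.004 fails, above passes
  at_iv <- evaluate_strain(mk_row(read_count = 1000L,
                                  read_count_uniq = 4L), cfg)
  expect_equal(at_iv$failed_criteria, "IV")
  expect_true(evaluate_strain(mk_row(read_count = 1000L,
                                     read_count_uniq = 6L), cfg)$accepted)
  # multiple violations are all listed
  multi <- evaluate_strain(mk_row(read_count = 9L, read_count_uniq = 0L,
                                  s_abundance = 0.001), cfg)
  expect_equal(multi$failed_criteria, "I,III,IV")
})

test_that("species evaluation re-thresholds abundance in a second pass without criterion IV", {
  cfg <- criteria_config()
  rows <- rbind(
    mk_row(200L, 100L, 0L, 20000L, 0.30, name = "spA"),
    mk_row(150L, 80L, 0L, 15000L, 0.15, name = "spB"),   # sets T = 0.15
    mk_row(300L, 0L, 0L, 30000L, 0.20, name = "spC"),    # fails IV only
    mk_row(100L, 0L, 0L, 10000L, 0.05, name = "spD"))    # fails IV, below T
  v <- evaluate_species(rows, cfg)
  expect_equal(v$accepted, c(TRUE, TRUE, TRUE, FALSE))
  # spC: IV omitted in pass 2, abundance 0.20 >= T
  # spD: abundance 0.05 < T, flagged as the abundance criterion
  expect_equal(v$failed_criteria[4], "III")
  # the species defining T stays accepted (inclusive comparison)
  expect_true(v$accepted[2])
})

test_that("species pass falls back to the configured abundance floor when nothing is selected", {
  cfg <- criteria_config()
  rows <- rbind(
    mk_row(9L, 5L, 0L, 900L, 0.50, name = "spA"),        # fails I
    mk_row(100L, 50L, 0L, 10000L, 0.02, name = "spB"))   # fails nothing but IV? no: passes
  # spB passes pass 1, so T = 0.02
  v <- evaluate_species(rows, cfg)
  expect_equal(v$accepted, c(FALSE, TRUE))
  rows2 <- rbind(
    mk_row(9L, 5L, 0L, 900L, 0.50, name = "spA"),
    mk_row(100L, 0L, 0L, 10000L, 0.02, name = "spB"))    # fails IV
  # nothing selected in pass 1 -> T = cfg floor; spB passes I, II and floor
  v2 <- evaluate_species(rows2, cfg)
  expect_equal(v2$accepted, c(FALSE, TRUE))
  expect_equal(nrow(evaluate_species(rows2[0, ], cfg)), 0L)
})

test_that("all species passing every criterion are all accepted", {
  rows <- rbind(mk_row(100L, 50L, 0L, 10000L, 0.2, name = "a"),
                mk_row(200L, 90L, 10L, 20000L, 0.4, name = "b"))
  expect_true(all(evaluate_species(rows, criteria_config())$accepted))
})

test_that("the alternative uniqueness-only pre-cycle is available", {
  cfg <- criteria_config(species_precycle = "uniq_only")
  rows <- rbind(
    mk_row(9L, 9L, 0L, 900L, 0.005, name = "noisy"),  # high uniq, tiny abundance
    mk_row(200L, 100L, 0L, 20000L, 0.3, name = "real"))
  v <- evaluate_species(rows, cfg)
  # the noisy row's abundance sets T = 0.005, but it still fails I
  expect_equal(v$accepted, c(FALSE, TRUE))
})

test_that("genus level uses only criteria I-III", {
  cfg <- criteria_config()
  v <- evaluate_genus_or_higher(
    mk_row(10L, 0L, 9L, 1000L, 0.011), cfg)
  expect_true(v$accepted)  # uniqueness ignored, boundary-passing values
  at <- evaluate_genus_or_higher(mk_row(s_abundance = 0.01), cfg)
  expect_equal(at$failed_criteria, "III")
})

test_that("partition is a disjoint cover at every level", {
  set.seed(77)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    mk_row(sample(0:200, 1), sample(0:50, 1), sample(0:300, 1),
           sample(500:20000, 1), stats::runif(1, 0, 0.3),
           name = paste0("r", i))
  }))
  for (lev in c("strain", "species", "genus", "phylum")) {
    p <- partition_clades(rows, lev)
    expect_equal(nrow(p$accepted) + nrow(p$rejected), nrow(rows))
    expect_length(intersect(p$accepted$name, p$rejected$name), 0)
    expect_setequal(c(p$accepted$name, p$rejected$name), rows$name)
    expect_true(all(p$rejected$failed_criteria != ""))
  }
  all_pass <- rbind(mk_row(name = "a"), mk_row(name = "b"))
  expect_equal(nrow(partition_clades(all_pass, "strain")$rejected), 0L)
})

test_that("tightening any threshold never grows the accepted set", {
  set.seed(78)
  rows <- do.call(rbind, lapply(1:60, function(i) {
    mk_row(sample(5:50, 1), sample(0:10, 1), sample(0:100, 1),
           sample(2000:8000, 1), stats::runif(1, 0, 0.05),
           name = paste0("r", i))
  }))
  base <- partition_clades(rows, "strain", criteria_config())$accepted$name
  tighter <- list(
    criteria_config(min_read_count = 20L),
    criteria_config(max_mismatch_ratio = 0.005),
    criteria_config(min_s_abundance = 0.02),
    criteria_config(min_unique_fraction = 0.1))
  for (cfg in tighter) {
    got <- partition_clades(rows, "strain", cfg)$accepted$name
    expect_true(all(got %in% base))
  }
})
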