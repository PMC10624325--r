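test_that("gene-name normalization is idempotent, case-insensitive and allele-blind", {
  variants <- c("TRAV1-2", "trav1-2", "TRAV1-02", "TRAV1-2*01", "Trav1-02*02")
  expect_true(all(normalize_gene(variants) == "TRAV1-2"))
  expect_identical(normalize_gene(normalize_gene(variants)),
                   normalize_gene(variants))
  expect_identical(normalize_gene("TRBV6-4*01"), "TRBV6-4")
  expect_identical(normalize_gene(c(NA, "")), c(NA, ""))
})

test_that("cell tables round-trip through both dialects field for field", {
  we <- worked_example_cohort()
  for (dialect in c("airr", "study_tsv")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_cell_table(we$cells, path, dialect)
    back <- read_cell_table(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(we$cells),
                 ignore_attr = TRUE)
  }
})

test_that("simulated cohorts round-trip and never silently drop a cell", {
  sim <- simulate_cohort(small_config(seed = 11))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(sim$cells, path, "airr")
  back <- read_cell_table(path, "airr")
  expect_equal(as.data.frame(back), as.data.frame(sim$cells),
               ignore_attr = TRUE)
  expect_identical(nrow(back) + nrow(attr(back, "rejected")), nrow(sim$cells))
})

test_that("bulk repertoires round-trip in AIRR and immunoSEQ dialects", {
  we <- worked_example_cohort()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_bulk_repertoire(we$blood$HC1, p1, "airr")
  expect_equal(read_bulk_repertoire(p1, "airr"), we$blood$HC1,
               ignore_attr = TRUE)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_bulk_repertoire(we$blood$CD2, p2, "immunoseq")
  expect_equal(read_bulk_repertoire(p2, "immunoseq", donor_id = "CD2",
                                    cohort = "CD"),
               we$blood$CD2, ignore_attr = TRUE)
})

test_that("shipped worked-example fixtures load and match the in-code cohort", {
  dir <- system.file("extdata", "worked_example", package = "maitrep")
  we <- worked_example_cohort()
  cells <- read_cell_table(file.path(dir, "cells.tsv"), "study_tsv")
  expect_equal(as.data.frame(cells), as.data.frame(we$cells), ignore_attr = TRUE)
  hc1 <- read_bulk_repertoire(file.path(dir, "blood_HC1.tsv"), "airr")
  expect_equal(hc1, we$blood$HC1, ignore_attr = TRUE)
})

test_that("a full biopsy of rows yields one record per cell with shared metadata", {
  sim <- simulate_cohort(sim_config(n_hc_donors = 1, n_cd_donors = 1,
                                    n_blood_per_cohort = 1,
                                    blood_cells_per_donor = 50,
                                    colon_cells_per_biopsy = 80,
                                    public_pool_size = 2, seed = 3))
  hc <- sim$cells[sim$cells$donor_id == "HC01", ]
  expect_identical(nrow(hc), 80L)
  expect_identical(unique(hc$tissue), "colon")
  expect_identical(unique(hc$inflammation), "uninflamed")
})

test_that("missing required columns and duplicate chains are reported", {
  we <- worked_example_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(we$cells, path, "airr")
  df <- readr::read_tsv(path, show_col_types = FALSE)
  p_bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df[, setdiff(names(df), "junction_aa")], p_bad)
  expect_error(read_cell_table(p_bad, "airr"), "junction_aa",
               class = "maitrep_format_error")
  # duplicate (cell_id, locus): ambiguity error by default, logged drop on request
  p_dup <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rbind(df, df[df$cell_id == "c1" & df$locus == "TRA", ]), p_dup)
  expect_error(read_cell_table(p_dup, "airr"), "c1",
               class = "maitrep_ambiguity_error")
  expect_warning(dropped <- read_cell_table(p_dup, "airr", on_duplicate = "drop"),
                 "doublet")
  expect_false("c1" %in% dropped$cell_id)
  expect_identical(attr(dropped, "rejected")$cell_id, "c1")
})

test_that("unparseable gene calls are kept but flagged nonproductive", {
  we <- worked_example_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(we$cells, path, "airr")
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df$v_call[df$cell_id == "c3" & df$locus == "TRB"] <- "not-a-gene"
  readr::write_tsv(df, path)
  expect_warning(cells <- read_cell_table(path, "airr"), "unparseable")
  expect_false(cells$beta_productive[cells$cell_id == "c3"])
  expect_identical(nrow(cells), nrow(we$cells))
})

test_that("a stray D call on a TRA row is reported and ignored", {
  we <- worked_example_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(we$cells, path, "airr")
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  df$d_call[df$cell_id == "c1" & df$locus == "TRA"] <- "TRBD1"
  readr::write_tsv(df, path)
  expect_warning(cells <- read_cell_table(path, "airr"), "d_call")
  expect_identical(nrow(cells), nrow(we$cells))
})

test_that("bulk reading merges identical rearrangements and filters nonproductive rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    amino_acid = c("CASSEGQGFF", "CASSEGQGFF", "CASSX*STOPF", "CASSOKAYF"),
    v_gene = "TRBV6-4", j_gene = "TRBJ2-1",
    templates = c(3, 2, 4, 1)), path)
  rep <- suppressMessages(
    read_bulk_repertoire(path, "immunoseq", donor_id = "D", cohort = "HC"))
  expect_identical(rep$clones$count[rep$clones$cdr3_aa == "CASSEGQGFF"], 5L)
  expect_false("CASSX*STOPF" %in% rep$clones$cdr3_aa)
  expect_identical(attr(rep, "n_excluded"), 1L)
  expect_identical(rep$total_cells, 6L)
})

test_that("bulk reading rejects bad counts and all-nonproductive files", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(amino_acid = "CASSF", v_gene = "TRBV1",
                                  j_gene = "TRBJ1-1", templates = 0), p1)
  expect_error(read_bulk_repertoire(p1, "immunoseq", donor_id = "D", cohort = "HC"),
               class = "maitrep_format_error")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(amino_acid = "CAS*SF", v_gene = "TRBV1",
                                  j_gene = "TRBJ1-1", templates = 2), p2)
  expect_error(suppressMessages(
    read_bulk_repertoire(p2, "immunoseq", donor_id = "D", cohort = "HC")),
    class = "maitrep_empty_error")
})

test_that("empty collections are not written without force", {
  we <- worked_example_cohort()
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_error(write_cell_table(we$cells[0, ], path, "study_tsv"),
               class = "maitrep_empty_error")
  expect_no_error(write_cell_table(we$cells[0, ], path, "study_tsv", force = TRUE))
})

test_that("simulated productive junctions translate consistently", {
  sim <- simulate_cohort(small_config(seed = 5))
  prod_a <- sim$cells[!is.na(sim$cells$alpha_cdr3_nt) & sim$cells$alpha_productive, ]
  expect_identical(translate_cdr3(prod_a$alpha_cdr3_nt), prod_a$alpha_cdr3_aa)
  expect_true(all(nchar(prod_a$alpha_cdr3_nt) %% 3 == 0))
  prod_b <- sim$cells[!is.na(sim$cells$beta_cdr3_nt) & sim$cells$beta_productive, ]
  expect_identical(translate_cdr3(prod_b$beta_cdr3_nt), prod_b$beta_cdr3_aa)
})
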