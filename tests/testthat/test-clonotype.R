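test_that("clonotype identity is exact at the nucleotide level", {
  base <- dplyr::bind_rows(
    one_cell(cell_id = "a1"), one_cell(cell_id = "a2"),
    one_cell(cell_id = "b1",
             beta_nt = "TGCGCAAGCAGCTTAGCACCAGGAGAGCAGTTCTTC"))  # synonymous
  base <- tibble::new_tibble(as.data.frame(base), class = "tcr_cells")
  ct <- build_clonotypes(base)
  # a1, a2 identical at nt -> one expanded clonotype; b1 has the same amino
  # acids but different nucleotides -> its own clonotype
  expect_identical(sort(ct$n_cells), c(1L, 2L))
  expect_identical(ct$expanded, c(TRUE, FALSE))
  sizes3 <- dplyr::bind_rows(base, one_cell(cell_id = "a3"))
  sizes3 <- tibble::new_tibble(as.data.frame(sizes3), class = "tcr_cells")
  expect_identical(sort(build_clonotypes(sizes3)$n_cells), c(1L, 3L))
})

test_that("cells with ambiguous bases are excluded from exact matching", {
  cells <- dplyr::bind_rows(
    one_cell(cell_id = "a1"),
    one_cell(cell_id = "n1", beta_nt = "TGTGCAAGCAGCTTAGCACCAGGAGAGCAGTTCTTN"))
  cells <- tibble::new_tibble(as.data.frame(cells), class = "tcr_cells")
  expect_message(ct <- build_clonotypes(cells), "n1")
  expect_identical(nrow(ct), 1L)
  expect_identical(attr(ct, "excluded"), "n1")
})

test_that("sharing edges enumerate all within-clonotype pairs with the right class", {
  we <- worked_example_cohort()
  canon <- canonical_cells(we$cells)
  ct <- build_clonotypes(canon)
  edges <- sharing_edges(ct, canon)
  tab <- table(edges$edge_class)
  expect_identical(as.integer(tab[["within_HC_biopsy"]]),
                   we$expected$edges$within_HC_biopsy)
  expect_identical(as.integer(tab[["within_CD_inflamed"]]),
                   we$expected$edges$within_CD_inflamed)
  expect_identical(as.integer(tab[["CD_cross_inflammation"]]),
                   we$expected$edges$CD_cross_inflammation)
  # a clonotype of k cells contributes choose(k, 2) edges
  per_ct <- table(edges$clonotype_id)
  sizes <- ct$n_cells[match(names(per_ct), ct$clonotype_id)]
  expect_identical(as.integer(per_ct), as.integer(choose(sizes, 2)))
  expect_false(any(ct$clonotype_id[ct$n_cells == 1L] %in% edges$clonotype_id))
})

test_that("the worked-example overlap table matches the hand enumeration", {
  we <- worked_example_cohort()
  ov <- colon_blood_overlap(canonical_cells(we$cells), we$blood)
  expect_equal(as.data.frame(ov), as.data.frame(we$expected$overlap),
               ignore_attr = TRUE)
})

test_that("a sequence in autologous and allogeneic blood increments each category once", {
  we <- worked_example_cohort()
  ov <- colon_blood_overlap(canonical_cells(we$cells), we$blood)
  hc <- ov[ov$stratum == "HC", ]
  # CASSLAPGATNEKLFF from HC2's colon is in HC2's own blood and HC1's blood
  expect_identical(hc$autologous, 3L)
  expect_identical(hc$allogeneic, 1L)
  expect_identical(hc$in_both, 3L)
})

test_that("overlap-table invariants hold across simulated cohorts", {
  for (seed in c(2, 12, 22)) {
    sim <- simulate_cohort(small_config(seed = seed))
    ov <- suppressMessages(
      colon_blood_overlap(canonical_cells(sim$cells), sim$blood))
    expect_true(all(ov$in_both <= ov$total_colon_unique))
    expect_true(all(pmax(ov$autologous, ov$allogeneic) <= ov$in_both))
    expect_true(all(ov$in_both <= ov$autologous + ov$allogeneic))
    expect_true(all(ov$autologous + ov$allogeneic <= 2L * ov$in_both))
    expect_identical(ov$pct_both, percent_round(ov$in_both, ov$total_colon_unique))
    # CD strata nest: the union row counts each sequence once
    cd <- ov[ov$stratum %in% c("CD all", "CD NC", "CD IC"), ]
    expect_lte(cd$total_colon_unique[1],
               cd$total_colon_unique[2] + cd$total_colon_unique[3])
    expect_gte(cd$total_colon_unique[1],
               max(cd$total_colon_unique[2], cd$total_colon_unique[3]))
  }
})

test_that("donor relabeling permutes outputs without changing counts", {
  sim <- simulate_cohort(small_config(seed = 41))
  canon <- canonical_cells(sim$cells)
  relabel <- function(x) sub("^HC", "ZHC", sub("^CD", "ZCD", x))
  cells2 <- canon
  cells2$donor_id <- relabel(cells2$donor_id)
  cells2$cell_id <- relabel(cells2$cell_id)
  blood2 <- lapply(sim$blood, function(r) {
    repertoire(relabel(r$donor_id), r$cohort, r$clones)
  })
  ov1 <- suppressMessages(colon_blood_overlap(canon, sim$blood))
  ov2 <- suppressMessages(colon_blood_overlap(cells2, blood2))
  expect_equal(as.data.frame(ov1), as.data.frame(ov2), ignore_attr = TRUE)
  p1 <- public_partition(sim$blood)
  p2 <- public_partition(blood2)
  expect_identical(p1[c("n_public", "n_cd_only", "n_hc_only", "n_shared")],
                   p2[c("n_public", "n_cd_only", "n_hc_only", "n_shared")])
})

test_that("publicity requires two persons and partitions by carrier cohorts", {
  mk <- function(d, co, seqs) {
    repertoire(d, co, tibble::tibble(cdr3_aa = seqs, v_call = "TRBV6-4",
                                     j_call = "TRBJ2-1",
                                     count = rep(1L, length(seqs))))
  }
  blood <- list(mk("CD1", "CD", c("AAA", "BBB", "DDD")),
                mk("CD2", "CD", c("AAA", "CCC")),
                mk("HC1", "HC", c("BBB", "CCC", "EEE")))
  pub <- public_partition(blood)
  expect_identical(pub$n_public, 3L)            # AAA, BBB, CCC
  expect_identical(pub$n_cd_only, 1L)           # AAA in CD1+CD2
  expect_identical(pub$n_hc_only, 0L)
  expect_identical(pub$n_shared, 2L)            # BBB, CCC span cohorts
  expect_identical(pub$n_cd_only + pub$n_hc_only + pub$n_shared, pub$n_public)
  expect_false("DDD" %in% pub$sequences$cdr3_aa) # single carrier: private
  expect_error(public_partition(blood[1]), class = "maitrep_data_error")
})

test_that("integer percents use round-half-away-from-zero", {
  expect_identical(percent_round(37, 87), 43L)   # 42.53
  expect_identical(percent_round(5, 8), 63L)     # 62.5 rounds away from zero
  expect_identical(percent_round(7, 59), 12L)
  expect_identical(percent_round(0, 10), 0L)
  expect_identical(percent_round(3, 0), 0L)
})
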