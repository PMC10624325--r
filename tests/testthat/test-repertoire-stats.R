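test_that("Simpson clonality hits its boundary anchors and small exact values", {
  expect_identical(simpson_clonality(c(5))$simpson, 1)
  expect_identical(simpson_clonality(c(1, 1, 1, 1))$simpson, 0)
  # counts (2,1,1): of the 6 unordered pairs of 4 cells exactly one is same-clone
  expect_equal(simpson_clonality(c(2, 1, 1))$simpson, 1 / 6)
  expect_equal(simpson_clonality(c(2, 1, 1))$simpson, simpson_bruteforce(c(2, 1, 1)))
  expect_error(simpson_clonality(c(1)), class = "maitrep_data_error")
})

test_that("Simpson clonality equals exhaustive pair enumeration on random repertoires", {
  set.seed(101)
  for (i in 1:25) {
    counts <- sample(1:12, sample(2:25, 1), replace = TRUE)
    expect_equal(simpson_clonality(counts)$simpson, simpson_bruteforce(counts),
                 tolerance = 1e-12)
  }
})

test_that("Morisita-Horn overlap hits anchors and the hand-worked fraction", {
  we <- worked_example_cohort()
  expect_identical(morisita_overlap(we$blood$HC1, we$blood$HC1), 1)
  disjoint <- repertoire("X", "HC", tibble::tibble(
    cdr3_aa = c("CZZA", "CZZB"), v_call = "", j_call = "", count = c(2L, 3L)))
  expect_identical(morisita_overlap(we$blood$HC1, disjoint), 0)
  # p = {A: .5, B: .5} vs q = {A: 1}: 2 * 0.5 / (0.5 + 1) = 2/3
  a <- repertoire("A", "HC", tibble::tibble(cdr3_aa = c("A", "B"), v_call = "",
                                            j_call = "", count = c(1L, 1L)))
  b <- repertoire("B", "HC", tibble::tibble(cdr3_aa = "A", v_call = "",
                                            j_call = "", count = 7L))
  expect_equal(morisita_overlap(a, b), 2 / 3)
})

test_that("Morisita-Horn matches a brute-force union evaluation and its invariances", {
  set.seed(202)
  for (i in 1:25) {
    ra <- random_repertoire("A", "HC")
    rb <- random_repertoire("B", "CD")
    got <- morisita_overlap(ra, rb)
    x <- setNames(ra$clones$count, ra$clones$cdr3_aa)
    y <- setNames(rb$clones$count, rb$clones$cdr3_aa)
    expect_equal(got, morisita_bruteforce(x, y), tolerance = 1e-12)
    expect_equal(got, morisita_overlap(rb, ra), tolerance = 1e-15)
    # scale invariance: multiplying one repertoire's counts changes nothing
    rb10 <- repertoire("B", "CD", dplyr::mutate(rb$clones, count = count * 10L))
    expect_equal(got, morisita_overlap(ra, rb10), tolerance = 1e-12)
  }
})

test_that("the classical count-based variant is available and agrees at the anchors", {
  we <- worked_example_cohort()
  disjoint <- repertoire("X", "HC", tibble::tibble(
    cdr3_aa = "CZZA", v_call = "", j_call = "", count = 5L))
  expect_identical(morisita_overlap(we$blood$HC1, disjoint, variant = "classical"), 0)
  self <- morisita_overlap(we$blood$HC1, we$blood$HC1, variant = "classical")
  expect_gt(self, 1)  # the classical estimator exceeds 1 on self-comparison
})

test_that("overlap matrix is symmetric with unit diagonal and partitions pairs by cohort", {
  set.seed(303)
  reps <- c(lapply(1:8, function(i) random_repertoire(sprintf("HC%02d", i), "HC")),
            lapply(1:8, function(i) random_repertoire(sprintf("CD%02d", i), "CD")))
  om <- overlap_matrix(reps)
  expect_identical(dim(om$matrix), c(16L, 16L))
  expect_identical(om$matrix, t(om$matrix))
  expect_true(all(diag(om$matrix) == 1))
  expect_true(all(om$matrix >= 0 & om$matrix <= 1))
  expect_identical(nrow(om$pairs), 120L)
  expect_identical(lengths(om$groups),
                   c(HCvsHC = 28L, CDvsCD = 28L, HCvsCD = 64L))
  expect_identical(sum(lengths(om$groups)), 120L)
})

test_that("consensus motif applies majority, bracket and wildcard rules", {
  # M at 6/11 is a majority: single residue
  seqs_major <- c(rep("CAVMDSNYQLIW", 6), rep("CAVRDSNYQLIW", 5))
  m1 <- consensus_motif(seqs_major)
  expect_identical(m1$motif, "CAVMDSNYQLIW")
  expect_equal(m1$support, 6 / 11)
  # 5 M + 5 R + 1 other: no majority, top two together pass -> bracket
  seqs_split <- c(rep("CAVMDSNYQLIW", 5), rep("CAVRDSNYQLIW", 5), "CAVGDSNYQLIW")
  m2 <- consensus_motif(seqs_split)
  expect_identical(m2$motif, "CAV[M/R]DSNYQLIW")
  expect_equal(m2$support, 10 / 11)
  # identical sequences: the sequence itself, full support
  m3 <- consensus_motif(rep("CAVMDSNYQLIW", 10))
  expect_identical(m3$motif, "CAVMDSNYQLIW")
  expect_identical(m3$support, 1)
  # maximally diverse position falls back to X
  m4 <- consensus_motif(c("CAAW", "CCGW", "CGTW", "CTCW", "CDDW"))
  expect_identical(substr(m4$motif, 2, 3), "XX")
  # order invariance
  expect_identical(consensus_motif(rev(seqs_split))$motif, m2$motif)
  # modal-length restriction
  m5 <- consensus_motif(c(rep("CAVMDSNYQLIW", 3), "CAAAF"))
  expect_identical(m5$n_used, 3L)
})

test_that("gene usage fractions are per segment and sum to one", {
  cells <- dplyr::bind_rows(lapply(1:4, function(i) {
    one_cell(cell_id = paste0("g", i), alpha_j = if (i == 4) "TRAJ20" else "TRAJ33")
  }))
  cells <- tibble::new_tibble(as.data.frame(cells), class = "tcr_cells")
  gu <- gene_usage(cells, "TRAJ")
  expect_equal(gu$fraction[gu$gene == "TRAJ33"], 0.75)
  expect_equal(gu$fraction[gu$gene == "TRAJ20"], 0.25)
  expect_equal(sum(gu$fraction), 1)
  sim <- simulate_cohort(small_config(seed = 51))
  canon <- canonical_cells(sim$cells)
  for (seg in c("TRAJ", "TRBV", "TRBD", "TRBJ")) {
    expect_equal(sum(gene_usage(canon, seg)$fraction), 1, tolerance = 1e-9)
  }
  rep1 <- sim$blood[[1]]
  expect_equal(sum(gene_usage(rep1, "TRBV")$fraction), 1, tolerance = 1e-9)
  expect_error(gene_usage(rep1, "TRAJ"), class = "maitrep_data_error")
  expect_error(gene_usage(cells[0, ], "TRAJ"), class = "maitrep_empty_error")
})
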