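# deterministic codon choice (alphabetically first) so the example needs no RNG
.det_back_translate <- function(aa_vec) {
  cod <- .aa_codons()
  vapply(aa_vec, function(aa) {
    ch <- strsplit(aa, "")[[1]]
    paste(vapply(ch, function(a) sort(cod[[a]])[1], character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' A tiny hand-checkable cohort
#'
#' Four donors (two healthy controls, two Crohn's), each with a small blood
#' repertoire and a handful of colonic cells, built literally in code with no
#' randomness. Every downstream quantity is small enough to enumerate by
#' hand; the hand-computed values ship in the `expected` element (and in the
#' fixture directory `inst/extdata/worked_example/`), so this cohort anchors
#' the end-to-end tests:
#'
#' * Simpson clonality — HC1 counts (4,1,1): 12/30 = 0.4; HC2 (2,2): 4/12 =
#'   1/3; CD1 (3,1) and CD2 (1,3): 6/12 = 0.5 each.
#' * Morisita-Horn — HC1 vs HC2 = 2/3; CD1 vs CD2 = 0.3.
#' * Public blood sequences — CASSLAPGATNEKLFF in both HC donors,
#'   CASSVDGNTEAFF in both CD donors: 2 public, 1 HC-only, 1 CD-only.
#' * Colon-blood overlap — per-stratum counts in `expected$overlap`
#'   (the pooled row is 8 unique colonic sequences, 5 in blood: 62.5%
#'   rounds half-away-from-zero to 63%).
#' * Sharing — one expanded HC clonotype (2 cells), one CD clonotype with
#'   cells in both the inflamed and uninflamed biopsy (3 cells: one
#'   inflamed-inflamed edge, two cross-inflammation edges).
#'
#' @return list with `cells`, `blood` (list of [repertoire()]) and
#'   `expected` (hand-computed reference values).
#' @export
worked_example_cohort <- function() {
  S <- c(S1 = "CASSLAPGATNEKLFF", S2 = "CASSEGQGAYEQYF", S3 = "CASSPRDRGYTF",
         S4 = "CASSQDRGNQPQHF", S5 = "CASSVDGNTEAFF", S6 = "CASSLGGAYNEQFF",
         S7 = "CASSDRDRVNTLYF", S8 = "CASSPGTSGSYEQYF", S9 = "CASSLLWDQPQHF",
         S10 = "CASSEARGYGYTF", S11 = "CASSTTNEKLFF")
  mk_rep <- function(donor, cohort, seqs, counts) {
    repertoire(donor, cohort, tibble::tibble(
      cdr3_aa = unname(S[seqs]), v_call = "TRBV6-4", j_call = "TRBJ2-1",
      count = counts))
  }
  blood <- list(
    HC1 = mk_rep("HC1", "HC", c("S1", "S2", "S3"), c(4L, 1L, 1L)),
    HC2 = mk_rep("HC2", "HC", c("S1", "S4"), c(2L, 2L)),
    CD1 = mk_rep("CD1", "CD", c("S5", "S6"), c(3L, 1L)),
    CD2 = mk_rep("CD2", "CD", c("S5", "S7"), c(1L, 3L))
  )

  alpha_aa <- "CAVMDSNYQLIW"
  alpha_nt <- .det_back_translate(alpha_aa)
  cell <- function(id, donor, cohort, inflammation, beta, canonical = TRUE,
                   alpha_v = "TRAV1-2") {
    b_aa <- unname(S[beta])
    tibble::tibble(
      cell_id = id, donor_id = donor, cohort = cohort, tissue = "colon",
      inflammation = inflammation,
      alpha_v_call = alpha_v, alpha_j_call = "TRAJ33",
      alpha_cdr3_nt = alpha_nt, alpha_cdr3_aa = alpha_aa,
      alpha_productive = TRUE,
      beta_v_call = "TRBV20-1", beta_d_call = "TRBD1", beta_j_call = "TRBJ2-1",
      beta_cdr3_nt = .det_back_translate(b_aa), beta_cdr3_aa = b_aa,
      beta_productive = TRUE)
  }
  cells <- dplyr::bind_rows(
    cell("c1", "HC1", "HC", "uninflamed", "S2"),
    cell("c2", "HC1", "HC", "uninflamed", "S2"),
    cell("c3", "HC1", "HC", "uninflamed", "S9"),
    cell("c4", "HC1", "HC", "uninflamed", "S11", alpha_v = "TRAV8-2"),
    cell("c5", "HC2", "HC", "uninflamed", "S4"),
    cell("c6", "HC2", "HC", "uninflamed", "S1"),
    cell("d1", "CD1", "CD", "inflamed", "S6"),
    cell("d2", "CD1", "CD", "inflamed", "S6"),
    cell("d3", "CD1", "CD", "uninflamed", "S6"),
    cell("d4", "CD1", "CD", "uninflamed", "S5"),
    cell("d5", "CD2", "CD", "uninflamed", "S8"),
    cell("d6", "CD2", "CD", "inflamed", "S10")
  )
  cells <- tibble::new_tibble(as.data.frame(cells), class = "tcr_cells")

  expected <- list(
    simpson = c(HC1 = 0.4, HC2 = 1 / 3, CD1 = 0.5, CD2 = 0.5),
    morisita = c(HC1_HC2 = 2 / 3, CD1_CD2 = 0.3),
    public = list(n_public = 2L, n_cd_only = 1L, n_hc_only = 1L, n_shared = 0L),
    overlap = tibble::tibble(
      stratum = c("HC", "CD all", "CD NC", "CD IC", "total"),
      total_colon_unique = c(4L, 4L, 3L, 2L, 8L),
      in_both = c(3L, 2L, 2L, 1L, 5L),
      autologous = c(3L, 2L, 2L, 1L, 5L),
      allogeneic = c(1L, 1L, 1L, 0L, 2L),
      pct_both = c(75L, 50L, 67L, 50L, 63L),
      pct_autologous = c(75L, 50L, 67L, 50L, 63L),
      pct_allogeneic = c(25L, 25L, 33L, 0L, 25L)),
    n_canonical = 11L,
    edges = list(within_HC_biopsy = 1L, within_CD_inflamed = 1L,
                 CD_cross_inflammation = 2L))
  list(cells = cells, blood = blood, expected = expected)
}
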