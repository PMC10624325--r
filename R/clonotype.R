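#' Round a percentage half away from zero
#'
#' Integer percentages in the overlap accounting are rounded half away from
#' zero (37/87 = 42.5% reports as 43%), not with base R's round-half-to-even.
#' @param count,total numerator and denominator counts.
#' @return integer percent vector; `0` when `total` is zero.
#' @export
percent_round <- function(count, total) {
  p <- ifelse(total > 0, 100 * count / total, 0)
  as.integer(sign(p) * floor(abs(p) + 0.5))
}

#' Group canonical cells into paired clonotypes
#'
#' Clonotype identity in the colon is exact: two cells belong to the same
#' clonotype when both their alpha and beta chains agree on V gene, J gene and
#' the CDR3 *nucleotide* sequence. Clonotypes are donor-scoped by default —
#' cross-donor identity is a separate (publicity) question asked at the
#' beta amino-acid level.
#'
#' Cells whose alpha or beta CDR3 nucleotide sequence contains an ambiguous
#' `N` are excluded from exact matching and reported in the `excluded`
#' attribute.
#'
#' @param cells canonical cells (see [canonical_cells()]).
#' @param within_donor scope clonotypes to a donor (default). `FALSE` pools
#'   cells across donors, which labels public paired identity explicitly.
#' @return tibble, one row per clonotype, with the alpha/beta key columns,
#'   `cell_ids` (list column), `n_cells`, and `expanded` (`n_cells >= 2`);
#'   attribute `excluded` holds the ids of `N`-containing cells.
#' @export
build_clonotypes <- function(cells, within_donor = TRUE) {
  has_n <- grepl("N", cells$alpha_cdr3_nt) | grepl("N", cells$beta_cdr3_nt)
  excluded <- cells$cell_id[has_n]
  if (length(excluded)) {
    inform(sprintf("excluded %d cell(s) with ambiguous bases from clonotype matching: %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  df <- cells[!has_n, , drop = FALSE]
  keys <- c(if (within_donor) "donor_id",
            "alpha_v_call", "alpha_j_call", "alpha_cdr3_nt",
            "beta_v_call", "beta_j_call", "beta_cdr3_nt")
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      beta_cdr3_aa = .data$beta_cdr3_aa[1],
      cell_ids = list(.data$cell_id),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(expanded = .data$n_cells >= 2L) |>
    dplyr::arrange(dplyr::desc(.data$n_cells))
  out$clonotype_id <- sprintf("ct%04d", seq_len(nrow(out)))
  out <- dplyr::relocate(out, "clonotype_id")
  attr(out, "excluded") <- excluded
  out
}

#' Enumerate cell-pair sharing edges within clonotypes
#'
#' Every unordered pair of distinct cells inside one clonotype is an edge —
#' the edge list behind a circos-style sharing plot. Edges are classed by the
#' tissue context of the two cells: pairs within a healthy-control biopsy,
#' within an inflamed or an uninflamed Crohn's biopsy, or spanning the
#' inflamed and uninflamed biopsies of one Crohn's donor.
#'
#' @param clonotypes output of [build_clonotypes()].
#' @param cells the cell table the clonotypes were built from (metadata
#'   lookup).
#' @return tibble with columns `cell_id_1`, `cell_id_2`, `clonotype_id`,
#'   `edge_class`.
#' @export
sharing_edges <- function(clonotypes, cells) {
  meta <- cells[, c("cell_id", "donor_id", "cohort", "inflammation")]
  edges <- clonotypes |>
    dplyr::filter(.data$n_cells >= 2L) |>
    dplyr::reframe(
      {
        ids <- sort(unlist(.data$cell_ids))
        pr <- combn(ids, 2L)
        tibble::tibble(cell_id_1 = pr[1, ], cell_id_2 = pr[2, ])
      },
      .by = "clonotype_id"
    )
  if (nrow(edges) == 0L) {
    return(tibble::tibble(cell_id_1 = character(), cell_id_2 = character(),
                          clonotype_id = character(), edge_class = character()))
  }
  m1 <- meta[match(edges$cell_id_1, meta$cell_id), ]
  m2 <- meta[match(edges$cell_id_2, meta$cell_id), ]
  cls <- ifelse(m1$cohort == "HC", "within_HC_biopsy",
         ifelse(m1$inflammation != m2$inflammation, "CD_cross_inflammation",
         ifelse(m1$inflammation == "inflamed", "within_CD_inflamed",
                "within_CD_uninflamed")))
  tibble::tibble(cell_id_1 = edges$cell_id_1, cell_id_2 = edges$cell_id_2,
                 clonotype_id = edges$clonotype_id, edge_class = cls)
}

# unique colon beta CDR3aa sequences with their carrier donors, for a subset
# of canonical colon cells
.colon_seq_carriers <- function(cells) {
  cells |>
    dplyr::filter(!grepl("N", .data$beta_cdr3_nt) | is.na(.data$beta_cdr3_nt)) |>
    dplyr::distinct(.data$beta_cdr3_aa, .data$donor_id) |>
    dplyr::group_by(.data$beta_cdr3_aa) |>
    dplyr::summarise(carriers = list(unique(.data$donor_id)), .groups = "drop")
}

.overlap_stratum <- function(seqs, blood_sets, label) {
  if (nrow(seqs) == 0L) {
    return(tibble::tibble(stratum = label, total_colon_unique = 0L, in_both = 0L,
                          autologous = 0L, allogeneic = 0L, pct_both = 0L,
                          pct_autologous = 0L, pct_allogeneic = 0L))
  }
  donors <- names(blood_sets)
  hit <- function(s, who) any(vapply(who, function(d) s %in% blood_sets[[d]], logical(1)))
  auto <- mapply(function(s, carriers) hit(s, intersect(carriers, donors)),
                 seqs$beta_cdr3_aa, seqs$carriers)
  allo <- mapply(function(s, carriers) hit(s, setdiff(donors, carriers)),
                 seqs$beta_cdr3_aa, seqs$carriers)
  both <- auto | allo
  n <- nrow(seqs)
  tibble::tibble(
    stratum = label, total_colon_unique = n,
    in_both = sum(both), autologous = sum(auto), allogeneic = sum(allo),
    pct_both = percent_round(sum(both), n),
    pct_autologous = percent_round(sum(auto), n),
    pct_allogeneic = percent_round(sum(allo), n)
  )
}

#' Colon-to-blood overlap accounting
#'
#' For each stratum of colonic biopsies — healthy controls, all Crohn's
#' biopsies, Crohn's uninflamed (NC), Crohn's inflamed (IC), and the pooled
#' total — counts the unique colonic beta-chain CDR3 amino-acid sequences and
#' how many of them also occur in blood: in any blood repertoire (`in_both`),
#' in the blood of a donor whose own colon carried the sequence
#' (`autologous`), and in the blood of at least one other person
#' (`allogeneic`). The two categories can overlap, so
#' `max(autologous, allogeneic) <= in_both <= autologous + allogeneic`.
#' Sequences seen in both the NC and IC biopsy of a donor count once in the
#' union strata. Percentages are of the stratum's unique colonic sequences,
#' rounded half away from zero.
#'
#' Colon donors without a blood sample still contribute colonic sequences;
#' they are reported via a message (the study design had more biopsy donors
#' than blood donors).
#'
#' @param cells canonical colonic cells.
#' @param blood list of blood [repertoire()] objects.
#' @return an `overlap_table` tibble, one row per stratum.
#' @export
colon_blood_overlap <- function(cells, blood) {
  cells <- cells[cells$tissue == "colon", , drop = FALSE]
  blood_sets <- lapply(blood, function(r) unique(r$clones$cdr3_aa))
  names(blood_sets) <- vapply(blood, `[[`, character(1), "donor_id")
  no_blood <- setdiff(unique(cells$donor_id), names(blood_sets))
  if (length(no_blood)) {
    inform(sprintf("colon donor(s) without a blood repertoire: %s",
                   paste(no_blood, collapse = ", ")))
  }
  strata <- list(
    HC     = cells[cells$cohort == "HC", ],
    `CD all` = cells[cells$cohort == "CD", ],
    `CD NC`  = cells[cells$cohort == "CD" & cells$inflammation == "uninflamed", ],
    `CD IC`  = cells[cells$cohort == "CD" & cells$inflammation == "inflamed", ],
    total  = cells
  )
  out <- dplyr::bind_rows(lapply(names(strata), function(nm) {
    .overlap_stratum(.colon_seq_carriers(strata[[nm]]), blood_sets, nm)
  }))
  class(out) <- c("overlap_table", class(out))
  out
}

#' Partition public blood sequences by cohort
#'
#' A beta-chain CDR3 amino-acid sequence is *public* when it occurs in the
#' blood repertoires of at least two distinct donors. Public sequences are
#' partitioned by the cohorts of their carriers: seen only in Crohn's donors,
#' only in healthy controls, or in at least one donor of each cohort. The
#' three classes always sum to the number of public sequences.
#'
#' @param blood list of blood [repertoire()] objects (at least two donors).
#' @return list with `sequences` (tibble: `cdr3_aa`, `donors` list column,
#'   `n_donors`, `class`), and counts `n_public`, `n_cd_only`, `n_hc_only`,
#'   `n_shared`.
#' @export
public_partition <- function(blood) {
  if (length(blood) < 2L) {
    abort("publicity needs at least two donors", class = "maitrep_data_error")
  }
  tab <- dplyr::bind_rows(lapply(blood, function(r) {
    tibble::tibble(cdr3_aa = unique(r$clones$cdr3_aa),
                   donor_id = r$donor_id, cohort = r$cohort)
  }))
  pub <- tab |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(
      donors = list(unique(.data$donor_id)),
      n_donors = length(unique(.data$donor_id)),
      class = {
        co <- unique(.data$cohort)
        if (length(co) == 2L) "shared" else if (co == "CD") "cd_only" else "hc_only"
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_donors >= 2L)
  list(
    sequences = pub,
    n_public = nrow(pub),
    n_cd_only = sum(pub$class == "cd_only"),
    n_hc_only = sum(pub$class == "hc_only"),
    n_shared = sum(pub$class == "shared")
  )
}
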