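#' Classify sorted cells as canonical MAIT versus contaminant
#'
#' MAIT cells carry a semi-invariant alpha chain: TRAV1-2 joined to TRAJ12,
#' TRAJ20 or TRAJ33. Flow sorting on surface phenotype alone is imperfect in
#' the colon, so each sequenced cell is gated here on its rearrangement: a
#' cell is canonical when its alpha chain is present, productive, uses
#' TRAV1-2 with one of the three invariant J segments, and (because clonotype
#' analysis needs productive pairs) its beta chain is present and productive.
#'
#' Non-canonical cells get the first failing reason in a fixed order —
#' `missing_alpha`, `nonproductive_alpha`, `wrong_trav`, `wrong_traj`,
#' `missing_beta` — so the contaminant breakdown is reproducible.
#'
#' @param cells a `tcr_cells` tibble (see [read_cell_table()]).
#' @param require_beta if `FALSE`, classify on the alpha chain alone (the
#'   alpha-only tabulation used for per-sample canonical fractions);
#'   `missing_beta` is then never assigned.
#' @return tibble with columns `cell_id`, `is_canonical`, `reason`
#'   (factor over the fixed reason levels).
#' @export
classify_cells <- function(cells, require_beta = TRUE) {
  a_present <- !is.na(cells$alpha_v_call)
  a_prod <- a_present & cells$alpha_productive
  trav_ok <- a_prod & cells$alpha_v_call == .mait_trav
  traj_ok <- trav_ok & cells$alpha_j_call %in% .mait_traj
  b_ok <- !is.na(cells$beta_v_call) & cells$beta_productive

  reason <- rep("canonical", nrow(cells))
  reason[traj_ok & !b_ok] <- "missing_beta"
  reason[trav_ok & !traj_ok] <- "wrong_traj"
  reason[a_prod & !trav_ok] <- "wrong_trav"
  reason[a_present & !a_prod] <- "nonproductive_alpha"
  reason[!a_present] <- "missing_alpha"
  if (!require_beta) reason[reason == "missing_beta"] <- "canonical"

  tibble::tibble(
    cell_id = cells$cell_id,
    is_canonical = reason == "canonical",
    reason = factor(reason, levels = .filter_reasons)
  )
}

#' Subset a cell table to canonical MAIT cells
#'
#' @inheritParams classify_cells
#' @return the canonical rows of `cells`.
#' @export
canonical_cells <- function(cells, require_beta = TRUE) {
  cls <- classify_cells(cells, require_beta = require_beta)
  cells[cls$is_canonical, , drop = FALSE]
}

#' Per-sample canonical/contaminant tabulation
#'
#' One row per sample (donor, tissue, inflammation) with total, canonical and
#' non-canonical cell counts, the canonical fraction, and the TRAJ usage among
#' canonical cells — the shape used to report sort purity per biopsy. The
#' pooled canonical fraction across all samples is attached as the
#' `canonical_fraction` attribute.
#'
#' @inheritParams classify_cells
#' @return tibble with columns `donor_id`, `tissue`, `inflammation`,
#'   `n_total`, `n_canonical`, `n_noncanonical`, `fraction_canonical`,
#'   `TRAJ12`, `TRAJ20`, `TRAJ33`.
#' @export
summarize_filter <- function(cells, require_beta = TRUE) {
  if (nrow(cells) == 0L) {
    abort("no cells to summarize", class = "maitrep_empty_error")
  }
  cls <- classify_cells(cells, require_beta = require_beta)
  df <- cells |>
    dplyr::mutate(is_canonical = cls$is_canonical)
  traj_of <- function(sub) {
    j <- sub$alpha_j_call[sub$is_canonical]
    vapply(.mait_traj, function(g) sum(j == g, na.rm = TRUE), integer(1))
  }
  out <- df |>
    dplyr::group_by(.data$donor_id, .data$tissue, .data$inflammation) |>
    dplyr::group_modify(function(sub, key) {
      traj <- traj_of(sub)
      tibble::tibble(
        n_total = nrow(sub),
        n_canonical = sum(sub$is_canonical),
        n_noncanonical = sum(!sub$is_canonical),
        fraction_canonical = sum(sub$is_canonical) / nrow(sub),
        TRAJ12 = traj[["TRAJ12"]], TRAJ20 = traj[["TRAJ20"]],
        TRAJ33 = traj[["TRAJ33"]]
      )
    }) |>
    dplyr::ungroup()
  attr(out, "canonical_fraction") <- sum(out$n_canonical) / sum(out$n_total)
  out
}
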