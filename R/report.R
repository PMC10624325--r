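#' Run the full repertoire analysis and write its report tables
#'
#' Orchestrates the pipeline on a cohort: classifies cells, writes the
#' per-sample canonical/contaminant summary (with a pooled TOTAL row), builds
#' clonotypes and their sharing edge list, tabulates alpha/beta gene usage
#' and the alpha-chain consensus motif over canonical cells, computes per-
#' donor blood Simpson clonality, the pairwise Morisita matrix and its cohort
#' groupings, the colon-blood overlap table, and the public-sequence cohort
#' partition. All outputs are TSV (plus a JSON copy of the scalar results);
#' a `manifest.json` lists every file written with its MD5 checksum, so a
#' rerun on identical inputs is verifiably identical.
#'
#' @param cells a `tcr_cells` tibble (colonic single cells).
#' @param blood list of blood [repertoire()] objects (may be empty).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_repertoire_analysis <- function(cells, blood, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, progress = FALSE)
    written <<- c(written, path)
    path
  }

  fs <- summarize_filter(cells)
  total_row <- tibble::tibble(
    donor_id = "TOTAL", tissue = "", inflammation = "",
    n_total = sum(fs$n_total), n_canonical = sum(fs$n_canonical),
    n_noncanonical = sum(fs$n_noncanonical),
    fraction_canonical = sum(fs$n_canonical) / sum(fs$n_total),
    TRAJ12 = sum(fs$TRAJ12), TRAJ20 = sum(fs$TRAJ20), TRAJ33 = sum(fs$TRAJ33))
  emit(dplyr::bind_rows(fs, total_row), "filter_summary.tsv")

  canon <- canonical_cells(cells)
  if (nrow(canon) == 0L) {
    abort(sprintf(
      "no canonical MAIT cells after filtering (%d cells: %s)",
      nrow(cells),
      paste(sprintf("%s=%d", names(table(classify_cells(cells)$reason)),
                    as.integer(table(classify_cells(cells)$reason))),
            collapse = ", ")),
      class = "maitrep_empty_error")
  }

  ct <- build_clonotypes(canon)
  ct_out <- ct |>
    dplyr::mutate(cell_ids = vapply(.data$cell_ids, paste, character(1),
                                    collapse = ";"))
  emit(ct_out, "clonotypes.tsv")
  edges <- sharing_edges(ct, canon)
  emit(edges, "sharing_edges.tsv")

  usage <- dplyr::bind_rows(lapply(c("TRAJ", "TRBV", "TRBD", "TRBJ"),
                                   function(seg) {
    dplyr::mutate(gene_usage(canon, seg), segment = seg, .before = 1)
  }))
  emit(usage, "gene_usage.tsv")

  motif <- consensus_motif(canon$alpha_cdr3_aa)
  motif_row <- tibble::tibble(chain = "alpha", support = motif$support,
                              n_used = motif$n_used)
  motif_row$motif <- motif$motif
  emit(motif_row[, c("chain", "motif", "support", "n_used")],
       "consensus_motif.tsv")

  diversity <- NULL
  om <- NULL
  if (length(blood) >= 1L) {
    diversity <- dplyr::bind_rows(lapply(blood, function(r) {
      d <- simpson_clonality(r)
      tibble::tibble(donor_id = r$donor_id, cohort = r$cohort,
                     simpson = d$simpson, n_cells = d$n_cells,
                     n_clones = d$n_clones)
    }))
    emit(diversity, "diversity.tsv")
  }
  if (length(blood) >= 2L) {
    om <- overlap_matrix(blood)
    grid <- tibble::as_tibble(om$matrix, rownames = "donor_id")
    emit(grid, "morisita_matrix.tsv")
    emit(om$pairs, "morisita_pairs.tsv")
    pub <- public_partition(blood)
    pub_out <- pub$sequences |>
      dplyr::mutate(donors = vapply(.data$donors, paste, character(1),
                                    collapse = ";"))
    emit(pub_out, "public_partition.tsv")
    emit(tibble::tibble(n_public = pub$n_public, n_cd_only = pub$n_cd_only,
                        n_hc_only = pub$n_hc_only, n_shared = pub$n_shared),
         "public_counts.tsv")
  } else {
    inform("fewer than two blood repertoires: overlap matrix and publicity skipped")
    pub <- NULL
  }
  ov <- NULL
  if (length(blood) >= 1L) {
    ov <- colon_blood_overlap(canon, blood)
    emit(ov, "overlap_table.tsv")
  }

  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  jsonlite::write_json(
    list(files = manifest,
         canonical_fraction = attr(fs, "canonical_fraction"),
         consensus_motif = motif$motif),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(filter_summary = fs, clonotypes = ct, edges = edges,
                 gene_usage = usage, motif = motif, diversity = diversity,
                 overlap_matrix = om, overlap_table = ov, public = pub,
                 manifest = manifest))
}

#' Nonparametric group comparisons of diversity and overlap
#'
#' Mirrors the reporting style of repertoire figures: an unpaired
#' Mann-Whitney test of blood Simpson clonality between cohorts and a
#' Kruskal-Wallis test across the three Morisita pair groups (HC vs HC, CD
#' vs CD, HC vs CD). Delegated to [stats::wilcox.test()] and
#' [stats::kruskal.test()]; p-values are reported unadjusted. Comparisons
#' with a group of fewer than two values are skipped with the reason in the
#' `note` column.
#'
#' @param diversity tibble with columns `cohort`, `simpson` (as written by
#'   [run_repertoire_analysis()]).
#' @param morisita_pairs tibble with columns `group`, `morisita`, or `NULL`.
#' @return tibble with `comparison`, `test`, `statistic`, `p_value`, `note`.
#' @export
compare_groups <- function(diversity, morisita_pairs = NULL) {
  rows <- list()
  g <- split(diversity$simpson, diversity$cohort)
  if (length(g) == 2L && all(lengths(g) >= 2L)) {
    wt <- suppressWarnings(wilcox.test(g[["CD"]], g[["HC"]]))
    rows[[1]] <- tibble::tibble(comparison = "simpson CD vs HC",
                                test = "mann_whitney",
                                statistic = unname(wt$statistic),
                                p_value = wt$p.value, note = "")
  } else {
    rows[[1]] <- tibble::tibble(comparison = "simpson CD vs HC",
                                test = "mann_whitney", statistic = NA_real_,
                                p_value = NA_real_,
                                note = "skipped: group with fewer than 2 values")
  }
  if (!is.null(morisita_pairs)) {
    gg <- split(morisita_pairs$morisita, morisita_pairs$group)
    if (length(gg) >= 2L && all(lengths(gg) >= 2L)) {
      kt <- kruskal.test(gg)
      rows[[2]] <- tibble::tibble(comparison = "morisita by cohort pairing",
                                  test = "kruskal_wallis",
                                  statistic = unname(kt$statistic),
                                  p_value = kt$p.value, note = "")
    } else {
      rows[[2]] <- tibble::tibble(comparison = "morisita by cohort pairing",
                                  test = "kruskal_wallis", statistic = NA_real_,
                                  p_value = NA_real_,
                                  note = "skipped: group with fewer than 2 values")
    }
  }
  dplyr::bind_rows(rows)
}
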