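#' @title Reading and writing TCR tables
#' @description
#' Two families of inputs are supported. Single-cell paired alpha/beta tables
#' carry one sorted cell per record with V/(D)/J gene calls, CDR3 nucleotide
#' and amino-acid junctions, productivity flags and sample metadata; they come
#' either as AIRR Rearrangement TSV (one row per chain) or as a wide per-cell
#' TSV. Bulk beta-chain repertoires carry one unique rearrangement per row
#' with a template count, either as AIRR TSV or as an immunoSEQ-style export
#' with a configurable column mapping.
#' @name repertoire_io
NULL

.meta_cols <- c("donor_id", "cohort", "tissue", "inflammation")

.chain_cols <- function(prefix) {
  paste0(prefix, "_", c("v_call", "d_call", "j_call", "cdr3_nt", "cdr3_aa", "productive"))
}

.cell_cols <- c("cell_id", .meta_cols, .chain_cols("alpha")[-2], .chain_cols("beta"))

.as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(trimws(as.character(x))) %in% c("T", "TRUE", "1", "YES")
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(miss, collapse = ", ")),
          class = "maitrep_format_error")
  }
}

.validate_meta <- function(df, what) {
  bad <- function(col, allowed) {
    v <- unique(df[[col]])
    setdiff(v[!is.na(v)], allowed)
  }
  for (spec in list(list("cohort", .cohorts), list("tissue", .tissues),
                    list("inflammation", .inflam))) {
    b <- bad(spec[[1]], spec[[2]])
    if (length(b)) {
      abort(sprintf("%s: invalid %s value(s): %s", what, spec[[1]],
                    paste(b, collapse = ", ")),
            class = "maitrep_format_error")
    }
  }
  mis <- df$tissue == "blood" & df$inflammation != "not_applicable"
  if (any(mis)) {
    warn("blood cells must have inflammation = not_applicable; coerced")
    df$inflammation[mis] <- "not_applicable"
  }
  df
}

# normalize one chain's columns in a wide cell tibble; flags unparseable gene
# calls by forcing productive = FALSE (the chain is kept, per the contract
# that reading never silently drops data)
.clean_chain <- function(cells, prefix) {
  v <- paste0(prefix, "_v_call"); j <- paste0(prefix, "_j_call")
  nt <- paste0(prefix, "_cdr3_nt"); aa <- paste0(prefix, "_cdr3_aa")
  pr <- paste0(prefix, "_productive")
  present <- !is.na(cells[[v]]) & nzchar(cells[[v]])
  cells[[v]][!present] <- NA_character_
  cells[[v]] <- normalize_gene(cells[[v]])
  cells[[j]] <- normalize_gene(cells[[j]])
  cells[[nt]] <- toupper(cells[[nt]])
  cells[[pr]] <- .as_logical_flag(cells[[pr]]) & present
  unparseable <- present & (!is_tr_gene(cells[[v]]) | !is_tr_gene(cells[[j]]))
  if (any(unparseable)) {
    warn(sprintf("%d %s chain(s) with unparseable gene calls kept as nonproductive (cells: %s)",
                 sum(unparseable), prefix,
                 paste(head(cells$cell_id[unparseable], 5), collapse = ", ")))
    cells[[pr]][unparseable] <- FALSE
  }
  if (prefix == "alpha") return(cells)
  d <- paste0(prefix, "_d_call")
  cells[[d]] <- normalize_gene(ifelse(is.na(cells[[d]]), "", cells[[d]]))
  cells[[d]][!present] <- NA_character_   # absent chain: every field NA
  cells
}

.finish_cells <- function(cells, rejected) {
  cells <- .validate_meta(cells, "cell table")
  cells <- .clean_chain(cells, "alpha")
  cells <- .clean_chain(cells, "beta")
  cells <- cells[, .cell_cols]
  cells <- tibble::new_tibble(cells, class = "tcr_cells")
  attr(cells, "rejected") <- rejected
  cells
}

#' Read a single-cell paired TCR table
#'
#' @param path TSV file path.
#' @param dialect `"airr"` for AIRR Rearrangement format (one row per chain,
#'   columns `cell_id`, `locus`, `v_call`, `d_call`, `j_call`, `junction`,
#'   `junction_aa`, `productive`, plus the sample metadata columns
#'   `donor_id`, `cohort`, `tissue`, `inflammation`), or `"study_tsv"` for the
#'   wide one-row-per-cell layout with `alpha_*`/`beta_*` column pairs.
#' @param on_duplicate what to do when a cell has more than one row for the
#'   same locus (a doublet a single-cell sort cannot phase): `"error"` lists
#'   the offending cell ids, `"drop"` removes those cells with a warning and
#'   records them in the `rejected` attribute.
#' @return a `tcr_cells` tibble, one row per cell, with an attribute
#'   `rejected` (tibble of dropped cell ids and reasons) so that
#'   `nrow(result) + nrow(attr(result, "rejected"))` equals the number of
#'   distinct input cell ids.
#' @export
read_cell_table <- function(path, dialect = c("airr", "study_tsv"),
                            on_duplicate = c("error", "drop")) {
  dialect <- match.arg(dialect)
  on_duplicate <- match.arg(on_duplicate)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "maitrep_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  rejected <- tibble::tibble(cell_id = character(), reason = character())
  if (dialect == "study_tsv") {
    .require_cols(df, setdiff(.cell_cols, "alpha_d_call"), "study_tsv table")
    dup <- df$cell_id[duplicated(df$cell_id)]
    if (length(dup)) {
      abort(paste0("duplicate cell_id rows: ", paste(unique(dup), collapse = ", ")),
            class = "maitrep_ambiguity_error")
    }
    return(.finish_cells(df, rejected))
  }
  .require_cols(df, c("cell_id", "locus", "v_call", "j_call", "junction",
                      "junction_aa", "productive", .meta_cols), "AIRR table")
  if (!"d_call" %in% names(df)) df$d_call <- ""
  bad_locus <- setdiff(unique(df$locus), c("TRA", "TRB"))
  if (length(bad_locus)) {
    abort(paste0("unknown locus value(s): ", paste(bad_locus, collapse = ", ")),
          class = "maitrep_format_error")
  }
  stray_d <- df$locus == "TRA" & !is.na(df$d_call) & nzchar(df$d_call)
  if (any(stray_d)) {
    warn(sprintf("d_call on TRA chain(s) ignored (cells: %s)",
                 paste(unique(df$cell_id[stray_d]), collapse = ", ")))
    df$d_call[stray_d] <- ""
  }
  key <- paste(df$cell_id, df$locus)
  dup_ids <- unique(df$cell_id[key %in% key[duplicated(key)]])
  if (length(dup_ids)) {
    if (on_duplicate == "error") {
      abort(paste0("ambiguous duplicate (cell_id, locus) rows for cell(s): ",
                   paste(dup_ids, collapse = ", ")),
            class = "maitrep_ambiguity_error")
    }
    warn(sprintf("dropped %d cell(s) with duplicate chains (likely doublets): %s",
                 length(dup_ids), paste(dup_ids, collapse = ", ")))
    rejected <- tibble::tibble(cell_id = dup_ids, reason = "duplicate_chain")
    df <- df[!df$cell_id %in% dup_ids, , drop = FALSE]
  }
  wide <- function(locus, prefix) {
    sub <- df[df$locus == locus, , drop = FALSE]
    out <- tibble::tibble(cell_id = sub$cell_id)
    out[[paste0(prefix, "_v_call")]] <- sub$v_call
    if (prefix == "beta") out[["beta_d_call"]] <- sub$d_call
    out[[paste0(prefix, "_j_call")]] <- sub$j_call
    out[[paste0(prefix, "_cdr3_nt")]] <- sub$junction
    out[[paste0(prefix, "_cdr3_aa")]] <- sub$junction_aa
    out[[paste0(prefix, "_productive")]] <- sub$productive
    out
  }
  meta <- df[!duplicated(df$cell_id), c("cell_id", .meta_cols)]
  cells <- meta |>
    dplyr::left_join(wide("TRA", "alpha"), by = "cell_id") |>
    dplyr::left_join(wide("TRB", "beta"), by = "cell_id")
  .finish_cells(cells, rejected)
}

#' Write a single-cell paired TCR table
#'
#' @param cells a `tcr_cells` tibble.
#' @param path output TSV path.
#' @param dialect output layout, as in [read_cell_table()].
#' @param force write even when `cells` is empty.
#' @return `path`, invisibly. Reading the file back with the same dialect
#'   reproduces the input field for field.
#' @export
write_cell_table <- function(cells, path, dialect = c("airr", "study_tsv"),
                             force = FALSE) {
  dialect <- match.arg(dialect)
  if (nrow(cells) == 0L && !force) {
    abort("refusing to write an empty cell table (use force = TRUE)",
          class = "maitrep_empty_error")
  }
  if (dialect == "study_tsv") {
    readr::write_tsv(as.data.frame(cells)[, .cell_cols], path, progress = FALSE)
    return(invisible(path))
  }
  has_a <- !is.na(cells$alpha_v_call)
  has_b <- !is.na(cells$beta_v_call)
  if (any(!has_a & !has_b)) {
    abort("cells without any chain cannot be represented in AIRR rows",
          class = "maitrep_format_error")
  }
  row_of <- function(idx, prefix, locus) {
    sub <- cells[idx, , drop = FALSE]
    tibble::tibble(
      cell_id = sub$cell_id, locus = locus,
      v_call = sub[[paste0(prefix, "_v_call")]],
      d_call = if (prefix == "beta") sub$beta_d_call else "",
      j_call = sub[[paste0(prefix, "_j_call")]],
      junction = sub[[paste0(prefix, "_cdr3_nt")]],
      junction_aa = sub[[paste0(prefix, "_cdr3_aa")]],
      productive = ifelse(sub[[paste0(prefix, "_productive")]], "T", "F"),
      donor_id = sub$donor_id, cohort = sub$cohort,
      tissue = sub$tissue, inflammation = sub$inflammation
    )
  }
  out <- dplyr::bind_rows(row_of(which(has_a), "alpha", "TRA"),
                          row_of(which(has_b), "beta", "TRB"))
  # keep the caller's cell order so read(write(x)) reproduces x row for row
  out <- out[order(match(out$cell_id, cells$cell_id), out$locus), ]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Default column mapping for immunoSEQ-style exports
#'
#' Maps the package's field names to the export's column headers. Whether the
#' abundance column holds templates or reads differs between export versions;
#' point `count` at whichever column the file carries.
#' @param cdr3_aa,v_call,j_call,count column names in the file.
#' @return named list used by [read_bulk_repertoire()].
#' @export
immunoseq_columns <- function(cdr3_aa = "amino_acid", v_call = "v_gene",
                              j_call = "j_gene", count = "templates") {
  list(cdr3_aa = cdr3_aa, v_call = v_call, j_call = j_call, count = count)
}

#' Read a bulk beta-chain repertoire
#'
#' Rows with identical `(cdr3_aa, v_call, j_call)` after gene-name
#' normalization are merged with counts summed. Nonproductive rows (a stop
#' `*` or frameshift `_` in the amino-acid junction) are excluded; the number
#' excluded is reported and stored in the `n_excluded` attribute.
#'
#' @param path TSV file path.
#' @param dialect `"airr"` (columns `junction_aa`, `v_call`, `j_call`,
#'   `duplicate_count`, optionally `donor_id`/`cohort`) or `"immunoseq"`.
#' @param donor_id,cohort sample identity; required for `"immunoseq"`, and
#'   used as fallback for `"airr"` files without metadata columns.
#' @param col_map column mapping from [immunoseq_columns()].
#' @return a [repertoire()] object.
#' @export
read_bulk_repertoire <- function(path, dialect = c("airr", "immunoseq"),
                                 donor_id = NULL, cohort = NULL,
                                 col_map = immunoseq_columns()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "maitrep_io_error")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (dialect == "airr") {
    .require_cols(df, c("junction_aa", "v_call", "j_call", "duplicate_count"),
                  "AIRR repertoire")
    clones <- tibble::tibble(cdr3_aa = df$junction_aa, v_call = df$v_call,
                             j_call = df$j_call, count = df$duplicate_count)
    if (is.null(donor_id) && "donor_id" %in% names(df)) donor_id <- df$donor_id[1]
    if (is.null(cohort) && "cohort" %in% names(df)) cohort <- df$cohort[1]
  } else {
    .require_cols(df, unlist(col_map), "immunoSEQ export")
    clones <- tibble::tibble(cdr3_aa = df[[col_map$cdr3_aa]],
                             v_call = df[[col_map$v_call]],
                             j_call = df[[col_map$j_call]],
                             count = df[[col_map$count]])
  }
  if (is.null(donor_id) || is.null(cohort)) {
    abort("donor_id and cohort are required (not present in the file)",
          class = "maitrep_format_error")
  }
  clones$count <- suppressWarnings(as.numeric(clones$count))
  if (any(is.na(clones$count)) || any(clones$count < 1)) {
    abort("template counts must be positive numbers", class = "maitrep_format_error")
  }
  keep <- aa_productive(clones$cdr3_aa)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    inform(sprintf("excluded %d nonproductive rearrangement row(s)", n_excluded))
  }
  clones <- clones[keep, , drop = FALSE]
  if (nrow(clones) == 0L) {
    abort("repertoire is empty after productivity filtering",
          class = "maitrep_empty_error")
  }
  out <- repertoire(donor_id, cohort, clones)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a bulk repertoire
#'
#' @param rep a [repertoire()] object.
#' @param path output TSV path.
#' @param dialect `"airr"` (self-describing, includes donor metadata) or
#'   `"immunoseq"` (column names from `col_map`; donor identity is not part
#'   of that format and must be re-supplied on read).
#' @param col_map column mapping for the immunoseq dialect.
#' @param force write even when the clone table is empty.
#' @return `path`, invisibly.
#' @export
write_bulk_repertoire <- function(rep, path, dialect = c("airr", "immunoseq"),
                                  col_map = immunoseq_columns(), force = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep$clones) == 0L && !force) {
    abort("refusing to write an empty repertoire (use force = TRUE)",
          class = "maitrep_empty_error")
  }
  if (dialect == "airr") {
    out <- tibble::tibble(junction_aa = rep$clones$cdr3_aa,
                          v_call = rep$clones$v_call,
                          j_call = rep$clones$j_call,
                          duplicate_count = rep$clones$count,
                          donor_id = rep$donor_id, cohort = rep$cohort)
  } else {
    out <- setNames(
      tibble::tibble(rep$clones$cdr3_aa, rep$clones$v_call,
                     rep$clones$j_call, rep$clones$count),
      unlist(col_map)[c("cdr3_aa", "v_call", "j_call", "count")]
    )
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write any maitrep collection to a TSV
#'
#' Dispatches to the matching writer so pipeline code can treat cell tables
#' and repertoires uniformly; round-trips with the corresponding reader.
#' @param x a `tcr_cells` tibble, a `tcr_repertoire`, or a plain data frame.
#' @param path output TSV path.
#' @param ... passed to the underlying writer (e.g. `dialect`, `force`).
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @export
write_table.tcr_cells <- function(x, path, ...) write_cell_table(x, path, ...)

#' @export
write_table.tcr_repertoire <- function(x, path, ...) write_bulk_repertoire(x, path, ...)

#' @export
write_table.data.frame <- function(x, path, ..., force = FALSE) {
  if (nrow(x) == 0L && !force) {
    abort("refusing to write an empty table (use force = TRUE)",
          class = "maitrep_empty_error")
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
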