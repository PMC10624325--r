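#' Construct a bulk TCR repertoire
#'
#' A repertoire is the unit on which diversity and overlap statistics are
#' computed: one donor and compartment, with a clone table of unique beta-chain
#' rearrangements and their template counts. Rows with identical
#' `(cdr3_aa, v_call, j_call)` are merged with counts summed.
#'
#' @param donor_id donor identifier.
#' @param cohort `"HC"` or `"CD"`.
#' @param clones a data frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `count` (positive integers). `v_call`/`j_call` may be empty strings when
#'   the upstream export carries none.
#' @param tissue compartment the repertoire was sampled from; bulk data here
#'   is blood.
#' @return an object of class `tcr_repertoire` with elements `donor_id`,
#'   `cohort`, `tissue`, `clones` (tibble) and `total_cells`.
#' @export
repertoire <- function(donor_id, cohort, clones, tissue = "blood") {
  cohort <- match.arg(cohort, .cohorts)
  tissue <- match.arg(tissue, .tissues)
  clones <- tibble::as_tibble(clones)
  need <- c("cdr3_aa", "count")
  if (!all(need %in% names(clones))) {
    abort(paste0("clone table must have columns: ", paste(need, collapse = ", ")),
          class = "maitrep_format_error")
  }
  if (!"v_call" %in% names(clones)) clones$v_call <- ""
  if (!"j_call" %in% names(clones)) clones$j_call <- ""
  if (any(is.na(clones$count)) || any(clones$count < 1)) {
    abort("clone counts must be positive integers", class = "maitrep_format_error")
  }
  if (any(!nzchar(clones$cdr3_aa) | is.na(clones$cdr3_aa))) {
    abort("clone cdr3_aa must be non-empty", class = "maitrep_format_error")
  }
  clones$v_call <- normalize_gene(ifelse(is.na(clones$v_call), "", clones$v_call))
  clones$j_call <- normalize_gene(ifelse(is.na(clones$j_call), "", clones$j_call))
  clones <- clones |>
    dplyr::group_by(.data$cdr3_aa, .data$v_call, .data$j_call) |>
    dplyr::summarise(count = as.integer(sum(.data$count)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$cdr3_aa)
  structure(
    list(donor_id = as.character(donor_id), cohort = cohort, tissue = tissue,
         clones = clones, total_cells = sum(clones$count)),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> donor %s (%s, %s): %d clones, %d cells\n",
              x$donor_id, x$cohort, x$tissue, nrow(x$clones), x$total_cells))
  print(head(x$clones, 5))
  invisible(x)
}

#' Clone counts of a repertoire, or pass numeric counts through
#' @noRd
clone_counts <- function(x) {
  if (inherits(x, "tcr_repertoire")) return(x$clones$count)
  if (is.numeric(x)) return(x)
  abort("expected a tcr_repertoire or a numeric count vector",
        class = "maitrep_type_error")
}

#' Collapse a repertoire to amino-acid beta clonotypes
#'
#' Publicity and colon-blood comparisons match on the CDR3 amino-acid sequence
#' alone; this sums counts over V/J within each `cdr3_aa`.
#' @param rep a `tcr_repertoire`.
#' @return tibble with columns `cdr3_aa`, `count`.
#' @export
beta_aa_clones <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  rep$clones |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}
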