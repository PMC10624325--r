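#' Simpson clonality of a repertoire
#'
#' The probability that two distinct cells drawn without replacement carry
#' the same clonotype: `sum(n_i * (n_i - 1)) / (N * (N - 1))` for clone sizes
#' `n_i` summing to `N`. This unbiased estimator hits both anchor points of
#' the index as used for repertoire data: exactly 1 for a monoclonal
#' repertoire and exactly 0 when every cell has a different sequence (the
#' plug-in `sum(p_i^2)` form does not reach 0).
#'
#' Blood diversity is computed on amino-acid beta clonotypes, the same
#' identity used for publicity comparisons.
#'
#' @param x a [repertoire()] object, or a numeric vector of clone counts.
#' @param level for repertoires, `"aa"` collapses clones to beta CDR3
#'   amino-acid identity first; `"clone"` uses the clone table rows as-is.
#' @return object of class `diversity_result`: list with `simpson`,
#'   `n_cells`, `n_clones`, `clone_counts`.
#' @export
simpson_clonality <- function(x, level = c("aa", "clone")) {
  level <- match.arg(level)
  n_i <- if (inherits(x, "tcr_repertoire") && level == "aa") {
    beta_aa_clones(x)$count
  } else {
    clone_counts(x)
  }
  n_i <- n_i[n_i > 0]
  N <- sum(n_i)
  if (N < 2) {
    abort("Simpson clonality is undefined for fewer than two cells",
          class = "maitrep_data_error")
  }
  structure(
    list(simpson = sum(n_i * (n_i - 1)) / (N * (N - 1)),
         n_cells = as.integer(N), n_clones = length(n_i),
         clone_counts = as.integer(n_i)),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("Simpson clonality %.4f (%d cells, %d clonotypes)\n",
              x$simpson, x$n_cells, x$n_clones))
  invisible(x)
}

#' Morisita overlap between two repertoires
#'
#' Repertoire similarity on beta CDR3 amino-acid clonotypes. The default is
#' the frequency-based Morisita-Horn form: with relative frequencies `p_i`,
#' `q_i` over the union of clonotypes,
#' `2 * sum(p_i * q_i) / (sum(p_i^2) + sum(q_i^2))` — 1 when the two
#' frequency distributions are identical, 0 when the clone sets are disjoint,
#' and invariant to scaling one repertoire's counts. The classical
#' count-based Morisita index (with unbiased within-repertoire Simpson terms
#' in the denominator) is available as `variant = "classical"`.
#'
#' @param rep_a,rep_b [repertoire()] objects.
#' @param variant `"horn"` (default) or `"classical"`.
#' @return a number in `[0, 1]` (the classical variant can slightly exceed 1
#'   on small samples, as is standard for that estimator).
#' @export
morisita_overlap <- function(rep_a, rep_b, variant = c("horn", "classical")) {
  variant <- match.arg(variant)
  a <- beta_aa_clones(rep_a); b <- beta_aa_clones(rep_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("Morisita overlap is undefined for an empty repertoire",
          class = "maitrep_data_error")
  }
  union_seqs <- union(a$cdr3_aa, b$cdr3_aa)
  x <- setNames(rep(0, length(union_seqs)), union_seqs)
  y <- x
  x[a$cdr3_aa] <- a$count
  y[b$cdr3_aa] <- b$count
  X <- sum(x); Y <- sum(y)
  if (variant == "horn") {
    p <- x / X; q <- y / Y
    denom <- sum(p^2) + sum(q^2)
    return(2 * sum(p * q) / denom)
  }
  lx <- sum(x * (x - 1)) / (X * (X - 1))
  ly <- sum(y * (y - 1)) / (Y * (Y - 1))
  if (lx + ly == 0) return(0)
  2 * sum(x * y) / ((lx + ly) * X * Y)
}

#' All pairwise Morisita overlaps across donors
#'
#' Computes the symmetric donor-by-donor overlap matrix (unit diagonal) and
#' groups the off-diagonal pair values by cohort pairing: both healthy
#' controls, both Crohn's, or one of each. With `n` donors there are
#' `choose(n, 2)` pair values and every pair falls in exactly one group.
#'
#' @param reps list of blood [repertoire()] objects (>= 2).
#' @param variant passed to [morisita_overlap()].
#' @return list with `matrix` (named square matrix), `pairs` (tibble:
#'   `donor_a`, `donor_b`, `group`, `morisita`) and `groups` (named list of
#'   numeric vectors `HCvsHC`, `CDvsCD`, `HCvsCD`).
#' @export
overlap_matrix <- function(reps, variant = c("horn", "classical")) {
  variant <- match.arg(variant)
  if (length(reps) < 2L) {
    abort("need at least two repertoires", class = "maitrep_data_error")
  }
  donors <- vapply(reps, `[[`, character(1), "donor_id")
  cohorts <- vapply(reps, `[[`, character(1), "cohort")
  n <- length(reps)
  m <- diag(1, n)
  dimnames(m) <- list(donors, donors)
  idx <- combn(n, 2L)
  vals <- apply(idx, 2L, function(ij) {
    morisita_overlap(reps[[ij[1]]], reps[[ij[2]]], variant = variant)
  })
  m[t(idx)] <- vals
  m[t(idx[2:1, , drop = FALSE])] <- vals
  grp <- apply(idx, 2L, function(ij) {
    co <- sort(cohorts[ij])
    if (identical(co, c("HC", "HC"))) "HCvsHC"
    else if (identical(co, c("CD", "CD"))) "CDvsCD"
    else "HCvsCD"
  })
  pairs <- tibble::tibble(donor_a = donors[idx[1, ]], donor_b = donors[idx[2, ]],
                          group = grp, morisita = vals)
  list(matrix = m, pairs = pairs,
       groups = list(HCvsHC = vals[grp == "HCvsHC"],
                     CDvsCD = vals[grp == "CDvsCD"],
                     HCvsCD = vals[grp == "HCvsCD"]))
}

.expand_motif <- function(motif) {
  # split into tokens: single residues, [A/B] alternatives, or X wildcards
  toks <- regmatches(motif, gregexpr("\\[[A-Z]/[A-Z]\\]|.", motif))[[1]]
  lapply(toks, function(t) {
    if (startsWith(t, "[")) strsplit(gsub("[][]", "", t), "/")[[1]] else t
  })
}

#' Consensus motif of a CDR3 set
#'
#' Restricts to sequences of the modal length, then per position emits the
#' single residue if it occurs in at least `majority` of sequences, else the
#' two most frequent residues bracketed (`[M/R]`) if together they reach
#' `majority`, else `X`. Support is the fraction of modal-length sequences
#' matched by the expanded motif (`X` matches anything).
#'
#' @param cdr3_aa character vector of amino-acid CDR3 sequences.
#' @param majority per-position frequency threshold (default 0.5).
#' @return list with `motif`, `support`, `n_used` (modal-length sequences),
#'   `length`.
#' @export
consensus_motif <- function(cdr3_aa, majority = 0.5) {
  cdr3_aa <- cdr3_aa[!is.na(cdr3_aa) & nzchar(cdr3_aa)]
  if (length(cdr3_aa) == 0L) {
    abort("no sequences for consensus", class = "maitrep_empty_error")
  }
  len_tab <- table(nchar(cdr3_aa))
  modal_len <- as.integer(names(len_tab)[which.max(len_tab)])
  seqs <- cdr3_aa[nchar(cdr3_aa) == modal_len]
  chars <- do.call(rbind, strsplit(seqs, ""))
  motif_toks <- apply(chars, 2L, function(col) {
    f <- sort(table(col), decreasing = TRUE) / length(col)
    if (f[1] >= majority) return(names(f)[1])
    if (length(f) >= 2L && f[1] + f[2] >= majority) {
      return(sprintf("[%s/%s]", names(f)[1], names(f)[2]))
    }
    "X"
  })
  motif <- paste(motif_toks, collapse = "")
  alt <- .expand_motif(motif)
  matches <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    all(mapply(function(c1, allowed) identical(allowed, "X") || c1 %in% allowed,
               ch, alt))
  }, logical(1))
  list(motif = motif, support = mean(matches),
       n_used = length(seqs), length = modal_len)
}

#' Gene segment usage frequencies
#'
#' Fraction of cells (or clonotypes) using each gene of a segment. Colonic
#' usage is taken over canonical cells; blood repertoires report beta-chain
#' V/J usage weighted by template counts.
#'
#' @param x a `tcr_cells` tibble or a [repertoire()] object.
#' @param segment one of `"TRAJ"`, `"TRAV"`, `"TRBV"`, `"TRBD"`, `"TRBJ"`.
#' @param by for cell tables: `"cell"` (default) counts every cell,
#'   `"clonotype"` counts each distinct donor-scoped paired clonotype once.
#' @return tibble with columns `gene`, `n`, `fraction` (fractions sum to 1).
#' @export
gene_usage <- function(x, segment = c("TRAJ", "TRAV", "TRBV", "TRBD", "TRBJ"),
                       by = c("cell", "clonotype")) {
  segment <- match.arg(segment)
  by <- match.arg(by)
  if (inherits(x, "tcr_repertoire")) {
    col <- switch(segment, TRBV = "v_call", TRBJ = "j_call",
                  abort("bulk repertoires carry beta V/J calls only",
                        class = "maitrep_data_error"))
    genes <- rep(x$clones[[col]], x$clones$count)
  } else {
    if (by == "clonotype") {
      ct <- build_clonotypes(x)
      x <- x[match(vapply(ct$cell_ids, `[`, character(1), 1), x$cell_id), ]
    }
    col <- switch(segment, TRAJ = "alpha_j_call", TRAV = "alpha_v_call",
                  TRBV = "beta_v_call", TRBD = "beta_d_call",
                  TRBJ = "beta_j_call")
    genes <- x[[col]]
  }
  genes <- genes[!is.na(genes) & nzchar(genes)]
  if (length(genes) == 0L) {
    abort("no gene calls after filtering", class = "maitrep_empty_error")
  }
  tab <- sort(table(genes), decreasing = TRUE)
  tibble::tibble(gene = names(tab), n = as.integer(tab),
                 fraction = as.numeric(tab) / sum(tab))
}
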