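#' Normalize IMGT receptor-gene names
#'
#' Upper-cases a gene call, strips any allele designation (`"*01"`), and
#' removes zero-padding from group/family numbers so that spelling variants of
#' the same gene segment compare equal (`"trav1-02"`, `"TRAV1-2*01"` and
#' `"TRAV1-2"` all normalize to `"TRAV1-2"`). Gene-level resolution is all the
#' downstream analysis uses: usage tables and clonotype keys are defined on
#' genes, not alleles.
#'
#' The transformation is idempotent: `normalize_gene(normalize_gene(x))`
#' equals `normalize_gene(x)`.
#'
#' @param x character vector of gene calls; `NA` and `""` pass through.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_gene(c("trav1-02", "TRBV6-4*01", "TRAJ33"))
normalize_gene <- function(x) {
  out <- toupper(trimws(as.character(x)))
  out <- sub("\\*.*$", "", out)                  # drop allele suffix
  out <- gsub("(?<=[V-])0+(?=[0-9])", "", out, perl = TRUE)  # TRAV1-02 -> TRAV1-2
  out <- sub("^TR([AB])([VDJ])0+([0-9])", "TR\\1\\2\\3", out)
  out[is.na(x)] <- NA_character_
  out
}

#' Test whether a gene call is a parseable TR locus segment
#' @noRd
is_tr_gene <- function(x) {
  !is.na(x) & grepl("^TR[AB][VDJ][0-9]", x)
}

# codon -> amino acid lookup, from the standard genetic code
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Translate CDR3 nucleotide sequences
#'
#' In-frame sequences are translated with the standard genetic code; stop
#' codons appear as `*`. Sequences whose length is not a multiple of three are
#' flagged out-of-frame: the readable codons are translated and a `_` appended,
#' the convention IMGT-style junction tables use for frameshifts.
#'
#' @param nt character vector of nucleotide sequences over `A,C,G,T,N`.
#' @return character vector of amino-acid strings (`X` for codons with `N`).
#' @export
translate_cdr3 <- function(nt) {
  tab <- .codon_table()
  vapply(nt, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s <- toupper(s)
    n_codon <- nchar(s) %/% 3
    if (n_codon == 0L) return("_")
    codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
    aa <- tab[codons]
    aa[is.na(aa)] <- "X"
    out <- paste(aa, collapse = "")
    if (nchar(s) %% 3 != 0L) out <- paste0(out, "_")
    out
  }, character(1), USE.NAMES = FALSE)
}

# amino acid -> representative codons (for back-generation in the simulator)
.aa_codons <- function() {
  tab <- .codon_table()
  split(names(tab), tab)
}

#' Is an amino-acid junction productive-looking (no stop, no frameshift mark)?
#' @noRd
aa_productive <- function(aa) {
  !is.na(aa) & nzchar(aa) & !grepl("[*_]", aa)
}
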