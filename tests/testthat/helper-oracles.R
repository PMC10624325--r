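# Independent oracles and small generators shared across test files.
# The oracles deliberately avoid the package's own code paths.

# Simpson clonality by exhaustive enumeration of unordered cell pairs:
# expand clone counts to one label per cell and count same-clone pairs.
simpson_bruteforce <- function(counts) {
  labels <- rep(seq_along(counts), counts)
  n <- length(labels)
  stopifnot(n >= 2)
  same <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + 1L
      if (labels[i] == labels[j]) same <- same + 1L
    }
  }
  same / total
}

# Morisita-Horn by naive loop over the union of clone labels.
morisita_bruteforce <- function(x, y) {
  labs <- union(names(x), names(y))
  px <- qy <- numeric(length(labs))
  for (k in seq_along(labs)) {
    px[k] <- if (labs[k] %in% names(x)) x[[labs[k]]] else 0
    qy[k] <- if (labs[k] %in% names(y)) y[[labs[k]]] else 0
  }
  px <- px / sum(px)
  qy <- qy / sum(qy)
  num <- 0
  for (k in seq_along(labs)) num <- num + px[k] * qy[k]
  2 * num / (sum(px^2) + sum(qy^2))
}

# random repertoire with <= max_clones clones over a shared label alphabet so
# that pairs of repertoires can overlap
random_repertoire <- function(donor, cohort, max_clones = 50, alphabet_size = 80) {
  n_clones <- sample(2:max_clones, 1)
  labs <- sample(sprintf("CASS%04dF", seq_len(alphabet_size)), n_clones)
  repertoire(donor, cohort, tibble::tibble(
    cdr3_aa = labs, v_call = "TRBV6-4", j_call = "TRBJ2-1",
    count = sample(1:20, n_clones, replace = TRUE)))
}

# exact (Clopper-Pearson) binomial interval
binom_ci99 <- function(x, n) {
  as.numeric(stats::binom.test(x, n, conf.level = 0.99)$conf.int)
}

# small, fast simulator configuration for property loops
small_config <- function(seed, public_pool_size = 8L, ...) {
  sim_config(n_hc_donors = 3L, n_cd_donors = 3L, n_blood_per_cohort = 2L,
             blood_cells_per_donor = 120L, colon_cells_per_biopsy = 30L,
             public_pool_size = public_pool_size, seed = seed, ...)
}

# one-row cell table builder for filter-rule tests
one_cell <- function(alpha_v = "TRAV1-2", alpha_j = "TRAJ33",
                     alpha_prod = TRUE, alpha_present = TRUE,
                     beta_present = TRUE, beta_prod = TRUE,
                     donor = "D1", cohort = "HC", tissue = "colon",
                     inflammation = "uninflamed", cell_id = "x1",
                     alpha_nt = "TGTGCAGTAATGGATAGCAACTATCAGTTAATTTGG",
                     beta_nt = "TGTGCAAGCAGCTTAGCACCAGGAGAGCAGTTCTTT") {
  tb <- tibble::tibble(
    cell_id = cell_id, donor_id = donor, cohort = cohort, tissue = tissue,
    inflammation = inflammation,
    alpha_v_call = if (alpha_present) alpha_v else NA_character_,
    alpha_j_call = if (alpha_present) alpha_j else NA_character_,
    alpha_cdr3_nt = if (alpha_present) alpha_nt else NA_character_,
    alpha_cdr3_aa = if (alpha_present) "CAVMDSNYQLIW" else NA_character_,
    alpha_productive = alpha_present && alpha_prod,
    beta_v_call = if (beta_present) "TRBV6-4" else NA_character_,
    beta_d_call = if (beta_present) "TRBD1" else NA_character_,
    beta_j_call = if (beta_present) "TRBJ2-1" else NA_character_,
    beta_cdr3_nt = if (beta_present) beta_nt else NA_character_,
    beta_cdr3_aa = if (beta_present) "CASSLAPGEQFF" else NA_character_,
    beta_productive = beta_present && beta_prod)
  tibble::new_tibble(as.data.frame(tb), class = "tcr_cells")
}
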