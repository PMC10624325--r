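#' Configuration for a synthetic MAIT cohort
#'
#' Defaults mirror the study design the analysis targets: ten donors per
#' cohort with colon biopsies (Crohn's donors contribute paired inflamed and
#' uninflamed biopsies, healthy controls one), the first eight donors of each
#' cohort also contributing a bulk blood beta-chain repertoire; up to 80
#' sorted cells per biopsy; blood sorts of tens of thousands of cells
#' represented at 1:100 scale (500 cells) for desk-scale runtimes; slightly
#' under half of sorted colonic cells carrying a canonical MAIT alpha
#' rearrangement, with TRAJ33 predominating and TRBV6-4 plus TRBV20-1
#' covering a small majority of beta chains.
#'
#' @param n_hc_donors,n_cd_donors donors per cohort with colon biopsies.
#' @param n_blood_per_cohort leading donors per cohort that also have blood.
#' @param blood_cells_per_donor cells per blood repertoire.
#' @param colon_cells_per_biopsy sorted cells per biopsy (at most 80).
#' @param canonical_alpha_fraction per-cell probability of a canonical MAIT
#'   rearrangement.
#' @param traj_weights named weights over TRAJ12/TRAJ20/TRAJ33 (sum to 1),
#'   drawn once per colonic clonotype.
#' @param trbv_weights named weights over beta V genes (sum to 1).
#' @param clone_size_law `"geometric"` (default) or `"zipf"` clone-size
#'   distribution.
#' @param blood_clone_size_param,colon_clone_size_param success probability
#'   of the geometric law (sizes are `1 + Geom(p)`), or the exponent when
#'   `clone_size_law = "zipf"`.
#' @param public_pool_size number of public beta sequences injected across
#'   blood repertoires.
#' @param publicity_rates named fractions (`cd_only`, `hc_only`, `shared`,
#'   sum to 1) of the public pool carried only by Crohn's donors, only by
#'   healthy controls, or by one of each.
#' @param colon_blood_autologous_rate probability that a canonical colonic
#'   beta sequence is injected into the same donor's blood.
#' @param colon_blood_allogeneic_rate probability that it is injected into
#'   one other random donor's blood.
#' @param cross_inflammation_sharing_rate probability that an uninflamed-
#'   biopsy clonotype of a Crohn's donor also seeds the inflamed biopsy.
#' @param contaminant_mix named fractions over the non-canonical cell
#'   reasons (`wrong_trav`, `wrong_traj`, `nonproductive_alpha`,
#'   `missing_alpha`, `missing_beta`; sum to 1).
#' @param seed master seed; per-donor substreams are derived from it so a
#'   donor's draws do not depend on how many other donors exist.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_hc_donors = 10L, n_cd_donors = 10L,
                       n_blood_per_cohort = 8L,
                       blood_cells_per_donor = 500L,
                       colon_cells_per_biopsy = 80L,
                       canonical_alpha_fraction = 0.45,
                       traj_weights = c(TRAJ12 = 0.10, TRAJ20 = 0.10, TRAJ33 = 0.80),
                       trbv_weights = c("TRBV6-4" = 0.30, "TRBV20-1" = 0.25,
                                        "TRBV4-2" = 0.15, "TRBV28" = 0.15,
                                        "TRBV19" = 0.15),
                       clone_size_law = c("geometric", "zipf"),
                       blood_clone_size_param = 0.5,
                       colon_clone_size_param = 0.6,
                       public_pool_size = 40L,
                       publicity_rates = c(cd_only = 0.24, hc_only = 0.09,
                                           shared = 0.67),
                       colon_blood_autologous_rate = 0.48,
                       colon_blood_allogeneic_rate = 0.13,
                       cross_inflammation_sharing_rate = 0.15,
                       contaminant_mix = c(wrong_trav = 0.50, wrong_traj = 0.15,
                                           nonproductive_alpha = 0.15,
                                           missing_alpha = 0.05,
                                           missing_beta = 0.15),
                       seed = 1L) {
  clone_size_law <- match.arg(clone_size_law)
  cfg <- list(n_hc_donors = as.integer(n_hc_donors),
              n_cd_donors = as.integer(n_cd_donors),
              n_blood_per_cohort = as.integer(n_blood_per_cohort),
              blood_cells_per_donor = as.integer(blood_cells_per_donor),
              colon_cells_per_biopsy = as.integer(colon_cells_per_biopsy),
              canonical_alpha_fraction = canonical_alpha_fraction,
              traj_weights = traj_weights, trbv_weights = trbv_weights,
              clone_size_law = clone_size_law,
              blood_clone_size_param = blood_clone_size_param,
              colon_clone_size_param = colon_clone_size_param,
              public_pool_size = as.integer(public_pool_size),
              publicity_rates = publicity_rates,
              colon_blood_autologous_rate = colon_blood_autologous_rate,
              colon_blood_allogeneic_rate = colon_blood_allogeneic_rate,
              cross_inflammation_sharing_rate = cross_inflammation_sharing_rate,
              contaminant_mix = contaminant_mix,
              seed = as.integer(seed))
  cfg_err <- function(msg) abort(msg, class = "maitrep_config_error")
  probs <- c(cfg$canonical_alpha_fraction, cfg$colon_blood_autologous_rate,
             cfg$colon_blood_allogeneic_rate, cfg$cross_inflammation_sharing_rate)
  if (any(probs < 0 | probs > 1)) cfg_err("probabilities must lie in [0, 1]")
  for (w in list(traj_weights, trbv_weights, publicity_rates, contaminant_mix)) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      cfg_err("weight vectors must be nonnegative and sum to 1")
    }
  }
  if (!setequal(names(traj_weights), .mait_traj)) {
    cfg_err("traj_weights must be named TRAJ12/TRAJ20/TRAJ33")
  }
  if (cfg$colon_cells_per_biopsy > 80L || cfg$colon_cells_per_biopsy < 1L) {
    cfg_err("colon_cells_per_biopsy must be between 1 and 80")
  }
  if (cfg$n_blood_per_cohort > min(cfg$n_hc_donors, cfg$n_cd_donors)) {
    cfg_err("n_blood_per_cohort cannot exceed the donors per cohort")
  }
  if (cfg$clone_size_law == "geometric" &&
      (cfg$blood_clone_size_param <= 0 || cfg$blood_clone_size_param > 1 ||
       cfg$colon_clone_size_param <= 0 || cfg$colon_clone_size_param > 1)) {
    cfg_err("geometric clone-size parameters must lie in (0, 1]")
  }
  if (cfg$public_pool_size * 2L >
      cfg$n_blood_per_cohort * 2L * cfg$blood_cells_per_donor) {
    cfg_err("public_pool_size is infeasible for the blood repertoire sizes")
  }
  structure(cfg, class = "sim_config")
}

# deterministic substream: donor k's draws never depend on other donors
.substream <- function(seed, k) {
  set.seed(((abs(seed) %% 1000003L) * 2039L + k) %% 2147483647L)
}

.aa_core_alphabet <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             c("C", "W", "F"))

# random CDR3beta amino-acid sequences: C + core of >= 8 residues + F/W
.rand_cdr3b <- function(n) {
  lens <- sample(10:18, n, replace = TRUE)
  vapply(lens, function(L) {
    paste0("C", paste(sample(.aa_core_alphabet, L - 2L, replace = TRUE),
                      collapse = ""),
           sample(c("F", "W"), 1L))
  }, character(1))
}

# draw n unique sequences (dedupe within the calling stream)
.rand_cdr3b_unique <- function(n) {
  out <- unique(.rand_cdr3b(ceiling(n * 1.2) + 5L))
  while (length(out) < n) out <- unique(c(out, .rand_cdr3b(n)))
  out[seq_len(n)]
}

# canonical MAIT alpha CDR3: consensus CAVMDSNYQLIW with an M/R dimorphism at
# position 4 and sparse substitutions elsewhere
.rand_cdr3a <- function(n, mut_rate = 0.02) {
  base <- strsplit("CAVMDSNYQLIW", "")[[1]]
  vapply(seq_len(n), function(i) {
    s <- base
    s[4] <- sample(c("M", "R", "V"), 1L, prob = c(0.48, 0.47, 0.05))
    for (p in 5:11) {
      if (runif(1) < mut_rate) s[p] <- sample(.aa_core_alphabet, 1L)
    }
    paste(s, collapse = "")
  }, character(1))
}

# back-generate a nucleotide junction consistent with its translation
.back_translate <- function(aa_vec) {
  cod <- .aa_codons()
  vapply(aa_vec, function(aa) {
    ch <- strsplit(aa, "")[[1]]
    paste(vapply(ch, function(a) {
      opts <- cod[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# clone sizes summing exactly to n_cells
.clone_sizes <- function(n_cells, law, param) {
  if (n_cells == 0L) return(integer(0))
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    draw <- if (law == "geometric") {
      1L + rgeom(n_cells, param)
    } else {
      k <- 1:30
      sample(k, n_cells, replace = TRUE, prob = k^(-param))
    }
    sizes <- c(sizes, draw)
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n_cells)
  sizes[sizes > 0]
}

.trbj_genes <- c("TRBJ1-1", "TRBJ1-2", "TRBJ2-1", "TRBJ2-3", "TRBJ2-7")
.trbd_genes <- c("TRBD1", "TRBD2")
.contam_trav <- c("TRAV8-2", "TRAV12-1", "TRAV13-1", "TRAV21", "TRAV29")
.contam_traj <- c("TRAJ9", "TRAJ42", "TRAJ49")

# place a sequence into a donor's blood clone table: replace an untouched
# singleton when one exists, otherwise append a count-1 clone
.inject_blood <- function(clones, seq) {
  free <- which(clones$count == 1L & !clones$locked)
  if (length(free)) {
    i <- free[1]
    clones$cdr3_aa[i] <- seq
    clones$locked[i] <- TRUE
  } else {
    clones <- dplyr::bind_rows(clones, tibble::tibble(
      cdr3_aa = seq, v_call = clones$v_call[1], j_call = clones$j_call[1],
      count = 1L, locked = TRUE))
  }
  clones
}

.empty_cells <- function() {
  tibble::tibble(cell_id = character(), donor_id = character(),
                 cohort = character(), tissue = character(),
                 inflammation = character(),
                 alpha_v_call = character(), alpha_j_call = character(),
                 alpha_cdr3_nt = character(), alpha_cdr3_aa = character(),
                 alpha_productive = logical(),
                 beta_v_call = character(), beta_d_call = character(),
                 beta_j_call = character(), beta_cdr3_nt = character(),
                 beta_cdr3_aa = character(), beta_productive = logical())
}

# build one biopsy: canonical clonotypes plus contaminants; returns cells and
# the canonical clonotype table used for cross-biopsy injection
.sim_biopsy <- function(cfg, donor, cohort, inflammation, biopsy_code,
                        beta_pool) {
  n <- cfg$colon_cells_per_biopsy
  canon <- rbinom(n, 1L, cfg$canonical_alpha_fraction) == 1L
  n_canon <- sum(canon)
  sizes <- .clone_sizes(n_canon, cfg$clone_size_law, cfg$colon_clone_size_param)
  n_ct <- length(sizes)
  ct <- tibble::tibble(
    alpha_v_call = rep(.mait_trav, n_ct),
    alpha_j_call = sample(names(cfg$traj_weights), n_ct, replace = TRUE,
                          prob = cfg$traj_weights),
    alpha_cdr3_aa = .rand_cdr3a(n_ct),
    beta_v_call = sample(names(cfg$trbv_weights), n_ct, replace = TRUE,
                         prob = cfg$trbv_weights),
    beta_d_call = sample(.trbd_genes, n_ct, replace = TRUE),
    beta_j_call = sample(.trbj_genes, n_ct, replace = TRUE),
    beta_cdr3_aa = beta_pool$take(n_ct),
    size = sizes
  )
  ct$alpha_cdr3_nt <- .back_translate(ct$alpha_cdr3_aa)
  ct$beta_cdr3_nt <- .back_translate(ct$beta_cdr3_aa)

  n_cont <- n - n_canon
  reasons <- if (n_cont > 0) {
    sample(names(cfg$contaminant_mix), n_cont, replace = TRUE,
           prob = cfg$contaminant_mix)
  } else character(0)

  cells <- .empty_cells()
  mk_cell <- function(id, a_v, a_j, a_aa, a_prod, b_v, b_d, b_j, b_aa, b_prod,
                      a_nt = NULL, b_nt = NULL) {
    # nt junctions are fixed per clonotype by the caller; contaminants get a
    # fresh back-translation here
    if (is.null(a_nt)) {
      a_nt <- if (!is.na(a_aa)) .back_translate(a_aa) else NA_character_
    }
    if (is.null(b_nt)) {
      b_nt <- if (!is.na(b_aa)) .back_translate(b_aa) else NA_character_
    }
    tibble::tibble(cell_id = id, donor_id = donor, cohort = cohort,
                   tissue = "colon", inflammation = inflammation,
                   alpha_v_call = a_v, alpha_j_call = a_j,
                   alpha_cdr3_nt = a_nt, alpha_cdr3_aa = a_aa,
                   alpha_productive = a_prod,
                   beta_v_call = b_v, beta_d_call = b_d, beta_j_call = b_j,
                   beta_cdr3_nt = b_nt, beta_cdr3_aa = b_aa,
                   beta_productive = b_prod)
  }
  cell_no <- 0L
  next_id <- function() {
    cell_no <<- cell_no + 1L
    sprintf("%s_%s_c%03d", donor, biopsy_code, cell_no)
  }
  canon_rows <- lapply(seq_len(n_ct), function(i) {
    dplyr::bind_rows(lapply(seq_len(ct$size[i]), function(j) {
      mk_cell(next_id(), ct$alpha_v_call[i], ct$alpha_j_call[i],
              ct$alpha_cdr3_aa[i], TRUE, ct$beta_v_call[i], ct$beta_d_call[i],
              ct$beta_j_call[i], ct$beta_cdr3_aa[i], TRUE,
              a_nt = ct$alpha_cdr3_nt[i], b_nt = ct$beta_cdr3_nt[i])
    }))
  })
  # the assigned clonotype row index lets the caller rewrite whole clonotypes
  canon_cells <- if (n_ct > 0L) dplyr::bind_rows(canon_rows) else .empty_cells()
  canon_cells$ct_index <- if (n_ct > 0L) rep(seq_len(n_ct), ct$size) else integer(0)

  cont_cells <- dplyr::bind_rows(lapply(reasons, function(r) {
    b_aa <- beta_pool$take(1L)
    b_v <- sample(names(cfg$trbv_weights), 1L, prob = cfg$trbv_weights)
    b_d <- sample(.trbd_genes, 1L); b_j <- sample(.trbj_genes, 1L)
    switch(r,
      wrong_trav = mk_cell(next_id(), sample(.contam_trav, 1L),
                           sample(c(.mait_traj, .contam_traj), 1L),
                           .rand_cdr3b(1L), TRUE, b_v, b_d, b_j, b_aa, TRUE),
      wrong_traj = mk_cell(next_id(), .mait_trav, sample(.contam_traj, 1L),
                           .rand_cdr3a(1L), TRUE, b_v, b_d, b_j, b_aa, TRUE),
      nonproductive_alpha = {
        aa <- sub("Q", "*", .rand_cdr3a(1L))  # premature stop in the junction
        mk_cell(next_id(), .mait_trav, sample(names(cfg$traj_weights), 1L,
                                              prob = cfg$traj_weights),
                aa, FALSE, b_v, b_d, b_j, b_aa, TRUE)
      },
      missing_alpha = mk_cell(next_id(), NA_character_, NA_character_,
                              NA_character_, FALSE, b_v, b_d, b_j, b_aa, TRUE),
      missing_beta = mk_cell(next_id(), .mait_trav,
                             sample(names(cfg$traj_weights), 1L,
                                    prob = cfg$traj_weights),
                             .rand_cdr3a(1L), TRUE, NA_character_,
                             NA_character_, NA_character_, NA_character_, FALSE)
    )
  }))
  if (nrow(cont_cells)) cont_cells$ct_index <- NA_integer_

  list(cells = dplyr::bind_rows(canon_cells, cont_cells), clonotypes = ct)
}

# stateful unique-sequence dispenser for one donor's colon draws
.seq_pool <- function() {
  seen <- character(0)
  list(take = function(n) {
    out <- character(0)
    while (length(out) < n) {
      cand <- setdiff(unique(.rand_cdr3b(n + 4L)), c(seen, out))
      out <- c(out, cand)
    }
    out <- out[seq_len(n)]
    seen <<- c(seen, out)
    out
  })
}

#' Simulate a seeded cohort with ground truth
#'
#' Generates colon single-cell tables and blood bulk repertoires with the
#' statistical structure the downstream analysis assumes, and records every
#' injected sharing event so recovery can be checked exactly: a pool of
#' public blood sequences with chosen carrier pairs, colonic beta sequences
#' injected into autologous and/or allogeneic blood, and uninflamed-biopsy
#' clonotypes reseeded into the paired inflamed biopsy of Crohn's donors.
#'
#' Background sequences are deduplicated within each donor's substream;
#' accidental cross-donor collisions (astronomically rare with cores of 8+
#' random residues) are detected after assembly and reported with a warning.
#'
#' @param config a [sim_config()].
#' @return list with `cells` (a `tcr_cells` tibble), `blood` (list of
#'   [repertoire()]), and `truth` (injected sharing records plus the expected
#'   public-partition counts implied by them).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  hc_donors <- sprintf("HC%02d", seq_len(cfg$n_hc_donors))
  cd_donors <- sprintf("CD%02d", seq_len(cfg$n_cd_donors))
  blood_donors <- c(hc_donors[seq_len(cfg$n_blood_per_cohort)],
                    cd_donors[seq_len(cfg$n_blood_per_cohort)])
  cohort_of <- function(d) ifelse(startsWith(d, "HC"), "HC", "CD")

  ## blood backgrounds (substreams 1..n_blood)
  blood_clones <- list()
  for (k in seq_along(blood_donors)) {
    d <- blood_donors[k]
    .substream(cfg$seed, k)
    sizes <- .clone_sizes(cfg$blood_cells_per_donor, cfg$clone_size_law,
                          cfg$blood_clone_size_param)
    blood_clones[[d]] <- tibble::tibble(
      cdr3_aa = .rand_cdr3b_unique(length(sizes)),
      v_call = sample(names(cfg$trbv_weights), length(sizes), replace = TRUE,
                      prob = cfg$trbv_weights),
      j_call = sample(.trbj_genes, length(sizes), replace = TRUE),
      count = as.integer(sizes), locked = FALSE)
  }

  ## public pool injection (substream 500)
  .substream(cfg$seed, 500L)
  n_pub <- cfg$public_pool_size
  n_cd <- as.integer(round(n_pub * cfg$publicity_rates[["cd_only"]]))
  n_hc <- as.integer(round(n_pub * cfg$publicity_rates[["hc_only"]]))
  n_sh <- n_pub - n_cd - n_hc
  pub_class <- c(rep("cd_only", n_cd), rep("hc_only", n_hc), rep("shared", n_sh))
  pub_seqs <- .rand_cdr3b_unique(n_pub)
  hc_blood <- blood_donors[cohort_of(blood_donors) == "HC"]
  cd_blood <- blood_donors[cohort_of(blood_donors) == "CD"]
  pub_carriers <- lapply(pub_class, function(cl) {
    switch(cl,
           cd_only = sample(cd_blood, 2L),
           hc_only = sample(hc_blood, 2L),
           shared = c(sample(cd_blood, 1L), sample(hc_blood, 1L)))
  })
  for (i in seq_len(n_pub)) {
    for (d in pub_carriers[[i]]) {
      blood_clones[[d]] <- .inject_blood(blood_clones[[d]], pub_seqs[i])
    }
  }
  truth_public <- tibble::tibble(cdr3_aa = pub_seqs, class = pub_class,
                                 donors = pub_carriers)

  ## colon biopsies (substreams 1000 + donor index)
  all_donors <- c(hc_donors, cd_donors)
  cells_list <- list()
  cross_truth <- list()
  donor_canon_ct <- list()
  for (k in seq_along(all_donors)) {
    d <- all_donors[k]
    co <- cohort_of(d)
    .substream(cfg$seed, 1000L + k)
    pool <- .seq_pool()
    if (co == "HC") {
      bx <- .sim_biopsy(cfg, d, co, "uninflamed", "NC", pool)
      cells_list[[d]] <- bx$cells
      donor_canon_ct[[d]] <- bx$clonotypes
    } else {
      nc <- .sim_biopsy(cfg, d, co, "uninflamed", "NC", pool)
      ic <- .sim_biopsy(cfg, d, co, "inflamed", "IC", pool)
      ## cross-inflammation reseeding: copy selected NC clonotypes over IC ones
      n_nc <- nrow(nc$clonotypes)
      n_ic <- nrow(ic$clonotypes)
      pick <- which(rbinom(n_nc, 1L, cfg$cross_inflammation_sharing_rate) == 1L)
      pick <- head(pick, n_ic)
      chain_cols <- c("alpha_v_call", "alpha_j_call", "alpha_cdr3_nt",
                      "alpha_cdr3_aa", "beta_v_call", "beta_d_call",
                      "beta_j_call", "beta_cdr3_nt", "beta_cdr3_aa")
      for (m in seq_along(pick)) {
        src <- nc$clonotypes[pick[m], ]
        tgt_rows <- which(ic$cells$ct_index == m)  # replace the m-th IC clonotype
        for (cl in chain_cols) {
          ic$cells[[cl]][tgt_rows] <- src[[cl]]
        }
        ic$clonotypes[m, chain_cols] <- src[, chain_cols]
      }
      if (length(pick)) {
        cross_truth[[d]] <- tibble::tibble(
          donor_id = d,
          alpha_cdr3_nt = nc$clonotypes$alpha_cdr3_nt[pick],
          beta_cdr3_nt = nc$clonotypes$beta_cdr3_nt[pick],
          beta_cdr3_aa = nc$clonotypes$beta_cdr3_aa[pick])
      }
      cells_list[[d]] <- dplyr::bind_rows(nc$cells, ic$cells)
      donor_canon_ct[[d]] <- dplyr::bind_rows(nc$clonotypes, ic$clonotypes)
    }
  }

  ## colon -> blood injections (substreams 2000 + donor index)
  auto_truth <- list()
  allo_truth <- list()
  for (k in seq_along(all_donors)) {
    d <- all_donors[k]
    if (!d %in% blood_donors) next
    .substream(cfg$seed, 2000L + k)
    dc <- cells_list[[d]]
    canon <- dc[!is.na(dc$ct_index), , drop = FALSE]
    seqs <- unique(canon$beta_cdr3_aa)
    for (s in seqs) {
      if (runif(1) < cfg$colon_blood_autologous_rate) {
        blood_clones[[d]] <- .inject_blood(blood_clones[[d]], s)
        auto_truth[[length(auto_truth) + 1L]] <-
          tibble::tibble(donor_id = d, cdr3_aa = s)
      }
      if (runif(1) < cfg$colon_blood_allogeneic_rate) {
        tgt <- sample(setdiff(blood_donors, d), 1L)
        blood_clones[[tgt]] <- .inject_blood(blood_clones[[tgt]], s)
        allo_truth[[length(allo_truth) + 1L]] <-
          tibble::tibble(colon_donor = d, blood_donor = tgt, cdr3_aa = s)
      }
    }
  }
  auto_truth <- dplyr::bind_rows(auto_truth)
  allo_truth <- dplyr::bind_rows(allo_truth)
  if (nrow(auto_truth) == 0L) {
    auto_truth <- tibble::tibble(donor_id = character(), cdr3_aa = character())
  }
  if (nrow(allo_truth) == 0L) {
    allo_truth <- tibble::tibble(colon_donor = character(),
                                 blood_donor = character(),
                                 cdr3_aa = character())
  }

  ## expected public partition implied by the injections alone: the injected
  ## pool (two carriers each) plus colonic sequences that reached two blood
  ## repertoires via a joint autologous + allogeneic injection
  joint <- dplyr::inner_join(auto_truth,
                             allo_truth |>
                               dplyr::rename(donor_id = "colon_donor"),
                             by = c("donor_id", "cdr3_aa"))
  joint_class <- if (nrow(joint)) {
    ifelse(cohort_of(joint$donor_id) != cohort_of(joint$blood_donor), "shared",
           ifelse(cohort_of(joint$donor_id) == "CD", "cd_only", "hc_only"))
  } else character(0)
  expected_public <- list(
    n_public = n_pub + nrow(joint),
    n_cd_only = n_cd + sum(joint_class == "cd_only"),
    n_hc_only = n_hc + sum(joint_class == "hc_only"),
    n_shared = n_sh + sum(joint_class == "shared"))
  expected_public <- lapply(expected_public, as.integer)

  cells <- dplyr::bind_rows(cells_list)
  cells$ct_index <- NULL
  cells <- tibble::new_tibble(as.data.frame(cells), class = "tcr_cells")

  blood <- lapply(blood_donors, function(d) {
    cl <- blood_clones[[d]]
    cl$locked <- NULL
    repertoire(d, cohort_of(d), cl)
  })
  names(blood) <- blood_donors

  ## collision audit: background sequences are unique per donor by
  ## construction; any cross-donor duplicate not explained by an injection is
  ## an accidental collision and gets reported
  injected <- unique(c(pub_seqs, auto_truth$cdr3_aa, allo_truth$cdr3_aa))
  seq_tab <- dplyr::bind_rows(lapply(blood, function(r) {
    tibble::tibble(cdr3_aa = unique(r$clones$cdr3_aa), donor = r$donor_id)
  }))
  multi <- seq_tab |>
    dplyr::count(.data$cdr3_aa) |>
    dplyr::filter(.data$n >= 2L, !.data$cdr3_aa %in% injected)
  colon_seqs <- unique(cells$beta_cdr3_aa[!is.na(cells$beta_cdr3_aa)])
  stray_blood <- setdiff(intersect(colon_seqs, seq_tab$cdr3_aa), injected)
  collisions <- unique(c(multi$cdr3_aa, stray_blood))
  if (length(collisions)) {
    warn(sprintf("accidental CDR3 collision(s) between independent pools: %s",
                 paste(collisions, collapse = ", ")))
  }

  truth <- list(
    public = truth_public,
    expected_public = expected_public,
    colon_blood_autologous = auto_truth,
    colon_blood_allogeneic = allo_truth,
    cross_inflammation = if (length(cross_truth)) {
      dplyr::bind_rows(cross_truth)
    } else {
      tibble::tibble(donor_id = character(), alpha_cdr3_nt = character(),
                     beta_cdr3_nt = character(), beta_cdr3_aa = character())
    },
    donor_clonotypes = donor_canon_ct,
    collisions = collisions)
  list(cells = cells, blood = blood, truth = truth, config = cfg)
}
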