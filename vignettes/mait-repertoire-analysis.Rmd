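---
title: "MAIT-cell TCR repertoire analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAIT-cell TCR repertoire analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maitrep)
```

## The problem

Mucosal-associated invariant T (MAIT) cells are defined by a semi-invariant
TCR alpha chain — TRAV1-2 joined to TRAJ12, TRAJ20 or TRAJ33 — restricted by
the non-polymorphic antigen-presenting molecule MR1. In the colon,
flow-sorting on surface phenotype is imperfect: a substantial fraction of
sorted "MAIT" cells turn out, on sequencing, not to carry the canonical
rearrangement. Any clonotype-level claim therefore has to start from a
sequence-level gate. Downstream, the scientific questions are about sharing
structure: clonal expansion within a biopsy, persistence of clonotypes
between the inflamed and uninflamed colon of one Crohn's disease (CD)
donor, overlap between a donor's colon and blood, and "public" sequences
seen in more than one person — and whether any of that structure segregates
with disease.

`maitrep` implements this as a pipeline over two data shapes: single-cell
paired alpha/beta tables (one sorted cell per record, with V/(D)/J calls,
CDR3 nucleotide and amino-acid junctions and productivity flags, as
produced by IMGT-style alignment of Sanger reads) and bulk beta-chain
repertoires (one unique rearrangement per row with a template count, as in
commercial immunoSEQ exports).

## The canonical filter

`classify_cells()` calls a cell canonical iff its alpha chain is present,
productive, uses TRAV1-2 (TRAV1-1 is rejected) with J in {TRAJ12, TRAJ20,
TRAJ33}, **and** its beta chain is present and productive. The beta
requirement exists because everything downstream operates on productive
pairs; cells failing only on the beta side are labelled `missing_beta`
rather than being folded into a generic rejection, and
`classify_cells(require_beta = FALSE)` recovers the alpha-only tabulation
used for per-sample purity tables. Non-canonical cells receive the *first*
failing reason in a fixed order (`missing_alpha`, `nonproductive_alpha`,
`wrong_trav`, `wrong_traj`, `missing_beta`), which makes contaminant
breakdowns reproducible regardless of evaluation order. Gene matching is at
gene level: allele suffixes (`*01`) are stripped and zero-padding
normalized by `normalize_gene()`, since no analysis here conditions on
allele.

## Two levels of clonotype identity

Colonic clonotypes are exact: both chains must agree on V gene, J gene and
the CDR3 *nucleotide* sequence, scoped within a donor. This is the right
identity for claims about clonal expansion, because nucleotide-level
identity across cells is essentially proof of a shared clonal origin.
All colon-to-blood and cross-donor comparisons instead use the beta-chain
CDR3 *amino-acid* sequence alone: bulk blood data has no alpha chains, and
publicity is conventionally counted on CDR3β amino acids. V/J are ignored
in publicity matching — convergent recombination producing the same amino
acid junction from different nucleotides is precisely what makes a sequence
public — and both levels are exposed so the choice is auditable. Clonotypes
whose junction contains an ambiguous `N` base are excluded from exact
matching (and logged) rather than being allowed to match anything.

## The overlap accounting

For each biopsy stratum (HC, CD all, CD uninflamed, CD inflamed, pooled
total) the unique colonic CDR3β set is intersected with blood: `in_both`
counts sequences present in *any* blood repertoire, `autologous` those in
the blood of a donor whose own colon carried the sequence, `allogeneic`
those in at least one other person's blood. The categories deliberately
overlap (a sequence can be both), so
`max(auto, allo) ≤ in_both ≤ auto + allo`. Union strata count a sequence
once even when it occurs in both biopsies of a donor. Percentages are
integer, of the stratum's unique-sequence count, rounded **half away from
zero**: with counts like 37/87 (42.53%) the half-to-even rule built into R
would report 42 where published tables of this shape report 43, so
`percent_round()` implements the away-from-zero convention; the tests
verify it reproduces a full published five-stratum table of ten
percentages from its printed integer counts.

Donors with biopsies but no blood sample are a design feature, not an
error: their sequences contribute to colon totals and remain eligible for
allogeneic matches, and the function reports them.

## Diversity and overlap statistics

Simpson clonality uses the unbiased pair-sampling estimator
$S = \sum_i n_i(n_i-1) / (N(N-1))$ — the probability that two distinct
cells share a clonotype. The plug-in $\sum p_i^2$ form was rejected
because it cannot reach 0 for an all-singleton repertoire, and the
convention this field reports anchors 0 at "every cell has a different
sequence" and 1 at monoclonality. Blood diversity is computed on
amino-acid beta clonotypes, the same identity used for publicity.

Repertoire overlap defaults to the frequency-based Morisita-Horn form
$M = 2\sum p_i q_i / (\sum p_i^2 + \sum q_i^2)$, which is symmetric,
invariant to scaling one repertoire's counts (important when comparing a
500-cell scaled repertoire to a 50,000-cell sort), 1 for identical
frequency vectors and 0 for disjoint supports. The classical count-based
Morisita index (unbiased Simpson terms in the denominator) is available via
`variant = "classical"`; it can exceed 1 on self-comparison, which is the
standard behaviour of that estimator and the reason it is not the default.
`overlap_matrix()` computes all `choose(n, 2)` pairs and groups them HC-HC /
CD-CD / HC-CD; with the study's 8 + 8 blood donors that is 120 values split
28/28/64.

Consensus motifs restrict to the modal junction length, then per position
report the single residue at frequency ≥ 0.5, else the top two residues
bracketed if together ≥ 0.5, else `X`. The 0.5 thresholds reproduce the
bracketed style in which semi-invariant alpha junctions are conventionally
reported (`CAV[M/R]DSNYQLIW`); both are tunable via the `majority`
argument. Support is the fraction of modal-length sequences matching the
expanded motif, so a reported motif always carries its own evidence.

Group comparisons (`compare_groups()`) are thin delegations to
`wilcox.test()` and `kruskal.test()`, reported unadjusted; they exist so
reports carry the same annotations repertoire figures conventionally do,
not as a statistical contribution of this package.

## The synthetic cohort generator

`simulate_cohort()` exists because raw repertoires of this design are
rarely deposited; it generates cohorts with the structure the analysis
assumes *plus ground-truth labels for every injected sharing event*, so
recovery can be asserted exactly rather than approximately.

Defaults mirror the emulated study design and are not tuning knobs: 10 + 10
donors (CD donors with paired inflamed/uninflamed biopsies, HC one biopsy),
the first 8 per cohort with blood; 80 cells per biopsy; blood sorts of up
to 50,000 cells represented at 1:100 scale (500 cells) to keep desk runs in
seconds; canonical alpha fraction 0.45 (slightly under half, as observed in
colonic sorts); TRAJ weights 0.1/0.1/0.8 with TRAJ33 predominant; beta V
weights giving TRBV6-4 + TRBV20-1 = 0.55, a small majority; public-pool
class fractions 0.24/0.09/0.67 (CD-only/HC-only/shared), matching the
roughly 1 : 0.4 : 2.8 proportions reported for blood MAIT publicity; colon
to blood injection rates 0.48 autologous and 0.13 allogeneic, matching the
"about half, mostly autologous, 13% allogeneic" overlap pattern; and a
0.15 cross-inflammation reseeding rate, which produces the
few-clonotypes-per-donor sharing that paired-biopsy studies report.

Mechanics worth knowing:

* **Randomness contract.** One master seed; every donor draws from a
  deterministically derived substream, so adding a donor does not perturb
  the others, and two runs with one seed are byte-identical.
* **Sequences.** CDR3β are `C` + 8–16 random residues + `F/W`;
  within-donor draws are deduplicated, and clonotype nucleotide junctions
  are back-generated from the amino acids once per clonotype, so cells of
  a clonotype are exactly identical and translation consistency holds by
  construction. Gene segments are drawn once per clonotype (cells of a
  clonotype share one rearrangement) — which is why parameter-recovery
  tests compare clonotype-weighted usage to exact binomial intervals, the
  per-cell fractions being overdispersed by clonal expansion.
* **Injection semantics.** Shared sequences (public pool, colon→blood,
  cross-inflammation) replace an untouched singleton clone where one
  exists, else append a count-1 clone, so injected totals stay near the
  configured sort sizes. The expected public partition is derived from the
  injection records themselves (including colonic sequences that reach two
  blood repertoires through joint autologous + allogeneic injection), not
  by re-running the analysis, so exact-recovery tests are not circular.
* **No unintended sharing.** Independent substreams cannot be globally
  deduplicated against each other, but with ≥ 8 random core residues the
  accidental-collision probability is about $10^{-4}$ per cohort; the
  generator audits the final tables and *reports* any collision, and every
  recovery test first asserts the audit came back empty.
* **Clone sizes.** Geometric (sizes `1 + Geom(p)`, p = 0.5 blood / 0.6
  colon) by default — simple and heavy-tailed enough to exercise expansion
  logic; a Zipf law is available for stress tests.

What the generator does *not* emulate: biophysical V(D)J recombination
statistics (junction composition is uniform over residues), sequencing
error, and the long-tailed clone-size laws of real deep blood sorts.
Passing recovery tests therefore demonstrates the *accounting* is exact,
not that the package's statistics are robust to real-data artifacts such
as cross-sample contamination or sequencing-error-inflated singletons.

## Numerical and edge-case choices

* Simpson clonality errors below N = 2 (undefined rather than silently 0).
* Morisita errors on empty repertoires; merging of duplicate
  `(cdr3_aa, V, J)` rows happens once, at `repertoire()` construction.
* Duplicate `(cell_id, locus)` rows are an ambiguity error by default —
  a single-cell Sanger design cannot phase a doublet — with an explicit
  `on_duplicate = "drop"` mode that removes and logs the affected cells.
* Unparseable gene calls keep their cell but force the chain
  nonproductive, with a warning; reading never silently drops a cell
  (`nrow(result) + nrow(rejected)` equals the distinct input cell count).
* Ties in the consensus motif are broken by `table()` order
  (alphabetical), which is deterministic.
* The worked example (`worked_example_cohort()`) is constructed literally,
  with a deterministic codon choice, so its Simpson, Morisita, overlap and
  edge counts are reproduced from hand enumeration in the tests.

## Problem sizes

The test suite runs the generator at two scales: a small configuration
(3 + 3 donors, 120-cell blood, 30-cell biopsies) for property loops over
seeds, and the full default scale (20 donors, 2,400 colonic cells, 16
blood repertoires) once for parameter-recovery checks; the complete suite
runs in well under a minute on one core. `scripts/acceptance.R` uses a
small seeded cohort to evaluate the two index boundary conventions
(monoclonal Simpson = 1; self-comparison Morisita = 1) at runtime.

## Known limitations

* Publicity matching is CDR3β-amino-acid-only by design; if a study
  defines publicity conditional on V genes, counts will differ.
* The immunoSEQ dialect needs a column mapping
  (`immunoseq_columns()`) because export versions disagree on whether the
  abundance column is templates or reads; the package takes whichever
  column it is pointed at.
* Alpha-chain consensus motifs assume a dominant junction length; highly
  length-heterogeneous inputs reduce `n_used` and the motif describes only
  the modal class.
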