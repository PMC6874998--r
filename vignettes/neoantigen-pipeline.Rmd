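---
title: "Consensus neoantigen discovery and cohort statistics with neocall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus neoantigen discovery and cohort statistics with neocall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocall)
library(dplyr)
```

## The problem

Tumors accumulate somatic mutations, and a nonsilent mutation can create a
peptide the immune system has never seen. When such a mutant peptide is
bound by one of the patient's HLA class-I molecules and presented on the
cell surface, it is a *neoantigen* — a tumor-specific target for T
cell-based immunotherapy. Most neoantigens are private to one patient, but
hotspot driver mutations (TP53 R175H, PIK3CA H1047R, KRAS G12D, ...) can
generate *recurrent* ("public") neoantigens shared across patients, which
makes off-the-shelf peptide panels conceivable.

`neocall` implements the full desk-side analysis: somatic mutations (MAF)
plus per-sample HLA genotypes go in; mutant/wild-type peptide pairs are
enumerated around every missense mutation; a panel of binding predictors
scores both peptides per allele; a consensus rule calls neoantigens; and
cohort statistics quantify load, recurrence, panel coverage, driver
exclusivity and clinical subgroup differences. Because patient sequencing
data cannot ship with a package, a synthetic-cohort generator with a known
ground-truth binding model makes every stage testable, including
parameter-recovery experiments that a real cohort could never support.

## The consensus calling rule

A candidate is a triple (peptide pair, sample, allele). A call is emitted
exactly when three criteria hold:

1. **Length**: the peptide is an 8--11mer. Enumeration guarantees this
   upstream; the caller re-checks it.
2. **Binding**: the *mutant* IC50 is strictly below 500 nM in at least two
   prediction tools. IC50 is the half-maximal inhibitory concentration in
   nM — lower means stronger binding, and 500 nM is the conventional
   binder threshold.
3. **Mutant selectivity**: the consensus (median-over-tools) mutant IC50
   is strictly below the consensus wild-type IC50, i.e. the mutation
   *improves* binding. Without this the wild-type peptide would be equally
   presented and the target would not be tumor-specific.

Three deliberate readings are baked in and tested:

* Criterion 3 is evaluated on the IC50 scale, comparing medians across
  tools. "Affinity score" is ambiguous (score and IC50 run in opposite
  directions); the IC50 reading matches the biological intent of
  mutant-selective binding and is applied consistently.
* All threshold comparisons are strict; ties fail. A peptide at exactly
  500 nM is not a binder, and a mutant exactly as good as its wild type
  is not selective.
* The consensus median is the lower of the two middle values for even
  tool counts, which keeps the summary deterministic and order-free.
* Criterion 2 constrains the mutant peptide only; no binding requirement
  is placed on the wild type.

## Predictors as PSSMs

The predictor family is abstracted as position-specific scoring matrices:
a 20 x L weight table per (allele, length), scoring a peptide as the mean
weight of its residues at their positions, mapped to nanomolar via the
standard transform `ic50 = 50000^(1 - score)`. Scores live in [0, 1]; a
score of 0.426 corresponds to the 500 nM threshold.

Alleles without a native matrix are covered by pocket-similarity
extrapolation: the synthesized PSSM is the average of available matrices
weighted by pseudo-sequence identity between alleles
(`synthesize_pssm()`). The shipped pseudo-sequences are synthetic
fixtures — they carry a plausible similarity structure, not biology.

For simulation, `simulate_binding_truth()` draws one ground-truth PSSM
per (allele, length), and each "tool" observes truth plus Gaussian noise
(SD 0.05 by default, clipped to [0, 1]). This mirrors the real situation
— several predictors estimating one underlying binding specificity — while
making the right answer knowable. Two numeric choices matter:

* **Anchor structure.** Positions 2 and the C-terminus get full weight
  dispersion; other positions get 30% of it, scaled by `motif_strength`
  (0 collapses the matrix to a constant).
* **Baseline 0.28.** Weights center on 0.28, placing a typical random
  peptide near 2400 nM — a clear non-binder — so that binders are a
  minority (roughly 5--10% of windows per allele) and per-sample
  neoantigen loads land in the realistic range of tens to a couple of
  hundred. This was fixed once on realism grounds, not fitted.

## The synthetic cohort

`cohort_config()` collects the generator's knobs; the defaults are the
study conditions the analysis assumes:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 200 | cohort scale at which recurrence and subgroup tests are meaningful |
| `burden_median` | 66 | median nonsilent mutations per gastric-tumor exome |
| `burden_dispersion` | 2 | negative-binomial size; tumors are overdispersed, the spread is a free parameter |
| `ct_fraction` | 0.45 | C>T transitions dominate the substitution spectrum |
| `age_effect` | 1.5 | multiplicative burden increase for age >= 60 |
| hotspots | 15 driver substitutions | recurrent gastric-cancer mutations at few-percent to ~20% prevalence |
| `exclusive_pairs` | TP53 vs CDH1/KMT2D/RYR1/PIK3CA/ARID1A, OR 0.25 | the canonical exclusivity axis |
| HLA frequencies | 9 common class-I alleles | stylized East-Asian allele mix, 3 per locus |

Design notes, in decreasing order of consequence:

* **Burden model.** Counts are negative-binomial. Only a median is a
  stated condition, so the mean is *calibrated*: given the ages (drawn
  first) the base mean is solved with `uniroot()` so that the
  age-effect *mixture* has the configured median. The calibration test
  checks the empirical median against the exact order-statistic 99%
  interval at n = 500.
* **Protein-space generation.** One transcript per gene; background
  missense mutations pick a gene proportional to length and a uniform
  residue; the amino-acid change is drawn directly (no codon model).
  Nucleotide-level ref/alt bases are drawn from the 6-class spectrum
  (C>T weight `ct_fraction`, remainder uniform, random strand) solely to
  drive the landscape summaries; they are deliberately decoupled from
  the amino-acid change.
* **Exclusivity by thinning.** After the mutation table is assembled,
  each configured pair's gene-level 2x2 table is computed and co-mutated
  samples are randomly thinned (dropping one gene's mutations) with the
  keep-probability solved so the *expected* odds ratio equals the
  target. Operating on the full table — background hits included —
  matters: with a small proteome, uniform background alone would mutate
  every large gene in most samples and erase any exclusivity structure.
  For the same reason the default proteome carries 2000 background genes
  of 500 residues, keeping per-gene background rates at a few percent.
* **HLA genotypes.** Loci A, B, C are sampled independently, two alleles
  per locus with replacement; homozygous duplicates collapse, giving 3-6
  distinct alleles per sample.
* **Seed discipline.** One master seed; every component (proteome,
  metadata, burden, genotypes, AF table, truth model, each tool's noise
  stream) derives a child stream by a fixed offset, so components are
  reproducible independently and the whole pipeline is byte-identical
  across runs.
* Samples whose burden draw is zero simply have no mutation rows; they
  remain cohort members and appear in the load table with zero counts.
  (Mutation or call records for samples *absent from the metadata* are
  an error — that direction is a real inconsistency.)

What the generator does **not** emulate: sequencing error and calling
artifacts, subclonal structure, expression and proteasomal processing,
germline variation, indel/frameshift neoepitopes, linkage between HLA
loci. Passing tests therefore demonstrate the statistical machinery and
the calling logic, not predictive accuracy on real tumors.

## Peptide enumeration

For a missense mutation at protein position p in a protein of length n,
every window of length L in {8, 9, 10, 11} whose span contains p is
emitted: starts run over `max(1, p - L + 1) .. min(p, n - L + 1)`, giving
up to 8 + 9 + 10 + 11 = 38 mutant/wild-type pairs at interior positions.
Distinct windows with identical peptide strings are kept (they differ in
start); scoring deduplicates by (peptide, allele) and joins back.

Only missense SNVs yield peptide pairs. Nonsense, nonstop, splice-site
and indel mutations are nonsilent — they count toward burden and the
gene-sample matrix — but no mutant-residue window is well defined for
them, so peptide generation skips them with a counted message. This is
the package's main interpretive narrowing and is surfaced in every run
log. Windows containing non-canonical residues (U, X) are dropped with a
warning because the scoring matrices are 20-letter.

## Statistics

* `fisher_exact_2x2()` is a direct hypergeometric enumeration (two-sided
  p = sum of probabilities of tables at most as likely as the observed,
  relative tie-slack 1e-12). The reported estimate is the *sample* odds
  ratio ad/bc; a Haldane-corrected version is carried for display only.
  An exhaustive sweep over all 1820 tables with total <= 12 checks it
  against the reference implementation.
* `wilcoxon_rank_sum()` uses the exact rank-sum distribution when the
  combined n is at most 20 without ties, otherwise the normal
  approximation with tie and continuity corrections; the mode is
  recorded. Exact mode is verified against full permutation enumeration
  for all group sizes with n <= 8.
* `spearman_rho()` is Pearson on mid-ranks with a t-approximate p-value,
  flagged approximate. Zero rank variance is an error, not an NA.
* `mutual_exclusivity_screen()` reports uncorrected p-values by default
  (matching the convention of calling a pair exclusive at P < 0.05),
  with Benjamini-Hochberg q-values available; direction comes from the
  sample odds ratio, with degenerate tables reported as undetermined
  with p = 1.
* Subgroup comparisons dichotomize age at 60 and run all pairwise
  Wilcoxon tests for stratifiers with 3+ levels; NA-level samples are
  excluded and counted. All tests are two-sided.
* Recurrence identity defaults to the mutant peptide string alone — the
  same peptide presented on different alleles in different patients is
  still one shared target; a peptide+allele mode exists for the stricter
  reading. Both load granularities are available for the same reason.
* Panel selection is explicit greedy maximum coverage: each step adds
  the identity covering the most uncovered samples, ties broken by total
  carrier count then lexicographically. Coverage denominators always
  include call-free samples.
* Gene ranking in the landscape is by the number of distinct mutated
  samples with lexicographic tie-break — frequency ranking, labelled as
  such; no significance model for "significantly mutated genes" is
  implied.

## Problem sizes used by the test suite

The suite runs everything at sizes chosen to keep a laptop-scale run
comfortable while preserving the structure under test: unit tests use
cohorts of 5-60 samples with burden median 10; the null-calibration
checks use 1000 replicates (exclusivity over 1000 independent gene pairs
in 200 samples; Wilcoxon on 40 + 40 identical distributions); the
parameter-recovery and power experiments use 200-sample cohorts with
9-mer windows, one allele per locus, five tools and burden median 30,
with 100 seeded replicates for the age-effect power check; the
load-burden correlation runs the full default configuration once. The
acceptance script (`scripts/acceptance.R`) runs the complete default
study — 200 samples, burden median 66, 8-11mers, 9 alleles, five tools,
roughly 20M predictions — in about two minutes.

## Known limitations

* The five simulated tools share one truth model and independent noise;
  real predictors have correlated, structured errors, so the consensus
  rule's real-world gain is not measured here.
* IC50-scale consensus assumes all tools are calibrated to the same nM
  scale; rank-based thresholds are not implemented.
* No expression, clonality, processing or immunogenicity filters — calls
  are binding-based candidates, not validated epitopes.
* The exclusivity thinning targets the expected odds ratio; any single
  realization scatters around the target, which the tests treat
  correctly as a property (realized OR < 1), not an equality.
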