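# neocall

Cohort-scale neoantigen discovery from somatic tumor mutations, with the
statistics needed to find recurrent ("public") neoantigens worth putting
on a therapeutic peptide panel.

`neocall` is for computational cancer-immunology analysts who have
per-sample somatic mutations (MAF) and HLA class-I genotypes and want a
tested, reproducible path from those inputs to: per-sample neoantigen
load, recurrent neoantigens shared across patients, greedy
maximum-coverage panels, mutual-exclusivity screens of driver genes, and
clinical subgroup comparisons. Because real patient data cannot ship with
a package, it also contains a first-class synthetic-cohort generator with
a ground-truth binding model, so every stage — including
parameter-recovery and power properties — is testable end to end.

## The method

A **neoantigen call** is made for a candidate (mutant/wild-type peptide
pair, sample, HLA allele) exactly when three criteria hold:

1. peptide length L ∈ {8, 9, 10, 11} (every window containing the mutated
   residue is enumerated: starts `max(1, p−L+1) … min(p, n−L+1)`, up to
   38 pairs per interior mutation);
2. mutant IC50 < 500 nM (strict) in at least 2 of the prediction tools;
3. consensus mutant IC50 < consensus wild-type IC50 (strict), where the
   consensus is the median over tools — the mutation must *improve*
   binding, otherwise the peptide is not tumor-selective.

Predictors are abstracted as position-specific scoring matrices (PSSMs):
`score(peptide) = mean_j W[aa_j, j]` with weights in [0, 1], mapped to
nanomolar by the standard transform

    IC50 = 50000^(1 − score)

Alleles without a native matrix are covered by pocket-similarity
extrapolation (pseudo-sequence-identity-weighted averaging of available
matrices). Cohort statistics use exact small-sample tests: Fisher's exact
test by direct hypergeometric enumeration for 2×2 co-mutation tables,
exact Wilcoxon rank-sum tests for subgroup load comparisons, and Spearman
correlation for the load-burden relationship.

## Worked example

Simulate a 60-sample cohort under the default study conditions (median
nonsilent burden 66, C>T-dominant spectrum, hotspot drivers, 1.5× burden
for age ≥ 60), then call neoantigens with five simulated predictors and
analyse the cohort:

```r
library(neocall)
library(dplyr)

cfg      <- cohort_config(n_samples = 60, seed = 11)
proteome <- default_proteome(seed = 11)
cohort   <- simulate_cohort(proteome, cfg)

af    <- simulate_population_af(cohort$mutations, common_fraction = 0.05, seed = 11)
kept  <- filter_common_variants(cohort$mutations, af)      # drop AF > 0.5% variants
pairs <- cohort_peptide_pairs(kept, proteome)              # 8-11mer MT/WT windows

truth <- simulate_binding_truth(cfg$hla_frequencies$allele, seed = 11)
tools <- simulate_tools(truth, n_tools = 5, seed = 11)
calls <- predict_bindings(pairs, cohort$genotypes, tools) |>
  call_neoantigens(pairs, cohort$genotypes, ic50_threshold = 500, min_tools = 2)

loads <- neoantigen_load(calls, cohort$mutations, cohort$metadata)
summary(loads$n_neoantigens)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   16.00   72.75  109.50  136.13  166.50  543.00

tidy(spearman_rho(loads$n_nonsilent, loads$n_neoantigens))
#> # A tibble: 1 × 6
#>   method   statistic estimate  p.value exact     n
#>   <chr>        <dbl>    <dbl>    <dbl> <lgl> <int>
#> 1 spearman     2988.    0.917 8.10e-25 FALSE    60
```

Per-sample neoantigen counts are in the expected range for tumor exomes,
and load tracks mutation burden tightly (Spearman ρ = 0.92 here).
Recurrent neoantigens concentrate in the hotspot drivers:

```r
rec <- recurrent_neoantigens(calls, min_samples = 2)
select(rec, identity, gene_id, aa_change, n_samples)
#> # A tibble: 30 × 4
#>   identity    gene_id aa_change n_samples
#>   <chr>       <chr>   <chr>         <int>
#> 1 CLRAKEWMA   TP53    R282W             7
#> 2 DGMVVMYNQHQ CDH1    D201N             7
#> 3 HGVYDSMWDLS TP53    R175H             7
#> 4 LMKLYAQWI   ARID1A  P548L             7
#> 5 HKQQPCDWFIS KMT2D   Q912K             6
#> # ℹ 25 more rows

panel <- select_panel_greedy(rec, k = 10)
panel_coverage(calls, panel, cohort$metadata$sample_id)
#> [1] 0.65
```

A 10-peptide greedy panel covers 65% of this cohort. The same objects
feed `compare_subgroups()` (Wilcoxon tests across age/sex/Lauren/stage/
location), `mutual_exclusivity_screen()` on the `gene_sample_matrix()`,
and plotting via `autoplot()` on landscape and load objects.

File-level orchestration (`run_simulate()`, `run_call()`, `run_stats()`)
writes the same results as TSVs with JSON run manifests, and
`inst/scripts/neocall.R` wraps them as `simulate` / `call` / `stats`
subcommands for shell use.

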