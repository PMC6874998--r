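# minimal hand-built calls table
toy_calls <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S3"),
    gene_id = "G1", protein_pos = 10L, ref_aa = "R", alt_aa = "H",
    allele = c("HLA-A02:01", "HLA-A02:01", "HLA-B07:02", "HLA-A02:01",
               "HLA-A02:01"),
    length = 9L, start = c(2L, 3L, 2L, 2L, 2L),
    mut_offset = c(9L, 8L, 9L, 9L, 9L),
    mt_peptide = c("PEPTIDEAH", "EPTIDEAHX", "PEPTIDEAH", "PEPTIDEAH",
                   "OTHERPEPK"),
    wt_peptide = c("PEPTIDEAR", "EPTIDEARX", "PEPTIDEAR", "PEPTIDEAR",
                   "OTHERPEPR"),
    n_tools_passing = 2L, consensus_mt_ic50 = 100,
    consensus_wt_ic50 = 1000)
}

toy_meta <- function() {
  tibble::tibble(sample_id = c("S1", "S2", "S3", "S4"),
                 age = c(70L, 50L, 65L, 45L),
                 sex = c("male", "female", "male", "female"),
                 lauren = c("intestinal", "diffuse", NA, "mixed"),
                 stage = c("I", "II", "III", "IV"),
                 location = c("antrum", "body", "cardia", "antrum"))
}

toy_muts <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S3", "S4"),
    gene_id = c("G1", "G2", "G1", "G1", "G3"), chrom = "1",
    genomic_pos = 1:5, ref_allele = "C", alt_allele = "T",
    variant_type = "SNP",
    variant_classification = c("missense", "silent", "missense",
                               "missense", "missense"),
    protein_pos = c(10L, NA, 10L, 10L, 3L),
    ref_aa = c("R", NA, "R", "R", "A"),
    alt_aa = c("H", NA, "H", "H", "V"))
}

test_that("load table deduplicates peptides and keeps call-free samples", {
  loads <- neoantigen_load(toy_calls(), toy_muts(), toy_meta())
  # S1 has 3 call rows but 2 distinct mutant peptides
  expect_equal(loads$n_neoantigens[loads$sample_id == "S1"], 2L)
  # S4 has no calls but stays in the table with zero
  expect_equal(loads$n_neoantigens[loads$sample_id == "S4"], 0L)
  # silent mutation not counted in burden
  expect_equal(loads$n_nonsilent[loads$sample_id == "S1"], 1L)
  expect_equal(loads$age_group, c(">=60", "<60", ">=60", "<60"))

  # peptide+allele granularity counts S1's repeated peptide per allele
  la <- neoantigen_load(toy_calls(), toy_muts(), toy_meta(),
                        identity = "peptide_allele")
  expect_equal(la$n_neoantigens[la$sample_id == "S1"], 3L)

  bad_calls <- dplyr::mutate(toy_calls(),
                             sample_id = sub("S3", "S9", sample_id))
  expect_error(neoantigen_load(bad_calls, toy_muts(), toy_meta()),
               class = "neocall_reconciliation_error")
})

test_that("load counts equal an independent group-by recount", {
  prot <- tiny_proteome()
  ch <- simulate_cohort(prot, tiny_config(seed = 61, n_samples = 12))
  pairs <- suppressMessages(cohort_peptide_pairs(ch$mutations, prot))
  truth <- simulate_binding_truth(unique(ch$genotypes$allele), seed = 61)
  tools <- simulate_tools(truth, 3, seed = 61)
  pred <- predict_bindings(pairs, ch$genotypes, tools)
  calls <- call_neoantigens(pred, pairs, ch$genotypes)
  loads <- neoantigen_load(calls, ch$mutations, ch$metadata)
  recount <- tapply(calls$mt_peptide, calls$sample_id,
                    function(x) length(unique(x)))
  for (s in loads$sample_id) {
    want <- recount[s]
    if (is.na(want)) want <- 0L
    expect_equal(loads$n_neoantigens[loads$sample_id == s],
                 as.integer(want), info = s)
  }
})

test_that("recurrence respects the carrier threshold and ordering", {
  rec2 <- recurrent_neoantigens(toy_calls(), min_samples = 2)
  expect_equal(rec2$identity, "PEPTIDEAH")
  expect_equal(rec2$n_samples, 2L)
  expect_equal(rec2$carriers[[1]], c("S1", "S2"))
  expect_equal(rec2$gene_id, "G1")
  expect_equal(rec2$aa_change, "R10H")

  rec1 <- recurrent_neoantigens(toy_calls(), min_samples = 1)
  expect_setequal(rec1$identity,
                  c("PEPTIDEAH", "EPTIDEAHX", "OTHERPEPK"))
  expect_equal(rec1$identity[1], "PEPTIDEAH")  # sorted by count desc
})

test_that("greedy panel reproduces the hand-enumerated trace", {
  rec <- tibble::tibble(
    identity = c("pepA", "pepB", "pepC"),
    mt_peptide = c("pepA", "pepB", "pepC"),
    gene_id = "G", aa_change = "X1Y", alleles = "HLA-A02:01",
    n_samples = c(2L, 2L, 1L),
    carriers = list(c("S1", "S2"), c("S2", "S3"), "S4"))
  panel <- select_panel_greedy(rec, k = 2)
  # first pick: pepA (2 new); tie at 1 new between pepB and pepC broken
  # by higher total carrier count -> pepB
  expect_equal(panel$identity, c("pepA", "pepB"))
  expect_equal(panel$n_new_samples, c(2L, 1L))
  expect_equal(panel$n_covered_cum, c(2L, 3L))

  one <- select_panel_greedy(rec, k = 1)
  expect_equal(one$identity, "pepA")

  all_p <- select_panel_greedy(rec, k = 10)
  expect_equal(all_p$identity, c("pepA", "pepB", "pepC"))

  # coverage of the trace: 3 of 4 cohort samples
  calls <- tibble::tibble(
    sample_id = c("S1", "S2", "S2", "S3", "S4"),
    gene_id = "G", protein_pos = 1L, ref_aa = "X", alt_aa = "Y",
    allele = "HLA-A02:01", length = 8L, start = 1L, mut_offset = 1L,
    mt_peptide = c("pepA", "pepA", "pepB", "pepB", "pepC"),
    wt_peptide = "w", n_tools_passing = 2L,
    consensus_mt_ic50 = 1, consensus_wt_ic50 = 2)
  expect_equal(panel_coverage(calls, panel, paste0("S", 1:4)), 0.75)
})

test_that("panel coverage is monotone and bounded by single-best", {
  calls <- toy_calls()
  cohort <- toy_meta()$sample_id
  expect_equal(panel_coverage(calls, character(0), cohort), 0)
  rec <- recurrent_neoantigens(calls, min_samples = 1)
  full <- panel_coverage(calls, rec$identity, cohort)
  expect_equal(full, 3 / 4)  # samples with >= 1 call
  cum <- vapply(seq_len(nrow(rec)), function(k) {
    panel_coverage(calls, rec$identity[seq_len(k)], cohort)
  }, numeric(1))
  expect_true(all(diff(cum) >= 0))
  greedy <- select_panel_greedy(rec, k = nrow(rec))
  best_single <- max(vapply(rec$identity, function(id) {
    panel_coverage(calls, id, cohort)
  }, numeric(1)))
  expect_gte(panel_coverage(calls, greedy, cohort), best_single)
})

test_that("exclusivity screen classifies directions and degenerate rows", {
  m <- matrix(0L, 2, 20, dimnames = list(c("A", "B"), paste0("s", 1:20)))
  m["A", 1:10] <- 1L
  m["B", 11:20] <- 1L
  res <- mutual_exclusivity_screen(m)
  expect_equal(res$direction, "exclusive")
  expect_equal(res$p_value,
               fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2))$p_value)

  m2 <- rbind(m, C = 0L)
  res2 <- mutual_exclusivity_screen(m2, tibble::tibble(gene_a = "A",
                                                       gene_b = "C"))
  expect_equal(res2$direction, "undetermined")
  expect_equal(res2$p_value, 1)

  expect_error(
    mutual_exclusivity_screen(m, tibble::tibble(gene_a = "A",
                                                gene_b = "Z")),
    class = "neocall_lookup_error")

  res3 <- mutual_exclusivity_screen(m2, correction = "benjamini_hochberg")
  expect_true("q_value" %in% names(res3))
  expect_equal(res3$q_value, p.adjust(res3$p_value, "BH"))
})

test_that("subgroup comparisons cover levels pairwise and handle NAs", {
  loads <- neoantigen_load(toy_calls(), toy_muts(), toy_meta())
  res <- compare_subgroups(loads, "stage")
  expect_equal(nrow(res), choose(4, 2))

  # identical groups -> p = 1
  ld <- tibble::tibble(sample_id = paste0("s", 1:8),
                       n_nonsilent = 1L,
                       n_neoantigens = rep(c(5L, 9L, 2L, 7L), 2),
                       age = 50L,
                       age_group = rep(c("<60", ">=60"), each = 4),
                       sex = "male", lauren = NA_character_,
                       stage = NA_character_,
                       location = NA_character_)
  class(ld) <- c("neo_load", class(ld))
  same <- compare_subgroups(ld, "age_group")
  expect_equal(same$p_value, 1)

  # lauren has an NA sample which must be excluded and counted
  res_l <- compare_subgroups(loads, "lauren")
  expect_true(all(res_l$n_na_excluded == 1))

  expect_error(compare_subgroups(ld, "sex"),
               class = "neocall_stratification_error")
})
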