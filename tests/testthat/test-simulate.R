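test_that("proteome generation respects bounds, determinism and composition", {
  one <- simulate_proteome(1, 8, 8, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(nchar(one$protein), 8)

  a <- simulate_proteome(50, 100, 500, seed = 7)
  b <- simulate_proteome(50, 100, 500, seed = 7)
  expect_identical(a, b)
  expect_true(all(nchar(a$protein) >= 100 & nchar(a$protein) <= 500))

  # residue frequencies ~ uniform over 20 letters (5-SE binomial band)
  big <- simulate_proteome(200, 100, 100, seed = 3)
  counts <- table(factor(strsplit(paste(big$protein, collapse = ""),
                                  "")[[1]],
                         levels = c("A", "C", "D", "E", "F", "G", "H", "I",
                                    "K", "L", "M", "N", "P", "Q", "R", "S",
                                    "T", "V", "W", "Y")))
  n <- sum(counts)
  se <- sqrt(n * 0.05 * 0.95)
  expect_true(all(abs(counts - n * 0.05) < 5 * se))

  expect_error(simulate_proteome(3, 5, 10, seed = 1),
               class = "neocall_parameter_error")
})

test_that("pinned residues land where requested", {
  prot <- tiny_proteome()
  expect_equal(substr(prot$protein[prot$gene_id == "TP53"], 50, 50), "R")
  expect_error(
    simulate_proteome(gene_ids = "G1", lengths = 20L, seed = 1,
                      force_residues = tibble::tibble(
                        gene_id = "G1", protein_pos = 50L, aa = "R")),
    class = "neocall_consistency_error")
})

test_that("hotspot carriage matches configured prevalence", {
  prot <- tiny_proteome()
  cfg1 <- tiny_config(n_samples = 10)
  cfg1$hotspots$prevalence <- 1.0
  ch <- simulate_cohort(prot, cfg1)
  carriers <- ch$mutations %>%
    dplyr::filter(gene_id == "TP53", protein_pos == 50, alt_aa == "H") %>%
    dplyr::distinct(sample_id)
  expect_equal(nrow(carriers), 10)

  cfg2 <- tiny_config(seed = 21, n_samples = 1000)
  cfg2$hotspots$prevalence <- 0.1
  ch2 <- simulate_cohort(prot, cfg2)
  k <- ch2$mutations %>%
    dplyr::filter(gene_id == "TP53", protein_pos == 50, alt_aa == "H") %>%
    dplyr::distinct(sample_id) %>% nrow()
  ci <- binom_ci99(1000, 0.1)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("hotspot inconsistent with proteome is rejected", {
  prot <- tiny_proteome()
  cfg <- tiny_config()
  cfg$hotspots$ref_aa <- "W"
  expect_error(simulate_cohort(prot, cfg),
               class = "neocall_consistency_error")
})

test_that("age >= 60 samples carry more mutations under age_effect", {
  prot <- tiny_proteome()
  cfg <- tiny_config(seed = 9, n_samples = 1000, age_effect = 1.5)
  ch <- simulate_cohort(prot, cfg)
  burden <- ch$mutations %>%
    dplyr::filter(variant_classification %in%
                    c("missense", "nonsense", "nonstop", "splice_site",
                      "frameshift", "in_frame_indel")) %>%
    dplyr::count(sample_id) %>%
    dplyr::left_join(ch$metadata, by = "sample_id")
  expect_gt(mean(burden$n[burden$age >= 60]),
            mean(burden$n[burden$age < 60]))
})

test_that("cohort median burden is calibrated despite the age effect", {
  prot <- tiny_proteome()
  cfg <- cohort_config(n_samples = 500, burden_median = 66,
                       hotspots = default_hotspots()[0, ],
                       exclusive_pairs = default_exclusive_pairs()[0, ],
                       hla_frequencies = tiny_config()$hla_frequencies,
                       seed = 13)
  ch <- simulate_cohort(prot, cfg)
  burden <- ch$mutations %>%
    dplyr::filter(variant_classification %in%
                    c("missense", "nonsense", "nonstop", "splice_site",
                      "frameshift", "in_frame_indel")) %>%
    dplyr::count(sample_id) %>%
    dplyr::right_join(ch$metadata["sample_id"], by = "sample_id") %>%
    dplyr::mutate(n = dplyr::coalesce(n, 0L))
  x <- sort(burden$n)
  # order-statistic 99% CI for the population median
  lo <- stats::qbinom(0.005, 500, 0.5)
  hi <- stats::qbinom(0.995, 500, 0.5) + 1
  expect_gte(66, x[lo])
  expect_lte(66, x[hi])
})

test_that("configured exclusivity is realized as odds ratio below 1", {
  prot <- tiny_proteome()
  cfg <- cohort_config(
    n_samples = 1000, burden_median = 5,
    hotspots = tibble::tibble(gene_id = c("TP53", "GENEB"),
                              protein_pos = c(50L, 40L),
                              ref_aa = c("R",
                                         substr(prot$protein[2], 40, 40)),
                              alt_aa = c("H", "A"),
                              prevalence = c(0.4, 0.4)),
    exclusive_pairs = tibble::tibble(gene_a = "TP53", gene_b = "GENEB",
                                     odds_ratio = 0.1),
    hla_frequencies = tiny_config()$hla_frequencies, seed = 23)
  ch <- simulate_cohort(prot, cfg)
  gsm <- gene_sample_matrix(ch$mutations, samples = ch$metadata$sample_id)
  res <- mutual_exclusivity_screen(gsm, tibble::tibble(gene_a = "TP53",
                                                       gene_b = "GENEB"))
  expect_lt(res$odds_ratio, 1)
  expect_equal(res$direction, "exclusive")
})

test_that("every emitted protein-space mutation is proteome-consistent", {
  prot <- tiny_proteome()
  ch <- simulate_cohort(prot, tiny_config(seed = 3, n_samples = 40))
  withp <- dplyr::filter(ch$mutations, !is.na(protein_pos),
                         variant_classification != "nonsense" |
                           !is.na(ref_aa))
  seqs <- stats::setNames(prot$protein, prot$gene_id)
  obs <- substr(seqs[withp$gene_id], withp$protein_pos, withp$protein_pos)
  expect_true(all(obs == withp$ref_aa))
})

test_that("simulation is deterministic for a fixed config and seed", {
  prot <- tiny_proteome()
  cfg <- tiny_config(seed = 11, n_samples = 25)
  a <- simulate_cohort(prot, cfg)
  b <- simulate_cohort(prot, cfg)
  expect_identical(a, b)
  af1 <- simulate_population_af(a$mutations, 0.2, seed = 4)
  af2 <- simulate_population_af(b$mutations, 0.2, seed = 4)
  expect_identical(af1, af2)
})

test_that("metadata uses the clinical vocabulary and HLA format is valid", {
  prot <- tiny_proteome()
  ch <- simulate_cohort(prot, tiny_config(seed = 2, n_samples = 60))
  expect_true(all(ch$metadata$sex %in% c("male", "female")))
  expect_true(all(is.na(ch$metadata$lauren) |
                    ch$metadata$lauren %in% c("intestinal", "diffuse",
                                              "mixed")))
  expect_true(all(is.na(ch$metadata$stage) |
                    ch$metadata$stage %in% c("I", "II", "III", "IV")))
  expect_true(all(ch$metadata$age >= 0))
  expect_true(all(grepl("^HLA-[ABC]\\d{2}:\\d{2}$", ch$genotypes$allele)))
  counts <- dplyr::count(ch$genotypes, sample_id)
  expect_true(all(counts$n >= 1 & counts$n <= 6))
})

test_that("invalid HLA frequencies and parameters are rejected", {
  bad <- tibble::tibble(allele = c("HLA-A02:01", "HLA-A11:01"),
                        locus = "A", frequency = c(0.6, 0.5))
  expect_error(cohort_config(hla_frequencies = bad),
               class = "neocall_parameter_error")
  expect_error(cohort_config(ct_fraction = 1.2),
               class = "neocall_parameter_error")
  expect_error(cohort_config(burden_median = 0),
               class = "neocall_parameter_error")
})

test_that("population AF table seeds exactly the requested common fraction", {
  prot <- tiny_proteome()
  ch <- simulate_cohort(prot, tiny_config(seed = 31, n_samples = 40))
  muts <- ch$mutations

  af0 <- simulate_population_af(muts, 0, seed = 1)
  expect_equal(sum(af0$seeded_common), 0)
  expect_equal(nrow(filter_common_variants(muts, af0)), nrow(muts))

  af1 <- simulate_population_af(muts, 1, seed = 1)
  expect_equal(nrow(filter_common_variants(muts, af1)), 0)

  af <- simulate_population_af(muts, 0.2, seed = 8)
  expect_equal(sum(af$seeded_common), round(0.2 * nrow(af)))
  expect_identical(af, simulate_population_af(muts, 0.2, seed = 8))
})

test_that("binding truth has the advertised degenerate and noise behavior", {
  flat <- simulate_binding_truth("HLA-A02:01", motif_strength = 0,
                                 noise_sd = 0, seed = 1, baseline = 0.4)
  peps <- c("ACDEFGHIK", "YYYYYYYYY", "KLMNPQRST")
  s <- truth_score(flat, peps, "HLA-A02:01")
  expect_equal(s, rep(0.4, 3))

  truth <- simulate_binding_truth("HLA-A02:01", seed = 2)
  tools0 <- simulate_tools(truth, 3, noise_sd = 0, seed = 5)
  pair <- toy_pair(mt = "ACDEFGHIK", wt = "ACDEFGHIR")
  pred <- predict_bindings(pair, "HLA-A02:01", tools0)
  truth_mt <- truth_score(truth, "ACDEFGHIK", "HLA-A02:01")
  expect_equal(pred$score[pred$peptide == "ACDEFGHIK"],
               rep(truth_mt, 3))

  # per-tool residual SD ~ configured noise SD (within 20%)
  set.seed(42)
  peps <- vapply(1:1000, function(i) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), 9,
                 replace = TRUE), collapse = "")
  }, character(1))
  tool <- simulate_tools(truth, 1, noise_sd = 0.05, seed = 6)[[1]]
  base <- truth_score(truth, peps, "HLA-A02:01")
  noisy <- withr::with_seed(neocall:::child_seed(tool$seed, 7),
                            stats::rnorm(1000, sd = 0.05))
  resid_sd <- stats::sd(pmin(1, pmax(0, base + noisy)) - base)
  expect_lt(abs(resid_sd - 0.05), 0.2 * 0.05)
})

test_that("promote_binder makes the target peptide a certain strong binder", {
  truth <- simulate_binding_truth(c("HLA-A02:01", "HLA-B07:02"), seed = 3,
                                  lengths = 9)
  truth <- promote_binder(truth, "ACDEFGHIK", wt_aa = "R", mut_offset = 9)
  for (al in c("HLA-A02:01", "HLA-B07:02")) {
    expect_equal(truth_score(truth, "ACDEFGHIK", al), 1)
    wt_score <- truth_score(truth, "ACDEFGHIR", al)
    expect_lt(wt_score, 1)
    expect_lt(score_to_ic50(1), 500)
  }
})
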