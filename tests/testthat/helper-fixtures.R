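# shared fixtures and independent oracles, all built in code

# exact 99% central binomial interval on a count
binom_ci99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)

# brute-force oracle: all substrings of length 8-11 of the mutant and
# wild-type proteins whose window contains the mutated position
brute_force_pairs <- function(wt_protein, p, alt_aa, lengths = 8:11) {
  mt_protein <- wt_protein
  substr(mt_protein, p, p) <- alt_aa
  n <- nchar(wt_protein)
  out <- list()
  for (L in lengths) {
    if (L > n) next
    for (s in seq_len(n - L + 1)) {
      if (s <= p && p <= s + L - 1) {
        out[[length(out) + 1]] <- data.frame(
          length = L, start = s, mut_offset = p - s + 1,
          mt_peptide = substr(mt_protein, s, s + L - 1),
          wt_peptide = substr(wt_protein, s, s + L - 1))
      }
    }
  }
  do.call(rbind, out)
}

# full-permutation oracle for the two-sided exact Wilcoxon rank-sum p-value
perm_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  w_all <- apply(combos, 2, function(i) sum(r[i])) -
    length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# small reusable proteome with one pinned hotspot residue
tiny_proteome <- function(seed = 5) {
  simulate_proteome(gene_ids = c("TP53", "GENEB", "GENEC"),
                    lengths = c(120L, 90L, 200L), seed = seed,
                    force_residues = tibble::tibble(
                      gene_id = "TP53", protein_pos = 50L, aa = "R"))
}

tiny_config <- function(seed = 5, n_samples = 12, ...) {
  cohort_config(
    n_samples = n_samples, burden_median = 10, burden_dispersion = 2,
    hotspots = tibble::tibble(gene_id = "TP53", protein_pos = 50L,
                              ref_aa = "R", alt_aa = "H",
                              prevalence = 0.5),
    exclusive_pairs = tibble::tibble(gene_a = character(),
                                     gene_b = character(),
                                     odds_ratio = numeric()),
    hla_frequencies = tibble::tibble(
      allele = c("HLA-A02:01", "HLA-B07:02", "HLA-C07:02"),
      locus = c("A", "B", "C"), frequency = 1),
    seed = seed, ...)
}

# hand-built predictions table for consensus tests: one candidate with
# given per-tool mutant and wild-type IC50 vectors
toy_predictions <- function(mt_ic50, wt_ic50, mt = "AAAAAAAK",
                            wt = "AAAAAAAR", allele = "HLA-A02:01") {
  dplyr::bind_rows(
    tibble::tibble(peptide = mt, allele = allele,
                   tool_id = paste0("t", seq_along(mt_ic50)),
                   score = ic50_to_score(mt_ic50), ic50 = mt_ic50),
    tibble::tibble(peptide = wt, allele = allele,
                   tool_id = paste0("t", seq_along(wt_ic50)),
                   score = ic50_to_score(wt_ic50), ic50 = wt_ic50))
}

toy_pair <- function(mt = "AAAAAAAK", wt = "AAAAAAAR",
                     sample_id = "S1") {
  tibble::tibble(sample_id = sample_id, gene_id = "G1", protein_pos = 8L,
                 ref_aa = substr(wt, 8, 8), alt_aa = substr(mt, 8, 8),
                 length = nchar(mt), start = 1L, mut_offset = 8L,
                 mt_peptide = mt, wt_peptide = wt)
}
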