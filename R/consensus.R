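# per-(peptide, allele) consensus aggregation of tool predictions:
# tool count, tools passing the IC50 threshold, and the consensus IC50
# (median across tools; lower of the two middle values for even counts,
# so the summary is deterministic and order-free)
consensus_stats <- function(predictions, ic50_threshold) {
  if (nrow(predictions) == 0) {
    return(tibble(peptide = character(), allele = character(),
                  n_tools = integer(), n_pass = integer(),
                  consensus_ic50 = numeric()))
  }
  ord <- order(predictions$allele, predictions$peptide, predictions$ic50,
               method = "radix")
  al <- predictions$allele[ord]
  pep <- predictions$peptide[ord]
  ic <- predictions$ic50[ord]
  n <- length(ic)
  new_grp <- c(TRUE, al[-1] != al[-n] | pep[-1] != pep[-n])
  starts <- which(new_grp)
  n_tools <- diff(c(starts, n + 1L))
  gi <- cumsum(new_grp)
  n_pass <- as.vector(rowsum(as.integer(ic < ic50_threshold), gi,
                             reorder = FALSE))
  k <- floor((n_tools + 1) / 2)
  med <- ic[starts + k - 1L]
  tibble(peptide = pep[starts], allele = al[starts],
         n_tools = as.integer(n_tools), n_pass = as.integer(n_pass),
         consensus_ic50 = med)
}

#' Call neoantigens by multi-tool consensus
#'
#' Applies the three consensus criteria to every candidate
#' (peptide pair, allele of the carrying sample): (1) peptide length
#' between 8 and 11 (guaranteed upstream, re-checked); (2) mutant IC50
#' strictly below `ic50_threshold` in at least `min_tools` tools; (3)
#' consensus (median-over-tools) mutant IC50 strictly below the consensus
#' wild-type IC50, i.e. the mutant peptide binds more strongly than its
#' wild-type counterpart. One call is emitted per (sample, mutation,
#' allele, peptide window); ties (IC50 exactly at threshold, or mutant
#' equal to wild type) fail.
#'
#' @param predictions Prediction tibble from [predict_bindings()].
#' @param pairs Peptide-pair tibble from [cohort_peptide_pairs()].
#' @param genotypes Tibble (`sample_id`, `allele`) or character vector of
#'   alleles applied to every sample.
#' @param ic50_threshold Binder threshold in nM (default 500).
#' @param min_tools Minimum number of tools passing the threshold
#'   (default 2).
#' @return A tibble of calls sorted by (sample, gene, position, allele,
#'   length, start), with `n_tools_passing`, `consensus_mt_ic50`,
#'   `consensus_wt_ic50` columns.
#' @export
call_neoantigens <- function(predictions, pairs, genotypes,
                             ic50_threshold = 500, min_tools = 2) {
  assert_scalar_number(ic50_threshold, "ic50_threshold", lower = 0)
  assert_scalar_number(min_tools, "min_tools", lower = 1)
  empty <- tibble(sample_id = character(), gene_id = character(),
                  protein_pos = integer(), ref_aa = character(),
                  alt_aa = character(), allele = character(),
                  length = integer(), start = integer(),
                  mut_offset = integer(), mt_peptide = character(),
                  wt_peptide = character(), n_tools_passing = integer(),
                  consensus_mt_ic50 = numeric(),
                  consensus_wt_ic50 = numeric())
  if (nrow(pairs) == 0) return(empty)
  if (is.character(genotypes)) {
    genotypes <- tidyr::expand_grid(sample_id = unique(pairs$sample_id),
                                    allele = unique(genotypes))
  }
  genotypes <- distinct(genotypes, .data$sample_id, .data$allele)
  stats <- consensus_stats(predictions, ic50_threshold)
  cand <- inner_join(pairs, genotypes, by = "sample_id",
                     relationship = "many-to-many") %>%
    left_join(rename(stats, mt_peptide = "peptide",
                     n_tools_mt = "n_tools", n_pass_mt = "n_pass",
                     consensus_mt_ic50 = "consensus_ic50"),
              by = c("mt_peptide", "allele")) %>%
    left_join(rename(select(stats, -"n_pass"), wt_peptide = "peptide",
                     n_tools_wt = "n_tools",
                     consensus_wt_ic50 = "consensus_ic50"),
              by = c("wt_peptide", "allele"))
  incomplete <- is.na(cand$consensus_mt_ic50) | is.na(cand$consensus_wt_ic50)
  if (any(incomplete)) {
    i <- which(incomplete)[1]
    abort(sprintf(
      "missing predictions for candidate %s %s p.%d allele %s (%s peptide)",
      cand$sample_id[i], cand$gene_id[i], cand$protein_pos[i],
      cand$allele[i],
      if (is.na(cand$consensus_mt_ic50[i])) "mutant" else "wild-type"),
      class = "neocall_incomplete_input")
  }
  cand %>%
    filter(.data$length >= 8, .data$length <= 11,
           .data$n_pass_mt >= min_tools,
           .data$consensus_mt_ic50 < .data$consensus_wt_ic50) %>%
    mutate(n_tools_passing = .data$n_pass_mt) %>%
    select(all_of(names(empty))) %>%
    arrange(.data$sample_id, .data$gene_id, .data$protein_pos,
            .data$allele, .data$length, .data$start)
}
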