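call_identity <- function(calls, identity) {
  if (identity == "peptide") calls$mt_peptide
  else paste(calls$mt_peptide, calls$allele, sep = "|")
}

#' Per-sample neoantigen load table
#'
#' Joins, for every cohort sample, the nonsilent mutation burden, the
#' neoantigen count (distinct mutant peptide strings by default, or
#' distinct peptide-allele combinations), and the clinical metadata with
#' an age dichotomy at 60. Samples with no calls (or no mutations) are
#' kept with zero counts.
#'
#' @param calls Call tibble from [call_neoantigens()].
#' @param mutations Mutation tibble.
#' @param metadata Metadata tibble (`sample_id`, `age`, `sex`, `lauren`,
#'   `stage`, `location`); defines the cohort sample universe. Mutation or
#'   call samples absent from it raise a reconciliation error.
#' @param identity `"peptide"` (default) or `"peptide_allele"`, the
#'   granularity at which neoantigens are counted.
#' @return A tibble of class `neo_load` with one row per cohort sample.
#' @export
neoantigen_load <- function(calls, mutations, metadata,
                            identity = c("peptide", "peptide_allele")) {
  identity <- match.arg(identity)
  orphans <- setdiff(unique(c(mutations$sample_id, calls$sample_id)),
                     metadata$sample_id)
  if (length(orphans) > 0) {
    abort(sprintf("sample(s) absent from metadata: %s",
                  paste(orphans, collapse = ", ")),
          class = "neocall_reconciliation_error")
  }
  burden <- mutations %>%
    filter(.data$variant_classification %in% NONSILENT_CLASSES) %>%
    count(.data$sample_id, name = "n_nonsilent")
  neo <- calls %>%
    mutate(identity = call_identity(calls, .env$identity)) %>%
    distinct(.data$sample_id, .data$identity) %>%
    count(.data$sample_id, name = "n_neoantigens")
  out <- metadata %>%
    left_join(burden, by = "sample_id") %>%
    left_join(neo, by = "sample_id") %>%
    mutate(n_nonsilent = dplyr::coalesce(.data$n_nonsilent, 0L),
           n_neoantigens = dplyr::coalesce(.data$n_neoantigens, 0L),
           age_group = ifelse(is.na(.data$age), NA_character_,
                              ifelse(.data$age >= 60, ">=60", "<60"))) %>%
    select("sample_id", "n_nonsilent", "n_neoantigens", "age", "age_group",
           "sex", "lauren", "stage", "location")
  class(out) <- c("neo_load", class(out))
  attr(out, "identity") <- identity
  out
}

#' Recurrent ("public") neoantigens
#'
#' Tabulates neoantigen identities carried by at least `min_samples`
#' distinct samples. By default the identity is the mutant peptide string
#' alone (the same peptide presented on different alleles in different
#' patients counts as shared); `"peptide_allele"` requires the allele to
#' match too.
#'
#' @inheritParams neoantigen_load
#' @param min_samples Minimum number of distinct carrier samples
#'   (default 2).
#' @return A tibble sorted by descending carrier count then identity, with
#'   columns `identity`, `mt_peptide`, `gene_id`, `aa_change`, `alleles`,
#'   `n_samples` and a list-column `carriers`.
#' @export
recurrent_neoantigens <- function(calls, min_samples = 2,
                                  identity = c("peptide",
                                               "peptide_allele")) {
  identity <- match.arg(identity)
  assert_scalar_number(min_samples, "min_samples", lower = 1)
  if (nrow(calls) == 0) {
    return(tibble(identity = character(), mt_peptide = character(),
                  gene_id = character(), aa_change = character(),
                  alleles = character(), n_samples = integer(),
                  carriers = list()))
  }
  calls %>%
    mutate(identity = call_identity(calls, .env$identity),
           aa_change = paste0(.data$ref_aa, .data$protein_pos,
                              .data$alt_aa)) %>%
    group_by(.data$identity) %>%
    summarise(mt_peptide = .data$mt_peptide[1],
              gene_id = paste(sort(unique(.data$gene_id)), collapse = ";"),
              aa_change = paste(sort(unique(.data$aa_change)),
                                collapse = ";"),
              alleles = paste(sort(unique(.data$allele)), collapse = ";"),
              n_samples = n_distinct(.data$sample_id),
              carriers = list(sort(unique(.data$sample_id))),
              .groups = "drop") %>%
    filter(.data$n_samples >= min_samples) %>%
    arrange(desc(.data$n_samples), .data$identity)
}

#' Greedy maximum-coverage panel selection
#'
#' Builds an ordered neoantigen panel: at each step the identity adding
#' the most not-yet-covered samples is chosen, with ties broken by higher
#' total carrier count and then lexicographic identity. Selection stops
#' after `k` picks or when no identity adds coverage.
#'
#' @param recurrence Recurrence tibble from [recurrent_neoantigens()]
#'   (needs `identity`, `n_samples`, `carriers`).
#' @param k Maximum panel size.
#' @return A tibble with columns `step`, `identity`, `n_new_samples`,
#'   `n_covered_cum`.
#' @export
select_panel_greedy <- function(recurrence, k) {
  assert_scalar_number(k, "k", lower = 1)
  covered <- character(0)
  picks <- list()
  pool <- recurrence
  for (step in seq_len(min(k, nrow(recurrence)))) {
    gains <- vapply(pool$carriers,
                    function(cs) length(setdiff(cs, covered)), integer(1))
    if (length(gains) == 0 || max(gains) == 0) break
    ord <- order(-gains, -pool$n_samples, pool$identity)
    best <- ord[1]
    covered <- union(covered, pool$carriers[[best]])
    picks[[step]] <- tibble(step = step, identity = pool$identity[best],
                            n_new_samples = gains[best],
                            n_covered_cum = length(covered))
    pool <- pool[-best, ]
  }
  if (length(picks) == 0) {
    return(tibble(step = integer(), identity = character(),
                  n_new_samples = integer(), n_covered_cum = integer()))
  }
  bind_rows(picks)
}

#' Fraction of cohort samples covered by a neoantigen panel
#'
#' @inheritParams neoantigen_load
#' @param panel Character vector of panel identities, or the tibble
#'   returned by [select_panel_greedy()].
#' @param cohort_samples Character vector of all cohort sample ids (the
#'   denominator includes call-free samples).
#' @return A single fraction in `[0, 1]`.
#' @export
panel_coverage <- function(calls, panel, cohort_samples,
                           identity = c("peptide", "peptide_allele")) {
  identity <- match.arg(identity)
  if (is.data.frame(panel)) panel <- panel$identity
  if (length(cohort_samples) == 0) {
    abort("`cohort_samples` must be non-empty",
          class = "neocall_parameter_error")
  }
  if (length(panel) == 0 || nrow(calls) == 0) return(0)
  hit <- calls %>%
    mutate(identity = call_identity(calls, .env$identity)) %>%
    filter(.data$identity %in% panel) %>%
    pull("sample_id")
  length(intersect(unique(hit), cohort_samples)) / length(cohort_samples)
}

#' Screen gene pairs for mutual exclusivity or co-occurrence
#'
#' For each gene pair, builds the 2x2 co-mutation table over samples and
#' applies Fisher's exact test. The direction is `"exclusive"` when the
#' sample odds ratio is below 1, `"co_occurring"` when above, and
#' `"undetermined"` for degenerate tables (e.g. an unmutated gene). No
#' multiple-testing correction is applied by default; Benjamini-Hochberg
#' q-values can be appended.
#'
#' @param matrix Binary gene-by-sample matrix from
#'   [gene_sample_matrix()].
#' @param gene_pairs Optional tibble (`gene_a`, `gene_b`); defaults to all
#'   unordered pairs of matrix rows.
#' @param correction `"none"` (default) or `"benjamini_hochberg"`.
#' @return A tibble with the 2x2 counts, `odds_ratio`, `p_value`,
#'   `direction`, and `q_value` when corrected.
#' @export
mutual_exclusivity_screen <- function(matrix, gene_pairs = NULL,
                                      correction = c("none",
                                                     "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (is.null(gene_pairs)) {
    genes <- rownames(matrix)
    if (length(genes) < 2) {
      abort("need at least two genes to screen",
            class = "neocall_parameter_error")
    }
    idx <- utils::combn(genes, 2)
    gene_pairs <- tibble(gene_a = idx[1, ], gene_b = idx[2, ])
  }
  missing <- setdiff(unique(c(gene_pairs$gene_a, gene_pairs$gene_b)),
                     rownames(matrix))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from matrix: %s",
                  paste(missing, collapse = ", ")),
          class = "neocall_lookup_error")
  }
  res <- purrr::map2_dfr(gene_pairs$gene_a, gene_pairs$gene_b,
                         function(ga, gb) {
    va <- matrix[ga, ] > 0
    vb <- matrix[gb, ] > 0
    tab <- matrix(c(sum(va & vb), sum(va & !vb),
                    sum(!va & vb), sum(!va & !vb)),
                  nrow = 2, byrow = TRUE)
    ht <- fisher_exact_2x2(tab)
    or <- unname(ht$estimate)
    tibble(gene_a = ga, gene_b = gb,
           n_both = tab[1, 1], n_a_only = tab[1, 2],
           n_b_only = tab[2, 1], n_neither = tab[2, 2],
           odds_ratio = or, p_value = ht$p_value,
           direction = if (is.nan(or)) "undetermined"
                       else if (or < 1) "exclusive" else "co_occurring")
  })
  if (correction == "benjamini_hochberg") {
    res$q_value <- p.adjust(res$p_value, method = "BH")
  }
  res
}

#' Compare neoantigen load between clinical subgroups
#'
#' Runs two-sided Wilcoxon rank-sum tests on the per-sample neoantigen
#' count across the levels of a clinical stratifier: a single test for
#' two-level stratifiers, all pairwise tests otherwise. Samples with a
#' missing level are excluded and counted in `n_na_excluded`.
#'
#' @param loads Load table from [neoantigen_load()].
#' @param stratifier One of `"age_group"`, `"sex"`, `"lauren"`, `"stage"`,
#'   `"location"`.
#' @return A tibble with one row per comparison: the two levels, group
#'   sizes, Wilcoxon statistic, p-value, exact flag and NA-exclusion
#'   count.
#' @export
compare_subgroups <- function(loads, stratifier = c("age_group", "sex",
                                                    "lauren", "stage",
                                                    "location")) {
  stratifier <- match.arg(stratifier)
  s <- loads[[stratifier]]
  n_na <- sum(is.na(s))
  keep <- !is.na(s)
  lv <- sort(unique(s[keep]))
  if (length(lv) < 2) {
    abort(sprintf("stratifier %s has fewer than 2 usable levels",
                  stratifier), class = "neocall_stratification_error")
  }
  pairs <- utils::combn(lv, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    la <- pairs[1, j]; lb <- pairs[2, j]
    xa <- loads$n_neoantigens[keep & s == la]
    xb <- loads$n_neoantigens[keep & s == lb]
    ht <- wilcoxon_rank_sum(xa, xb)
    tibble(stratifier = stratifier, group_a = la, group_b = lb,
           n_a = length(xa), n_b = length(xb),
           statistic = unname(ht$statistic), p_value = ht$p_value,
           exact = ht$exact, n_na_excluded = n_na)
  })
}
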