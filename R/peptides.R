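#' Apply a missense substitution to a protein sequence
#'
#' @param protein_seq Wild-type protein string.
#' @param protein_pos 1-based residue index of the substitution.
#' @param ref_aa Expected wild-type residue at that position; a mismatch
#'   raises a consistency error carrying the expected/observed residues.
#' @param alt_aa Mutant residue.
#' @return The mutant protein string, differing from the input at exactly
#'   `protein_pos`.
#' @examples
#' apply_missense("ACDEF", 3, "D", "N")
#' @export
apply_missense <- function(protein_seq, protein_pos, ref_aa, alt_aa) {
  n <- nchar(protein_seq)
  if (protein_pos < 1 || protein_pos > n) {
    abort(sprintf("protein_pos %d outside sequence of length %d",
                  protein_pos, n), class = "neocall_parameter_error")
  }
  obs <- substr(protein_seq, protein_pos, protein_pos)
  if (obs != ref_aa) {
    abort(sprintf("reference residue mismatch at position %d: expected %s, observed %s",
                  protein_pos, ref_aa, obs),
          class = "neocall_consistency_error")
  }
  substr(protein_seq, protein_pos, protein_pos) <- alt_aa
  protein_seq
}

#' Enumerate mutant/wild-type peptide pairs around a missense mutation
#'
#' Emits every window of each requested length that contains the mutated
#' residue: for length L and mutated position p in a protein of length n,
#' starts run over `max(1, p - L + 1) .. min(p, n - L + 1)`. Each pair
#' carries the mutant and wild-type peptide (differing at exactly one
#' position) and the 1-based offset of the mutated residue within the
#' window. Windows containing non-canonical residues (e.g. U or X) are
#' dropped with a warning, since downstream scoring matrices are
#' 20-letter.
#'
#' @param wt_protein Wild-type protein string.
#' @param mutation A list or one-row data frame with `sample_id`,
#'   `gene_id`, `protein_pos`, `ref_aa`, `alt_aa` and
#'   `variant_classification` (must be `"missense"`).
#' @param lengths Peptide lengths to enumerate (default 8:11).
#' @return A tibble with one row per (length, start) window: `sample_id`,
#'   `gene_id`, `protein_pos`, `ref_aa`, `alt_aa`, `length`, `start`,
#'   `mut_offset`, `mt_peptide`, `wt_peptide`.
#' @export
enumerate_peptide_pairs <- function(wt_protein, mutation, lengths = 8:11) {
  mutation <- as.list(mutation)
  if (!identical(mutation$variant_classification %||% "missense",
                 "missense")) {
    abort(sprintf("peptide pairs are only defined for missense mutations (got %s)",
                  mutation$variant_classification),
          class = "neocall_unsupported_classification")
  }
  p <- mutation$protein_pos
  mt_protein <- apply_missense(wt_protein, p, mutation$ref_aa,
                               mutation$alt_aa)
  n <- nchar(wt_protein)
  rows <- list()
  for (L in sort(lengths)) {
    lo <- max(1L, p - L + 1L)
    hi <- min(p, n - L + 1L)
    if (lo > hi) next
    starts <- seq.int(lo, hi)
    rows[[as.character(L)]] <- tibble(
      length = L, start = starts, mut_offset = p - starts + 1L,
      mt_peptide = substring(mt_protein, starts, starts + L - 1L),
      wt_peptide = substring(wt_protein, starts, starts + L - 1L))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(length = integer(), start = integer(),
                  mut_offset = integer(), mt_peptide = character(),
                  wt_peptide = character())
  }
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                out$mt_peptide) |
    !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
           out$wt_peptide)
  if (any(bad)) {
    warn(sprintf("dropping %d window(s) containing non-canonical residues",
                 sum(bad)))
    out <- out[!bad, ]
  }
  tibble(sample_id = mutation$sample_id %||% NA_character_,
         gene_id = mutation$gene_id %||% NA_character_,
         protein_pos = as.integer(p),
         ref_aa = mutation$ref_aa, alt_aa = mutation$alt_aa) %>%
    tidyr::expand_grid(out)
}

#' Enumerate peptide pairs for a whole cohort
#'
#' Runs [enumerate_peptide_pairs()] for every missense mutation of a
#' mutation table against the proteome. Nonsilent mutations of other
#' classes (nonsense, nonstop, splice-site, indels) carry no well-defined
#' mutant residue window and are skipped with a counted message; the skip
#' count is attached as the `skipped_nonmissense` attribute.
#'
#' @param mutations Mutation tibble.
#' @param proteome Proteome tibble (`gene_id`, `protein`).
#' @param lengths Peptide lengths (default 8:11).
#' @return A tibble of peptide pairs for all missense mutations.
#' @export
cohort_peptide_pairs <- function(mutations, proteome, lengths = 8:11) {
  nonsilent <- filter(mutations,
                      .data$variant_classification %in% NONSILENT_CLASSES)
  missense <- filter(nonsilent, .data$variant_classification == "missense")
  n_skipped <- nrow(nonsilent) - nrow(missense)
  if (n_skipped > 0) {
    inform(sprintf(
      "skipping %d nonsilent non-missense mutation(s): no peptide construction",
      n_skipped))
  }
  prot <- setNames(proteome$protein, proteome$gene_id)
  missing <- setdiff(unique(missense$gene_id), names(prot))
  if (length(missing) > 0) {
    abort(sprintf("mutated gene(s) absent from proteome: %s",
                  paste(missing, collapse = ", ")),
          class = "neocall_consistency_error")
  }
  # vectorized window enumeration over all missense mutations at once
  out <- if (nrow(missense) == 0) {
    tibble(sample_id = character(), gene_id = character(),
           protein_pos = integer(), ref_aa = character(),
           alt_aa = character(), length = integer(), start = integer(),
           mut_offset = integer(), mt_peptide = character(),
           wt_peptide = character())
  } else {
    wt <- prot[missense$gene_id]
    obs <- substr(wt, missense$protein_pos, missense$protein_pos)
    bad <- obs != missense$ref_aa
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "reference residue mismatch for %s p.%d: expected %s, observed %s",
        missense$gene_id[i], missense$protein_pos[i], missense$ref_aa[i],
        obs[i]), class = "neocall_consistency_error")
    }
    n <- nchar(wt)
    p <- missense$protein_pos
    grids <- lapply(sort(lengths), function(L) {
      lo <- pmax(1L, p - L + 1L)
      hi <- pmin(p, n - L + 1L)
      k <- pmax(0L, hi - lo + 1L)
      idx <- rep.int(seq_len(nrow(missense)), k)
      starts <- unlist(lapply(which(k > 0), function(i) seq.int(lo[i], hi[i])),
                       use.names = FALSE)
      if (length(idx) == 0) return(NULL)
      wt_pep <- substring(wt[idx], starts, starts + L - 1L)
      off <- p[idx] - starts + 1L
      mt_pep <- wt_pep
      substr(mt_pep, off, off) <- missense$alt_aa[idx]
      tibble(sample_id = missense$sample_id[idx],
             gene_id = missense$gene_id[idx],
             protein_pos = as.integer(p[idx]),
             ref_aa = missense$ref_aa[idx],
             alt_aa = missense$alt_aa[idx],
             length = L, start = starts, mut_offset = off,
             mt_peptide = mt_pep, wt_peptide = wt_pep)
    })
    bind_rows(grids)
  }
  alphabet_re <- sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = ""))
  bad <- !grepl(alphabet_re, out$mt_peptide) |
    !grepl(alphabet_re, out$wt_peptide)
  if (any(bad)) {
    warn(sprintf("dropping %d window(s) containing non-canonical residues",
                 sum(bad)))
    out <- out[!bad, ]
  }
  out <- arrange(out, .data$sample_id, .data$gene_id, .data$protein_pos,
                 .data$length, .data$start)
  attr(out, "skipped_nonmissense") <- n_skipped
  out
}
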