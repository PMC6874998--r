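#' Construct a position-specific scoring matrix
#'
#' A PSSM holds per-residue, per-position weights in `[0, 1]` for one
#' allele and one peptide length; it is the common abstraction behind the
#' matrix/affinity family of MHC class-I binding predictors.
#'
#' @param allele Allele name (e.g. `"HLA-A02:01"`).
#' @param length Peptide length (8-11 in this pipeline).
#' @param weights A 20 x `length` numeric matrix with rownames equal to the
#'   20 canonical residues.
#' @return An object of class `pssm`.
#' @export
new_pssm <- function(allele, length, weights) {
  weights <- as.matrix(weights)
  if (!identical(dim(weights), c(20L, as.integer(length)))) {
    abort("PSSM weights must be a 20 x length matrix",
          class = "neocall_parameter_error")
  }
  if (!all(is.finite(weights))) {
    abort("PSSM weights must all be finite", class = "neocall_parameter_error")
  }
  if (is.null(rownames(weights))) rownames(weights) <- AA_ALPHABET
  if (!identical(sort(rownames(weights)), AA_ALPHABET)) {
    abort("PSSM rownames must be the 20 canonical residues",
          class = "neocall_parameter_error")
  }
  weights <- weights[AA_ALPHABET, , drop = FALSE]
  structure(list(allele = allele, length = as.integer(length),
                 weights = weights), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> allele=%s length=%d\n", x$allele, x$length))
  invisible(x)
}

# residue-index matrix (n x L) for equal-length peptides; byte-level
# translation keeps this linear-time over millions of peptides
peptide_index_matrix <- function(peptides, L) {
  codes <- utf8ToInt(paste(peptides, collapse = ""))
  lut <- integer(128)
  lut[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_len(20)
  idx <- lut[codes]
  if (any(idx == 0L)) {
    abort("peptides must use the 20-letter amino-acid alphabet",
          class = "neocall_parameter_error")
  }
  matrix(idx, ncol = L, byrow = TRUE)
}

#' Score peptides against a PSSM
#'
#' The score of a peptide is the arithmetic mean over positions of the
#' weight of its residue at that position; with weights in `[0, 1]` the
#' score is too.
#'
#' @param pssm A [new_pssm()] object.
#' @param peptides Character vector of peptides, all of length
#'   `pssm$length`.
#' @return Numeric vector of scores.
#' @export
score_peptide <- function(pssm, peptides) {
  stopifnot(inherits(pssm, "pssm"))
  if (length(peptides) == 0) return(numeric(0))
  if (any(nchar(peptides) != pssm$length)) {
    abort(sprintf("all peptides must have length %d", pssm$length),
          class = "neocall_parameter_error")
  }
  im <- peptide_index_matrix(peptides, pssm$length)
  w <- pssm$weights
  acc <- numeric(nrow(im))
  for (j in seq_len(ncol(im))) acc <- acc + w[im[, j], j]
  unname(acc) / pssm$length
}

#' Convert a binding score to IC50 (nM) and back
#'
#' Uses the standard log-transform of the matrix-predictor family:
#' `ic50 = 50000^(1 - score)`, so score 1 maps to 1 nM, score 0 to
#' 50000 nM, and the conventional 500 nM binder threshold corresponds to a
#' score of about 0.426.
#'
#' @param score Numeric vector in `[0, 1]`.
#' @return `score_to_ic50()`: IC50 values in nM; `ic50_to_score()`: scores.
#' @export
score_to_ic50 <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    abort("`score` must lie in [0, 1]", class = "neocall_parameter_error")
  }
  50000^(1 - score)
}

#' @param ic50 Numeric vector in `(0, 50000]`.
#' @rdname score_to_ic50
#' @export
ic50_to_score <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0) || any(ic50 > 50000)) {
    abort("`ic50` must lie in (0, 50000]", class = "neocall_parameter_error")
  }
  1 - log(ic50) / log(50000)
}

#' Write and read PSSM files
#'
#' Plain-text TSV format: a first line `#allele=<name> length=<L>`, a
#' header row of positions `1..L`, then one row per residue.
#'
#' @param pssm A [new_pssm()] object.
#' @param path File path.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#allele=%s length=%d", pssm$allele, pssm$length), con)
  writeLines(paste(c("residue", seq_len(pssm$length)), collapse = "\t"), con)
  for (r in rownames(pssm$weights)) {
    writeLines(paste(c(r, formatC(pssm$weights[r, ], digits = 9,
                                  format = "g")), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines[1],
                  regexec("^#allele=(\\S+) length=(\\d+)$", lines[1]))[[1]]
  if (length(m) != 3) {
    abort("PSSM file must start with '#allele=<name> length=<L>'",
          class = "neocall_format_error")
  }
  L <- as.integer(m[3])
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  res <- vapply(body, `[`, character(1), 1)
  w <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(L)))
  rownames(w) <- res
  new_pssm(m[2], L, w[AA_ALPHABET, , drop = FALSE])
}

#' Bundled synthetic HLA pseudo-sequences
#'
#' A fixed-length residue string over binding-pocket positions for each
#' supported allele. These are synthetic fixtures (not biologically
#' sourced); they only carry the similarity structure that PSSM synthesis
#' for uncovered alleles needs.
#'
#' @return A tibble with columns `allele`, `pseudo_seq`.
#' @export
default_pseudo_sequences <- function() {
  path <- system.file("extdata", "synthetic_pseudo_sequences.tsv",
                      package = "neocall", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Build an allele registry
#'
#' The registry makes allele coverage explicit: it maps alleles to
#' binding-pocket pseudo-sequences and to the natively available PSSMs, and
#' is the basis for similarity-weighted PSSM synthesis for alleles without
#' a native matrix.
#'
#' @param pssms A list of [new_pssm()] objects (native matrices).
#' @param pseudo_sequences Tibble with columns `allele`, `pseudo_seq`
#'   (all the same length).
#' @return An object of class `allele_registry`.
#' @export
allele_registry <- function(pssms = list(),
                            pseudo_sequences = default_pseudo_sequences()) {
  ps <- as_tibble(pseudo_sequences)
  if (length(unique(nchar(ps$pseudo_seq))) > 1) {
    abort("pseudo-sequences must all have the same length",
          class = "neocall_parameter_error")
  }
  for (p in pssms) {
    stopifnot(inherits(p, "pssm"))
    if (!p$allele %in% ps$allele) {
      abort(sprintf("registered PSSM allele %s has no pseudo-sequence",
                    p$allele), class = "neocall_parameter_error")
    }
  }
  names(pssms) <- vapply(pssms, function(p) paste(p$allele, p$length,
                                                  sep = "|"), character(1))
  structure(list(pssms = pssms, pseudo = ps), class = "allele_registry")
}

pseudo_identity <- function(a, b) {
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Synthesize a PSSM for an uncovered allele
#'
#' Pocket-similarity extrapolation: the returned matrix is the
#' similarity-weighted average of the registry's native PSSMs of the
#' requested length, with weights proportional to pseudo-sequence identity
#' between the target allele and each source allele (weights sum to 1).
#' A native PSSM for the target is returned unchanged.
#'
#' @param target_allele Allele to cover.
#' @param registry An [allele_registry()].
#' @param length Peptide length.
#' @return A [new_pssm()] object for `target_allele`.
#' @export
synthesize_pssm <- function(target_allele, registry, length) {
  stopifnot(inherits(registry, "allele_registry"))
  key <- paste(target_allele, length, sep = "|")
  if (!is.null(registry$pssms[[key]])) return(registry$pssms[[key]])
  sources <- Filter(function(p) p$length == length, registry$pssms)
  if (length(sources) == 0) {
    have <- unique(vapply(registry$pssms, function(p)
      sprintf("%s (L=%d)", p$allele, p$length), character(1)))
    abort(sprintf("no PSSM of length %d available; registry has: %s",
                  length, paste(have, collapse = ", ")),
          class = "neocall_coverage_error")
  }
  tp <- registry$pseudo$pseudo_seq[match(target_allele,
                                         registry$pseudo$allele)]
  if (is.na(tp)) {
    abort(sprintf("allele %s has no pseudo-sequence", target_allele),
          class = "neocall_coverage_error")
  }
  ident <- vapply(sources, function(p) {
    sp <- registry$pseudo$pseudo_seq[match(p$allele, registry$pseudo$allele)]
    pseudo_identity(tp, sp)
  }, numeric(1))
  w <- if (sum(ident) == 0) rep(1 / length(ident), length(ident))
       else ident / sum(ident)
  avg <- Reduce(`+`, Map(function(p, wi) wi * p$weights, sources, w))
  new_pssm(target_allele, length, avg)
}

#' Predictor tool configurations
#'
#' The multi-predictor consensus rule needs several interchangeable
#' scorers. Two kinds are provided: `tool_simulated()` scores peptides as
#' ground-truth score plus Gaussian noise (clipped to `[0, 1]`), emulating
#' an external predictor observing the same underlying binding
#' specificity; `tool_pssm()` scores with a registry's native or
#' synthesized PSSM (pocket-similarity extrapolation).
#'
#' @param tool_id Short identifier used in prediction output.
#' @param truth A `binding_truth` object.
#' @param noise_sd Per-score noise SD (defaults to the truth model's).
#' @param seed Seed controlling this tool's noise stream.
#' @return An object of class `neo_tool`.
#' @export
tool_simulated <- function(tool_id, truth, noise_sd = NULL, seed = 1) {
  stopifnot(inherits(truth, "binding_truth"))
  structure(list(tool_id = tool_id, type = "simulated", truth = truth,
                 noise_sd = noise_sd %||% truth$noise_sd, seed = seed),
            class = "neo_tool")
}

#' @param registry An [allele_registry()] for `tool_pssm()`.
#' @rdname tool_simulated
#' @export
tool_pssm <- function(tool_id, registry) {
  stopifnot(inherits(registry, "allele_registry"))
  structure(list(tool_id = tool_id, type = "pssm", registry = registry,
                 noise_sd = 0, seed = 0), class = "neo_tool")
}

#' Build a panel of simulated prediction tools
#'
#' Returns `n_tools` independent noisy observers of one ground-truth
#' binding model, mirroring the multi-predictor setup used for consensus
#' neoantigen calling.
#'
#' @param truth A `binding_truth` object.
#' @param n_tools Number of tools (>= 2 for the consensus rule).
#' @param noise_sd Per-score noise SD (defaults to the truth model's).
#' @param seed Master seed; each tool gets a derived child stream.
#' @return A list of `neo_tool` objects.
#' @export
simulate_tools <- function(truth, n_tools = 5, noise_sd = NULL, seed = 1) {
  lapply(seq_len(n_tools), function(i) {
    tool_simulated(sprintf("sim%d", i), truth, noise_sd = noise_sd,
                   seed = child_seed(seed, 61 + i))
  })
}

# noise-free base score of a tool for equal-length peptides under an allele
tool_base_score <- function(tool, peptides, allele) {
  if (tool$type == "simulated") {
    truth_score(tool$truth, peptides, allele)
  } else {
    pssm <- synthesize_pssm(allele, tool$registry, nchar(peptides[1]))
    score_peptide(pssm, peptides)
  }
}

#' Predict peptide-HLA binding with a panel of tools
#'
#' Scores both the mutant and the wild-type peptide of every pair against
#' every class-I allele of the carrying sample, once per tool. Duplicate
#' peptide strings are scored once per (allele, tool); homozygous
#' (duplicated) alleles are collapsed. Tool noise is seed-controlled by the
#' tool configuration and drawn over a canonical (allele, peptide) order,
#' so output is deterministic for fixed inputs.
#'
#' @param pairs Peptide-pair tibble (see [enumerate_peptide_pairs()]);
#'   must contain `sample_id`, `mt_peptide`, `wt_peptide`.
#' @param genotypes Either a tibble with columns `sample_id`, `allele`, or
#'   a character vector of alleles applied to every sample.
#' @param tools List of `neo_tool` configurations (>= 2; the consensus
#'   rule needs at least two).
#' @return A tibble with columns `peptide`, `allele`, `tool_id`, `score`,
#'   `ic50`: one row per distinct (peptide, allele) per tool.
#' @export
predict_bindings <- function(pairs, genotypes, tools) {
  if (length(tools) < 2) {
    abort("at least two tools are required for consensus calling",
          class = "neocall_parameter_error")
  }
  if (nrow(pairs) == 0) {
    return(tibble(peptide = character(), allele = character(),
                  tool_id = character(), score = numeric(),
                  ic50 = numeric()))
  }
  if (is.character(genotypes)) {
    genotypes <- tidyr::expand_grid(sample_id = unique(pairs$sample_id),
                                    allele = unique(genotypes))
  }
  genotypes <- distinct(genotypes, .data$sample_id, .data$allele)
  tasks <- bind_rows(
    dplyr::transmute(pairs, sample_id = .data$sample_id,
                     peptide = .data$mt_peptide),
    dplyr::transmute(pairs, sample_id = .data$sample_id,
                     peptide = .data$wt_peptide)
  ) %>%
    inner_join(genotypes, by = "sample_id",
               relationship = "many-to-many") %>%
    distinct(.data$peptide, .data$allele) %>%
    mutate(length = nchar(.data$peptide)) %>%
    arrange(.data$allele, .data$length, .data$peptide)

  # (allele, length) chunk boundaries; tasks are sorted so chunks are runs
  new_chunk <- c(TRUE, tasks$allele[-1] != tasks$allele[-nrow(tasks)] |
                   tasks$length[-1] != tasks$length[-nrow(tasks)])
  chunk_start <- which(new_chunk)
  chunk_end <- c(chunk_start[-1] - 1L, nrow(tasks))

  # tools sharing one base scorer (e.g. noisy observers of the same truth
  # model) reuse its base scores; only the noise differs per tool
  base_cache <- new.env(parent = emptyenv())
  base_for <- function(tool) {
    key <- if (tool$type == "simulated") rlang::obj_address(tool$truth)
           else rlang::obj_address(tool$registry)
    if (!is.null(base_cache[[key]])) return(base_cache[[key]])
    base <- numeric(nrow(tasks))
    for (i in seq_along(chunk_start)) {
      sel <- chunk_start[i]:chunk_end[i]
      base[sel] <- tool_base_score(tool, tasks$peptide[sel],
                                   tasks$allele[chunk_start[i]])
    }
    base_cache[[key]] <- base
    base
  }

  out <- vector("list", length(tools))
  for (t in seq_along(tools)) {
    tool <- tools[[t]]
    score <- base_for(tool)
    if (tool$noise_sd > 0) {
      noise <- withr::with_seed(child_seed(tool$seed, 7),
                                rnorm(nrow(tasks), sd = tool$noise_sd))
      score <- pmin(1, pmax(0, score + noise))
    }
    out[[t]] <- tibble(peptide = tasks$peptide, allele = tasks$allele,
                       tool_id = tool$tool_id, score = score,
                       ic50 = score_to_ic50(score))
  }
  bind_rows(out)
}
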