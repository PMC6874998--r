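# internal <-> MAF classification vocabulary
maf_class_out <- function(classification, variant_type) {
  dplyr::case_when(
    classification == "missense" ~ "Missense_Mutation",
    classification == "nonsense" ~ "Nonsense_Mutation",
    classification == "nonstop" ~ "Nonstop_Mutation",
    classification == "splice_site" ~ "Splice_Site",
    classification == "silent" ~ "Silent",
    classification == "frameshift" & variant_type == "INS" ~ "Frame_Shift_Ins",
    classification == "frameshift" ~ "Frame_Shift_Del",
    classification == "in_frame_indel" & variant_type == "INS" ~ "In_Frame_Ins",
    classification == "in_frame_indel" ~ "In_Frame_Del",
    TRUE ~ "Unknown"
  )
}

maf_class_in <- function(label) {
  l <- tolower(label)
  dplyr::case_when(
    l == "missense_mutation" ~ "missense",
    l == "nonsense_mutation" ~ "nonsense",
    l == "nonstop_mutation" ~ "nonstop",
    l == "splice_site" ~ "splice_site",
    l %in% c("silent", "synonymous") ~ "silent",
    l %in% c("frame_shift_ins", "frame_shift_del") ~ "frameshift",
    l %in% c("in_frame_ins", "in_frame_del") ~ "in_frame_indel",
    TRUE ~ "other"
  )
}

MAF_REQUIRED <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                  "Reference_Allele", "Tumor_Seq_Allele2",
                  "Variant_Classification", "Variant_Type",
                  "Tumor_Sample_Barcode")

#' Read and write somatic mutations in MAF format
#'
#' `read_maf()` parses a tab-separated Mutation Annotation Format file into
#' the internal mutation tibble (one row per mutation per sample). Column
#' matching is case-insensitive; extra columns are ignored; rows with an
#' unrecognized variant classification map to `"other"`, and blank protein
#' fields become `NA`. `write_maf()` is its inverse.
#'
#' @param path Path to a MAF file.
#' @return `read_maf()`: a tibble with columns `sample_id`, `gene_id`,
#'   `chrom`, `genomic_pos`, `ref_allele`, `alt_allele`, `variant_type`,
#'   `variant_classification`, `protein_pos`, `ref_aa`, `alt_aa`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("MAF file not found: %s", path),
          class = "neocall_format_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  nm <- names(raw)
  idx <- match(tolower(MAF_REQUIRED), tolower(nm))
  if (anyNA(idx)) {
    abort(sprintf("MAF is missing required column(s): %s",
                  paste(MAF_REQUIRED[is.na(idx)], collapse = ", ")),
          class = "neocall_format_error")
  }
  names(raw)[idx] <- MAF_REQUIRED
  pos <- suppressWarnings(as.numeric(raw$Start_Position))
  if (nrow(raw) > 0 && anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    abort(sprintf("unparseable Start_Position at data row %d", bad),
          class = "neocall_format_error")
  }
  ppos_col <- nm[match("protein_position", tolower(nm))]
  aa_col <- nm[match("amino_acids", tolower(nm))]
  ppos <- if (!is.na(ppos_col)) {
    suppressWarnings(as.integer(raw[[ppos_col]]))
  } else rep(NA_integer_, nrow(raw))
  aa <- if (!is.na(aa_col)) raw[[aa_col]] else rep(NA_character_, nrow(raw))
  aa[!is.na(aa) & aa == ""] <- NA_character_
  aa_split <- stringr::str_split_fixed(dplyr::coalesce(aa, "/"), "/", 2)
  aa_split[aa_split == ""] <- NA_character_
  tibble(
    sample_id = raw$Tumor_Sample_Barcode,
    gene_id = raw$Hugo_Symbol,
    chrom = raw$Chromosome,
    genomic_pos = as.integer(pos),
    ref_allele = raw$Reference_Allele,
    alt_allele = raw$Tumor_Seq_Allele2,
    variant_type = raw$Variant_Type,
    variant_classification = maf_class_in(raw$Variant_Classification),
    protein_pos = ppos,
    ref_aa = aa_split[seq_len(nrow(raw)), 1],
    alt_aa = aa_split[seq_len(nrow(raw)), 2]
  )
}

#' @param mutations Mutation tibble (see [read_maf()] for columns).
#' @rdname read_maf
#' @export
write_maf <- function(mutations, path) {
  out <- tibble(
    Hugo_Symbol = mutations$gene_id,
    Chromosome = mutations$chrom,
    Start_Position = mutations$genomic_pos,
    Reference_Allele = mutations$ref_allele,
    Tumor_Seq_Allele2 = mutations$alt_allele,
    Variant_Classification = maf_class_out(mutations$variant_classification,
                                           mutations$variant_type),
    Variant_Type = mutations$variant_type,
    Tumor_Sample_Barcode = mutations$sample_id,
    Protein_position = mutations$protein_pos,
    Amino_acids = ifelse(is.na(mutations$ref_aa), NA_character_,
                         paste0(mutations$ref_aa, "/", mutations$alt_aa))
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Filter common population variants
#'
#' Removes every mutation whose population allele frequency is strictly
#' greater than `threshold` in at least one of the database columns of the
#' AF table (columns starting with `af_`), emulating the common-variant
#' filter against 1000 Genomes / ESP6500 / dbSNP / ExAC. Variants absent
#' from the table, or with all frequencies at or below the threshold, are
#' kept; input order is preserved.
#'
#' @param mutations Mutation tibble.
#' @param af_table Population AF tibble keyed by (`chrom`, `genomic_pos`,
#'   `ref_allele`, `alt_allele`) with one or more `af_*` columns.
#' @param threshold Frequency threshold (default 0.005, i.e. 0.5%).
#' @return The filtered mutation tibble.
#' @export
filter_common_variants <- function(mutations, af_table, threshold = 0.005) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  af_cols <- grep("^af_", names(af_table), value = TRUE)
  if (length(af_cols) == 0) {
    abort("`af_table` has no af_* columns", class = "neocall_format_error")
  }
  af_table <- mutate(af_table, chrom = as.character(.data$chrom),
                     genomic_pos = as.integer(.data$genomic_pos))
  common <- af_table %>%
    filter(dplyr::if_any(all_of(af_cols), ~ !is.na(.x) & .x > threshold)) %>%
    distinct(.data$chrom, .data$genomic_pos, .data$ref_allele,
             .data$alt_allele)
  anti_join(mutations, common,
            by = c("chrom", "genomic_pos", "ref_allele", "alt_allele"))
}

#' Classify a single-nucleotide substitution
#'
#' Maps an ordered base pair to one of the six pyrimidine-reference SNV
#' classes (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`, `T>G`); purine-reference
#' pairs are reverse-complemented first, so e.g. `G>A` reports as `C>T`.
#'
#' @param ref,alt Reference and alternate bases (vectors of `A`/`C`/`G`/`T`,
#'   pairwise distinct).
#' @return Character vector of SNV classes.
#' @export
snv_class <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) {
    abort("`ref` and `alt` must be distinct bases in {A,C,G,T}",
          class = "neocall_parameter_error")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  ref[purine] <- comp[ref[purine]]
  alt[purine] <- comp[alt[purine]]
  paste0(ref, ">", alt)
}

#' Summarize the mutation landscape of a cohort
#'
#' Tabulates counts by variant classification, by variant type, and by the
#' six SNV classes; per-sample nonsilent burden; and genes ranked by the
#' number of distinct samples carrying at least one nonsilent mutation
#' (ties broken lexicographically). "Nonsilent" covers missense, nonsense,
#' nonstop, splice-site, frameshift and in-frame-indel classes.
#'
#' @param mutations Mutation tibble.
#' @param top_k Number of top genes to keep (default 10).
#' @return An object of class `neo_landscape`: a list of tibbles
#'   `classification_counts`, `type_counts`, `snv_class_counts`,
#'   `per_sample`, `top_genes`.
#' @export
summarize_landscape <- function(mutations, top_k = 10) {
  classification_counts <- mutations %>%
    count(variant_classification = factor(.data$variant_classification,
                                          levels = VARIANT_CLASSES),
          .drop = FALSE, name = "n") %>%
    mutate(variant_classification = as.character(.data$variant_classification))
  type_counts <- mutations %>%
    count(variant_type = factor(.data$variant_type,
                                levels = c("SNP", "INS", "DEL")),
          .drop = FALSE, name = "n") %>%
    mutate(variant_type = as.character(.data$variant_type))
  snvs <- filter(mutations, .data$variant_type == "SNP")
  snv_counts <- if (nrow(snvs) > 0) {
    tibble(snv_class = factor(snv_class(snvs$ref_allele, snvs$alt_allele),
                              levels = SNV_CLASSES)) %>%
      count(.data$snv_class, .drop = FALSE, name = "n") %>%
      mutate(snv_class = as.character(.data$snv_class))
  } else {
    tibble(snv_class = SNV_CLASSES, n = 0L)
  }
  nonsilent <- filter(mutations,
                      .data$variant_classification %in% NONSILENT_CLASSES)
  per_sample <- mutations %>%
    distinct(.data$sample_id) %>%
    left_join(count(nonsilent, .data$sample_id, name = "n_nonsilent"),
              by = "sample_id") %>%
    mutate(n_nonsilent = dplyr::coalesce(.data$n_nonsilent, 0L)) %>%
    arrange(.data$sample_id)
  top_genes <- nonsilent %>%
    distinct(.data$gene_id, .data$sample_id) %>%
    count(.data$gene_id, name = "n_samples") %>%
    arrange(desc(.data$n_samples), .data$gene_id) %>%
    head(top_k)
  structure(list(classification_counts = classification_counts,
                 type_counts = type_counts,
                 snv_class_counts = snv_counts,
                 per_sample = per_sample,
                 top_genes = top_genes,
                 n_mutations = nrow(mutations)),
            class = "neo_landscape")
}

#' @export
print.neo_landscape <- function(x, ...) {
  cat(sprintf("<neo_landscape> %d mutations in %d samples\n",
              x$n_mutations, nrow(x$per_sample)))
  cat("top mutated genes:",
      paste(head(x$top_genes$gene_id, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Binary gene-by-sample mutation matrix
#'
#' Entry (g, s) is 1 when sample s carries at least one nonsilent mutation
#' in gene g. The column set is the cohort sample set, so call-free samples
#' appear as zero columns when `samples` is supplied.
#'
#' @param mutations Mutation tibble.
#' @param genes Optional gene restriction (rows).
#' @param samples Optional sample universe (columns); defaults to the
#'   samples present in `mutations`.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
gene_sample_matrix <- function(mutations, genes = NULL, samples = NULL) {
  nonsilent <- filter(mutations,
                      .data$variant_classification %in% NONSILENT_CLASSES)
  samples <- samples %||% sort(unique(mutations$sample_id))
  genes <- genes %||% sort(unique(nonsilent$gene_id))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  hits <- nonsilent %>%
    filter(.data$gene_id %in% genes, .data$sample_id %in% samples) %>%
    distinct(.data$gene_id, .data$sample_id)
  m[cbind(hits$gene_id, hits$sample_id)] <- 1L
  m
}
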