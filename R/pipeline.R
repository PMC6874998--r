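# fixed-precision TSV writer: doubles serialized with 9 significant digits
# so repeated runs are byte-identical across platforms
write_tsv_fixed <- function(df, path) {
  df <- dplyr::mutate(df, across(dplyr::where(is.double),
                                 ~ formatC(.x, digits = 9, format = "g")))
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write a proteome FASTA
#'
#' Thin wrappers over Biostrings keyed by `gene_id`.
#'
#' @param proteome Proteome tibble (`gene_id`, `protein`).
#' @param path FASTA file path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required for FASTA I/O")
  }
  aa <- Biostrings::AAStringSet(setNames(proteome$protein,
                                         proteome$gene_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required for FASTA I/O")
  }
  aa <- Biostrings::readAAStringSet(path)
  tibble(gene_id = names(aa), protein = as.character(aa))
}

#' Read a cohort configuration from YAML
#'
#' Flat-key YAML mirroring [cohort_config()]; `hotspots`,
#' `exclusive_pairs` and `hla_frequencies` are lists of records. `seed`
#' is required; unknown keys raise a validation error naming them.
#'
#' @param path YAML file path.
#' @return A validated `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "neocall_config_error")
  }
  if (is.null(cfg$seed)) {
    abort("config validation failed: field `seed` is required",
          class = "neocall_config_error")
  }
  for (f in c("hotspots", "exclusive_pairs", "hla_frequencies")) {
    if (!is.null(cfg[[f]])) cfg[[f]] <- bind_rows(lapply(cfg[[f]],
                                                         as_tibble))
  }
  if (!is.null(cfg$class_mix)) cfg$class_mix <- unlist(cfg$class_mix)
  do.call(cohort_config, cfg)
}

write_manifest <- function(out_dir, stage, seed, params, counts, files) {
  manifest <- list(
    package = "neocall",
    version = as.character(utils::packageVersion("neocall")),
    stage = stage, seed = seed, params = params, counts = counts,
    files = as.list(tools::md5sum(files[file.exists(files)]))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Simulate a cohort and write all pipeline inputs
#'
#' Generates the synthetic study inputs (proteome FASTA, mutation MAF,
#' metadata TSV, HLA genotype TSV, population AF TSV) plus the
#' ground-truth binding model (one PSSM file per allele and length, with
#' a JSON sidecar), and a run manifest with record counts and file
#' digests.
#'
#' @param config A [cohort_config()] object or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @param proteome Optional proteome tibble; defaults to
#'   [default_proteome()] seeded from the config.
#' @param common_fraction Fraction of variants seeded as common in the
#'   population AF table.
#' @param motif_strength,noise_sd Ground-truth binding model parameters.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(config, out_dir, proteome = NULL,
                         common_fraction = 0.05, motif_strength = 1,
                         noise_sd = 0.05) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  proteome <- proteome %||% default_proteome(config$seed)
  cohort <- simulate_cohort(proteome, config)
  af <- simulate_population_af(cohort$mutations, common_fraction,
                               seed = config$seed)
  truth <- simulate_binding_truth(config$hla_frequencies$allele,
                                  motif_strength = motif_strength,
                                  noise_sd = noise_sd, seed = config$seed)
  paths <- list(
    proteome = file.path(out_dir, "proteome.fasta"),
    maf = file.path(out_dir, "mutations.maf"),
    metadata = file.path(out_dir, "metadata.tsv"),
    hla = file.path(out_dir, "hla_genotypes.tsv"),
    af = file.path(out_dir, "population_af.tsv")
  )
  write_proteome_fasta(proteome, paths$proteome)
  write_maf(cohort$mutations, paths$maf)
  write_tsv_fixed(cohort$metadata, paths$metadata)
  write_tsv_fixed(cohort$genotypes, paths$hla)
  write_tsv_fixed(af, paths$af)
  truth_dir <- file.path(out_dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  truth_files <- character(0)
  for (p in truth$pssms) {
    f <- file.path(truth_dir, sprintf("%s_L%d.pssm",
                                      gsub("[^A-Za-z0-9]", "_", p$allele),
                                      p$length))
    write_pssm(p, f)
    truth_files <- c(truth_files, f)
  }
  meta_path <- file.path(truth_dir, "truth.json")
  jsonlite::write_json(list(alleles = truth$alleles,
                            lengths = truth$lengths,
                            noise_sd = truth$noise_sd,
                            baseline = truth$baseline),
                       meta_path, auto_unbox = TRUE, digits = NA)
  stage_log("simulate", "%d samples, %d mutations, %d genotype rows",
            config$n_samples, nrow(cohort$mutations),
            nrow(cohort$genotypes))
  write_manifest(out_dir, "simulate", config$seed,
                 params = list(common_fraction = common_fraction,
                               motif_strength = motif_strength,
                               noise_sd = noise_sd,
                               n_samples = config$n_samples,
                               burden_median = config$burden_median),
                 counts = list(mutations = nrow(cohort$mutations),
                               samples = config$n_samples,
                               af_rows = nrow(af)),
                 files = c(unlist(paths), truth_files, meta_path))
  invisible(c(paths, list(truth_dir = truth_dir)))
}

# rebuild a binding_truth object from the files run_simulate() wrote
read_binding_truth <- function(truth_dir) {
  meta <- jsonlite::read_json(file.path(truth_dir, "truth.json"),
                              simplifyVector = TRUE)
  files <- list.files(truth_dir, pattern = "\\.pssm$", full.names = TRUE)
  pssms <- lapply(files, read_pssm)
  names(pssms) <- vapply(pssms, function(p) paste(p$allele, p$length,
                                                  sep = "|"), character(1))
  structure(list(pssms = pssms, alleles = meta$alleles,
                 lengths = meta$lengths, noise_sd = meta$noise_sd,
                 baseline = meta$baseline), class = "binding_truth")
}

#' Run the neoantigen-calling pipeline on files
#'
#' Executes the calling stages in order — common-variant filter, peptide
#' enumeration, multi-tool binding prediction, consensus calling — and
#' writes the calls TSV plus a manifest with per-stage record counts.
#'
#' @param maf Path to the mutation MAF.
#' @param hla Path to the HLA genotype TSV (`sample_id`, `allele`).
#' @param proteome Path to the proteome FASTA.
#' @param af_table Path to the population AF TSV.
#' @param truth_dir Directory of ground-truth PSSMs written by
#'   [run_simulate()].
#' @param out_dir Output directory.
#' @param ic50_threshold,min_tools Consensus parameters (defaults 500 nM,
#'   2 tools).
#' @param lengths Peptide lengths (default 8:11).
#' @param n_tools Number of simulated prediction tools (default 5).
#' @param af_threshold Common-variant frequency threshold (default
#'   0.005).
#' @param seed Seed for the tools' noise streams.
#' @return Invisibly, the path of the calls TSV.
#' @export
run_call <- function(maf, hla, proteome, af_table, truth_dir, out_dir,
                     ic50_threshold = 500, min_tools = 2, lengths = 8:11,
                     n_tools = 5, af_threshold = 0.005, seed = 1) {
  if (min_tools > n_tools) {
    abort(sprintf("min_tools (%d) exceeds the configured tool count (%d)",
                  min_tools, n_tools), class = "neocall_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mutations <- read_maf(maf)
  genotypes <- readr::read_tsv(hla, show_col_types = FALSE,
                               progress = FALSE)
  prot <- read_proteome_fasta(proteome)
  af <- readr::read_tsv(af_table, show_col_types = FALSE, progress = FALSE)
  stage_log("filter", "%d mutations in", nrow(mutations))
  kept <- filter_common_variants(mutations, af, threshold = af_threshold)
  stage_log("filter", "%d mutations kept", nrow(kept))
  pairs <- cohort_peptide_pairs(kept, prot, lengths = lengths)
  stage_log("peptides", "%d peptide pairs (%d non-missense skipped)",
            nrow(pairs), attr(pairs, "skipped_nonmissense"))
  truth <- read_binding_truth(truth_dir)
  tools <- simulate_tools(truth, n_tools = n_tools, seed = seed)
  predictions <- predict_bindings(pairs, genotypes, tools)
  stage_log("predict", "%d predictions", nrow(predictions))
  calls <- call_neoantigens(predictions, pairs, genotypes,
                            ic50_threshold = ic50_threshold,
                            min_tools = min_tools)
  stage_log("consensus", "%d calls", nrow(calls))
  calls_path <- file.path(out_dir, "neoantigen_calls.tsv")
  write_tsv_fixed(calls, calls_path)
  write_manifest(out_dir, "call", seed,
                 params = list(ic50_threshold = ic50_threshold,
                               min_tools = min_tools,
                               lengths = lengths, n_tools = n_tools,
                               af_threshold = af_threshold),
                 counts = list(mutations_in = nrow(mutations),
                               mutations_kept = nrow(kept),
                               pairs = nrow(pairs),
                               predictions = nrow(predictions),
                               calls = nrow(calls)),
                 files = calls_path)
  invisible(calls_path)
}

#' Run the cohort statistics stage on files
#'
#' Computes the five cohort-level outputs — per-sample load, recurrent
#' neoantigens, greedy panel with cumulative coverage, mutual-exclusivity
#' screen, subgroup comparisons — and writes one TSV per analysis plus a
#' manifest. Stratifiers with fewer than two usable levels are skipped
#' with a message; the others are still emitted.
#'
#' @param calls Path to the calls TSV from [run_call()].
#' @param maf Path to the mutation MAF.
#' @param metadata Path to the metadata TSV.
#' @param out_dir Output directory.
#' @param min_samples Recurrence threshold (default 2).
#' @param k_panel Greedy panel size (default 10).
#' @param identity Neoantigen identity granularity.
#' @param correction Multiple-testing correction for the exclusivity
#'   screen.
#' @param exclusivity_genes Genes to screen pairwise; defaults to the 20
#'   most frequently mutated.
#' @return Invisibly, a named list of output paths.
#' @export
run_stats <- function(calls, maf, metadata, out_dir, min_samples = 2,
                      k_panel = 10,
                      identity = c("peptide", "peptide_allele"),
                      correction = c("none", "benjamini_hochberg"),
                      exclusivity_genes = NULL) {
  identity <- match.arg(identity)
  correction <- match.arg(correction)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calls_df <- readr::read_tsv(calls, show_col_types = FALSE,
                              progress = FALSE)
  mutations <- read_maf(maf)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE,
                          progress = FALSE)
  loads <- neoantigen_load(calls_df, mutations, meta, identity = identity)
  rec <- recurrent_neoantigens(calls_df, min_samples = min_samples,
                               identity = identity)
  panel <- select_panel_greedy(rec, k = k_panel)
  coverage <- panel_coverage(calls_df, panel, meta$sample_id,
                             identity = identity)
  stage_log("stats", "panel of %d covers %.1f%% of %d samples",
            nrow(panel), 100 * coverage, nrow(meta))
  gsm <- gene_sample_matrix(mutations, samples = meta$sample_id)
  if (is.null(exclusivity_genes)) {
    freq <- sort(rowSums(gsm), decreasing = TRUE)
    exclusivity_genes <- names(freq)[seq_len(min(20, length(freq)))]
  }
  excl <- mutual_exclusivity_screen(gsm[exclusivity_genes, , drop = FALSE],
                                    correction = correction)
  subgroups <- purrr::map_dfr(
    c("age_group", "sex", "lauren", "stage", "location"),
    function(strat) {
      tryCatch(compare_subgroups(loads, strat),
               neocall_stratification_error = function(e) {
                 stage_log("stats", "skipping stratifier %s: %s", strat,
                           conditionMessage(e))
                 tibble()
               })
    })
  paths <- list(load = file.path(out_dir, "load.tsv"),
                recurrence = file.path(out_dir, "recurrence.tsv"),
                panel = file.path(out_dir, "panel.tsv"),
                exclusivity = file.path(out_dir, "exclusivity.tsv"),
                subgroups = file.path(out_dir, "subgroups.tsv"))
  write_tsv_fixed(as_tibble(loads), paths$load)
  write_tsv_fixed(select(rec, -"carriers"), paths$recurrence)
  panel_out <- mutate(panel,
                      coverage_fraction = .data$n_covered_cum / nrow(meta))
  write_tsv_fixed(panel_out, paths$panel)
  write_tsv_fixed(excl, paths$exclusivity)
  write_tsv_fixed(subgroups, paths$subgroups)
  write_manifest(out_dir, "stats", NA,
                 params = list(min_samples = min_samples,
                               k_panel = k_panel, identity = identity,
                               correction = correction),
                 counts = list(samples = nrow(meta),
                               calls = nrow(calls_df),
                               recurrent = nrow(rec),
                               panel_size = nrow(panel),
                               panel_coverage = coverage),
                 files = unlist(paths))
  invisible(paths)
}
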