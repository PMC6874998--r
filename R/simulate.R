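#' Simulate a synthetic proteome
#'
#' Generates a set of protein sequences over the 20-letter amino-acid
#' alphabet. The proteome is the coordinate system every downstream stage
#' (mutation placement, peptide enumeration) operates in; it stands in for a
#' real reference protein set so the whole pipeline can be exercised without
#' downloads.
#'
#' @param n_genes Number of genes to generate (ignored when `gene_ids` is
#'   given).
#' @param min_len,max_len Inclusive bounds on protein length; lengths are
#'   drawn uniformly. Must satisfy `8 <= min_len <= max_len`.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param gene_ids Optional character vector of gene identifiers; its length
#'   overrides `n_genes`.
#' @param lengths Optional integer vector of per-gene lengths (recycled
#'   against `gene_ids`); overrides the uniform draw.
#' @param force_residues Optional tibble with columns `gene_id`,
#'   `protein_pos`, `aa`: residues pinned to a fixed value, used to make
#'   hotspot reference residues consistent with the proteome.
#' @return A tibble with columns `gene_id`, `protein` (sequence string).
#' @examples
#' simulate_proteome(3, 50, 60, seed = 1)
#' @export
simulate_proteome <- function(n_genes = NULL, min_len = 100, max_len = 500,
                              seed = 1, gene_ids = NULL, lengths = NULL,
                              force_residues = NULL) {
  if (is.null(gene_ids)) {
    assert_scalar_number(n_genes, "n_genes", lower = 1)
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
  }
  if (anyDuplicated(gene_ids)) {
    abort("`gene_ids` must be unique", class = "neocall_parameter_error")
  }
  if (is.null(lengths)) {
    if (!(min_len >= 8 && min_len <= max_len)) {
      abort("need 8 <= min_len <= max_len", class = "neocall_parameter_error")
    }
  } else {
    if (any(lengths < 8)) {
      abort("all `lengths` must be >= 8", class = "neocall_parameter_error")
    }
    lengths <- rep_len(as.integer(lengths), length(gene_ids))
  }
  withr::with_seed(child_seed(seed, 11), {
    if (is.null(lengths)) {
      pool <- seq.int(min_len, max_len)
      lengths <- pool[sample.int(length(pool), length(gene_ids),
                                 replace = TRUE)]
    }
    seqs <- vapply(lengths, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  prot <- tibble(gene_id = gene_ids, protein = seqs)
  if (!is.null(force_residues)) {
    for (i in seq_len(nrow(force_residues))) {
      g <- force_residues$gene_id[i]
      p <- force_residues$protein_pos[i]
      j <- match(g, prot$gene_id)
      if (is.na(j) || p > nchar(prot$protein[j])) {
        abort(sprintf("cannot pin residue: gene %s position %d not in proteome",
                      g, p), class = "neocall_consistency_error")
      }
      substr(prot$protein[j], p, p) <- force_residues$aa[i]
    }
  }
  prot
}

#' Default HLA class-I allele frequency table
#'
#' A stylized set of common East-Asian class-I alleles with per-locus
#' frequencies summing to 1, in the 4-digit `HLA-A02:01` naming convention.
#'
#' @return A tibble with columns `allele`, `locus`, `frequency`.
#' @export
default_hla_frequencies <- function() {
  tibble(
    allele = c("HLA-A02:01", "HLA-A11:01", "HLA-A24:02",
               "HLA-B07:02", "HLA-B35:01", "HLA-B58:01",
               "HLA-C07:02", "HLA-C03:03", "HLA-C07:01"),
    locus = rep(c("A", "B", "C"), each = 3),
    frequency = c(0.35, 0.30, 0.35,
                  0.30, 0.35, 0.35,
                  0.40, 0.30, 0.30)
  )
}

#' Default hotspot driver mutations
#'
#' Recurrent gastric-cancer driver substitutions (e.g. TP53 R175H, PIK3CA
#' H1047R, KRAS G12D) with cohort prevalences in the few-percent range,
#' plus higher-prevalence TP53/ARID1A-axis drivers so that gene-level
#' mutual-exclusivity structure can be realized.
#'
#' @return A tibble with columns `gene_id`, `protein_pos`, `ref_aa`,
#'   `alt_aa`, `prevalence`.
#' @export
default_hotspots <- function() {
  tibble::tribble(
    ~gene_id,  ~protein_pos, ~ref_aa, ~alt_aa, ~prevalence,
    "TP53",     175L, "R", "H", 0.180,
    "TP53",     273L, "R", "H", 0.150,
    "TP53",     282L, "R", "W", 0.140,
    "PIK3CA",  1047L, "H", "R", 0.120,
    "KRAS",      12L, "G", "D", 0.017,
    "KRAS",      13L, "G", "D", 0.016,
    "PGM5",      98L, "I", "V", 0.028,
    "ERBB3",    104L, "V", "M", 0.012,
    "C6",       817L, "K", "T", 0.006,
    "TRIM49C",  327L, "S", "R", 0.011,
    "OR4C16",   135L, "S", "R", 0.007,
    "CDH1",     201L, "D", "N", 0.180,
    "KMT2D",    912L, "Q", "K", 0.170,
    "RYR1",     614L, "E", "K", 0.130,
    "ARID1A",   548L, "P", "L", 0.200
  )
}

#' Default mutually exclusive gene pairs
#'
#' TP53 against five genes reported as mutated exclusively with it in
#' gastric cancer, each with a target odds ratio below 1.
#'
#' @return A tibble with columns `gene_a`, `gene_b`, `odds_ratio`.
#' @export
default_exclusive_pairs <- function() {
  tibble(
    gene_a = "TP53",
    gene_b = c("CDH1", "KMT2D", "RYR1", "PIK3CA", "ARID1A"),
    odds_ratio = 0.25
  )
}

#' Default synthetic proteome for the cohort generator
#'
#' Builds a proteome containing the default hotspot genes (at roughly their
#' real protein lengths, with hotspot reference residues pinned) plus
#' `n_background` generic genes.
#'
#' @param seed Integer seed.
#' @param n_background Number of generic background genes. The default of
#'   2000 genes of 500 residues keeps per-gene background mutation rates
#'   realistic (a few percent per sample) so that driver-gene structure is
#'   carried by the hotspots, not by uniform background hits.
#' @param background_length Length of each background gene.
#' @return A proteome tibble (see [simulate_proteome()]).
#' @export
default_proteome <- function(seed = 1, n_background = 2000,
                             background_length = 500L) {
  drivers <- tibble(
    gene_id = c("TP53", "PIK3CA", "KRAS", "PGM5", "ERBB3", "C6", "TRIM49C",
                "OR4C16", "CDH1", "KMT2D", "RYR1", "ARID1A"),
    length = c(393L, 1068L, 189L, 567L, 1342L, 934L, 452L,
               311L, 882L, 1537L, 1061L, 1285L)
  )
  bg_ids <- sprintf("G%04d", seq_len(n_background))
  hs <- default_hotspots()
  simulate_proteome(
    seed = seed,
    gene_ids = c(drivers$gene_id, bg_ids),
    lengths = c(drivers$length, rep(as.integer(background_length),
                                    n_background)),
    force_residues = dplyr::select(hs, gene_id = "gene_id",
                                   protein_pos = "protein_pos", aa = "ref_aa")
  )
}

#' Build and validate a cohort simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator into a validated
#' list. Defaults reproduce the statistical structure the analysis assumes:
#' an overdispersed per-sample nonsilent burden with median 66, a C>T
#' dominated substitution spectrum, hotspot driver mutations, TP53-centered
#' mutual exclusivity, a multiplicative burden increase for patients aged
#' 60 and over, and HLA genotypes drawn per locus from an allele-frequency
#' table.
#'
#' @param n_samples Number of tumor samples.
#' @param burden_median Target cohort median of the per-sample nonsilent
#'   mutation count.
#' @param burden_dispersion Negative-binomial size parameter (smaller =
#'   more overdispersed).
#' @param ct_fraction Fraction of SNVs in the C>T class; the remaining five
#'   classes share the rest uniformly.
#' @param hotspots Tibble of hotspot substitutions (`gene_id`,
#'   `protein_pos`, `ref_aa`, `alt_aa`, `prevalence`).
#' @param exclusive_pairs Tibble of gene pairs (`gene_a`, `gene_b`,
#'   `odds_ratio` < 1) whose co-mutation is thinned to the target odds
#'   ratio.
#' @param age_effect Multiplicative factor on the expected burden for
#'   samples with age >= 60.
#' @param hla_frequencies Allele-frequency tibble (`allele`, `locus`,
#'   `frequency`); frequencies must sum to 1 per locus.
#' @param silent_fraction Expected silent SNVs per nonsilent mutation.
#' @param class_mix Named probabilities over nonsilent classes used for
#'   background mutations.
#' @param seed Master seed; all component streams derive from it by fixed
#'   offsets.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 200,
                          burden_median = 66,
                          burden_dispersion = 2,
                          ct_fraction = 0.45,
                          hotspots = default_hotspots(),
                          exclusive_pairs = default_exclusive_pairs(),
                          age_effect = 1.5,
                          hla_frequencies = default_hla_frequencies(),
                          silent_fraction = 0.38,
                          class_mix = c(missense = 0.8516, nonsense = 0.0575,
                                        nonstop = 0.0011, splice_site = 0.0263,
                                        frameshift = 0.0423,
                                        in_frame_indel = 0.0212),
                          seed = 1) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(burden_median, "burden_median", lower = 1e-9)
  assert_scalar_number(burden_dispersion, "burden_dispersion", lower = 1e-9)
  assert_scalar_number(ct_fraction, "ct_fraction", lower = 0, upper = 1)
  assert_scalar_number(age_effect, "age_effect", lower = 0)
  assert_scalar_number(seed, "seed")
  if (nrow(hotspots) > 0 &&
      (any(hotspots$prevalence < 0) || any(hotspots$prevalence > 1))) {
    abort("hotspot prevalences must lie in [0, 1]",
          class = "neocall_parameter_error")
  }
  if (nrow(exclusive_pairs) > 0 && any(exclusive_pairs$odds_ratio <= 0)) {
    abort("exclusive-pair odds ratios must be > 0",
          class = "neocall_parameter_error")
  }
  hla_frequencies <- as_tibble(hla_frequencies)
  if (is.null(hla_frequencies$locus)) {
    hla_frequencies$locus <- sub("^HLA-([ABC]).*$", "\\1",
                                 hla_frequencies$allele)
  }
  bad <- hla_frequencies %>%
    group_by(.data$locus) %>%
    summarise(total = sum(.data$frequency), .groups = "drop") %>%
    filter(abs(.data$total - 1) > 1e-9)
  if (nrow(bad) > 0) {
    abort(sprintf("HLA frequencies must sum to 1 per locus (off at: %s)",
                  paste(bad$locus, collapse = ", ")),
          class = "neocall_parameter_error")
  }
  if (any(hla_frequencies$frequency < 0 | hla_frequencies$frequency > 1)) {
    abort("HLA frequencies must lie in [0, 1]",
          class = "neocall_parameter_error")
  }
  class_mix <- class_mix / sum(class_mix)
  cfg <- list(n_samples = as.integer(n_samples),
              burden_median = burden_median,
              burden_dispersion = burden_dispersion,
              ct_fraction = ct_fraction,
              hotspots = as_tibble(hotspots),
              exclusive_pairs = as_tibble(exclusive_pairs),
              age_effect = age_effect,
              hla_frequencies = hla_frequencies,
              silent_fraction = silent_fraction,
              class_mix = class_mix,
              seed = seed)
  structure(cfg, class = "cohort_config")
}

# clinical category probabilities for the metadata model (gastric-cancer
# cohort marginals: ~62% aged >= 60, ~70% male, intestinal-dominant Lauren
# mix, stage III-heavy staging, antrum/body/cardia locations)
sim_metadata <- function(n_samples, seed) {
  ids <- sprintf("S%0*d", max(4, nchar(n_samples)), seq_len(n_samples))
  withr::with_seed(child_seed(seed, 17), {
    age <- pmax(25, pmin(90, round(rnorm(n_samples, mean = 63.5, sd = 11))))
    sex <- sample(c("male", "female"), n_samples, replace = TRUE,
                  prob = c(0.703, 0.297))
    lauren <- sample(c("intestinal", "diffuse", "mixed", NA), n_samples,
                     replace = TRUE, prob = c(32, 28, 10, 4) / 74)
    stage <- sample(c("I", "II", "III", "IV"), n_samples, replace = TRUE,
                    prob = c(7, 7, 51, 9) / 74)
    location <- sample(c("antrum", "body", "cardia", "other"), n_samples,
                       replace = TRUE, prob = c(17, 31, 22, 4) / 74)
  })
  tibble(sample_id = ids, age = as.integer(age), sex = sex,
         lauren = lauren, stage = stage, location = location)
}

# base NB mean calibrated so the age-effect mixture has the target median
calibrate_burden_mu <- function(target_median, size, effects) {
  g <- function(mu) mean(pnbinom(target_median, size = size,
                                 mu = mu * effects)) - 0.5
  uniroot(g, lower = target_median / 20, upper = target_median * 20,
          tol = 1e-8)$root
}

sim_hla_genotypes <- function(metadata, hla_frequencies, seed) {
  loci <- split(hla_frequencies, hla_frequencies$locus)
  n <- nrow(metadata)
  withr::with_seed(child_seed(seed, 29), {
    per_locus <- lapply(loci, function(tab) {
      a1 <- sample(tab$allele, n, replace = TRUE, prob = tab$frequency)
      a2 <- sample(tab$allele, n, replace = TRUE, prob = tab$frequency)
      cbind(a1, a2)
    })
  })
  alleles <- do.call(cbind, per_locus)
  purrr::map_dfr(seq_len(n), function(i) {
    tibble(sample_id = metadata$sample_id[i],
           allele = sort(unique(alleles[i, ])))
  })
}

# draws an SNV class honoring ct_fraction, then orients it onto a random
# strand (pyrimidine-reference classes cover both orientations)
sim_snv_bases <- function(n, ct_fraction) {
  probs <- rep((1 - ct_fraction) / 5, 6)
  probs[SNV_CLASSES == "C>T"] <- ct_fraction
  cls <- sample(SNV_CLASSES, n, replace = TRUE, prob = probs)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  flip <- runif(n) < 0.5
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  list(ref = ref, alt = alt)
}

#' Simulate a tumor cohort
#'
#' Draws per-sample metadata, HLA genotypes, and somatic mutations with the
#' configured statistical structure: negative-binomial nonsilent burden
#' (median-calibrated, multiplied by `age_effect` for samples aged >= 60),
#' uniform placement of background mutations over the proteome, a C>T
#' dominated substitution spectrum, independent per-sample hotspot
#' carriage, and co-mutation thinning that realizes the configured
#' mutual-exclusivity odds ratios.
#'
#' @param proteome Proteome tibble from [simulate_proteome()].
#' @param config A [cohort_config()] object.
#' @return A list with tibbles `mutations`, `metadata`, `genotypes`.
#' @export
simulate_cohort <- function(proteome, config) {
  stopifnot(inherits(config, "cohort_config"))
  # hotspot consistency with proteome
  hs <- config$hotspots
  if (nrow(hs) > 0) {
    for (i in seq_len(nrow(hs))) {
      j <- match(hs$gene_id[i], proteome$gene_id)
      if (is.na(j)) {
        abort(sprintf("hotspot gene %s absent from proteome", hs$gene_id[i]),
              class = "neocall_consistency_error")
      }
      obs <- substr(proteome$protein[j], hs$protein_pos[i], hs$protein_pos[i])
      if (obs != hs$ref_aa[i]) {
        abort(sprintf(
          "hotspot %s p.%d expects %s but proteome has %s",
          hs$gene_id[i], hs$protein_pos[i], hs$ref_aa[i], obs),
          class = "neocall_consistency_error")
      }
    }
  }
  metadata <- sim_metadata(config$n_samples, config$seed)
  genotypes <- sim_hla_genotypes(metadata, config$hla_frequencies,
                                 config$seed)
  n <- config$n_samples
  effects <- ifelse(metadata$age >= 60, config$age_effect, 1)

  gene_len <- nchar(proteome$protein)
  gene_offset <- c(0, cumsum(3L * gene_len + 1000L))[seq_along(gene_len)]

  withr::with_seed(child_seed(config$seed, 31), {
    mu <- calibrate_burden_mu(config$burden_median, config$burden_dispersion,
                              effects)
    burden <- rnbinom(n, size = config$burden_dispersion, mu = mu * effects)

    # hotspot carriage, independent per sample
    carriage <- matrix(FALSE, nrow = n, ncol = nrow(hs))
    if (nrow(hs) > 0) {
      for (k in seq_len(nrow(hs))) {
        carriage[, k] <- runif(n) < hs$prevalence[k]
      }
    }

    n_hot <- if (nrow(hs) > 0) rowSums(carriage) else rep(0L, n)
    n_background <- pmax(0L, burden - n_hot)
    n_silent <- stats::rpois(n, config$silent_fraction * burden)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sid <- metadata$sample_id[i]
      out <- list()
      if (nrow(hs) > 0 && any(carriage[i, ])) {
        idx <- which(carriage[i, ])
        bases <- sim_snv_bases(length(idx), config$ct_fraction)
        gi <- match(hs$gene_id[idx], proteome$gene_id)
        out$hot <- tibble(
          sample_id = sid, gene_id = hs$gene_id[idx], chrom = "1",
          genomic_pos = gene_offset[gi] + 3L * (hs$protein_pos[idx] - 1L) + 1L,
          ref_allele = bases$ref, alt_allele = bases$alt,
          variant_type = "SNP", variant_classification = "missense",
          protein_pos = as.integer(hs$protein_pos[idx]),
          ref_aa = hs$ref_aa[idx], alt_aa = hs$alt_aa[idx])
      }
      nb <- n_background[i]
      if (nb > 0) {
        cls <- sample(names(config$class_mix), nb, replace = TRUE,
                      prob = config$class_mix)
        gi <- sample.int(nrow(proteome), nb, replace = TRUE,
                         prob = gene_len)
        pos <- floor(runif(nb) * gene_len[gi]) + 1L
        has_protein <- cls %in% c("missense", "nonsense", "nonstop")
        pos[cls == "nonstop"] <- gene_len[gi[cls == "nonstop"]]
        ref_aa <- substr(proteome$protein[gi], pos, pos)
        alt_aa <- vapply(ref_aa, function(a) {
          sample(setdiff(AA_ALPHABET, a), 1)
        }, character(1), USE.NAMES = FALSE)
        alt_aa[cls == "nonsense"] <- "*"
        is_indel <- cls %in% c("frameshift", "in_frame_indel")
        vt <- ifelse(is_indel,
                     sample(c("INS", "DEL"), nb, replace = TRUE), "SNP")
        bases <- sim_snv_bases(nb, config$ct_fraction)
        bases$ref[is_indel] <- ifelse(vt[is_indel] == "DEL", "AC", "-")
        bases$alt[is_indel] <- ifelse(vt[is_indel] == "DEL", "-", "AC")
        out$bg <- tibble(
          sample_id = sid, gene_id = proteome$gene_id[gi], chrom = "1",
          genomic_pos = gene_offset[gi] + 3L * (pos - 1L) + 1L,
          ref_allele = bases$ref, alt_allele = bases$alt,
          variant_type = vt, variant_classification = cls,
          protein_pos = ifelse(has_protein, as.integer(pos), NA_integer_),
          ref_aa = ifelse(has_protein, ref_aa, NA_character_),
          alt_aa = ifelse(has_protein, alt_aa, NA_character_))
      }
      ns <- n_silent[i]
      if (ns > 0) {
        gi <- sample.int(nrow(proteome), ns, replace = TRUE, prob = gene_len)
        pos <- floor(runif(ns) * gene_len[gi]) + 1L
        bases <- sim_snv_bases(ns, config$ct_fraction)
        out$silent <- tibble(
          sample_id = sid, gene_id = proteome$gene_id[gi], chrom = "1",
          genomic_pos = gene_offset[gi] + 3L * (pos - 1L) + 2L,
          ref_allele = bases$ref, alt_allele = bases$alt,
          variant_type = "SNP", variant_classification = "silent",
          protein_pos = NA_integer_, ref_aa = NA_character_,
          alt_aa = NA_character_)
      }
      rows[[i]] <- bind_rows(out)
    }
  })
  mutations <- bind_rows(rows) %>%
    distinct(.data$sample_id, .data$chrom, .data$genomic_pos,
             .data$alt_allele, .keep_all = TRUE)
  # realize mutual exclusivity on the gene-level mutation status: thin
  # co-mutated samples (background and hotspot hits alike) down to the
  # configured odds ratio by dropping one gene's mutations at random
  if (nrow(config$exclusive_pairs) > 0) {
    withr::with_seed(child_seed(config$seed, 43), {
      all_samples <- metadata$sample_id
      for (p in seq_len(nrow(config$exclusive_pairs))) {
        ga <- config$exclusive_pairs$gene_a[p]
        gb <- config$exclusive_pairs$gene_b[p]
        target <- config$exclusive_pairs$odds_ratio[p]
        nonsil <- mutations$variant_classification %in% NONSILENT_CLASSES
        sa <- unique(mutations$sample_id[nonsil & mutations$gene_id == ga])
        sb <- unique(mutations$sample_id[nonsil & mutations$gene_id == gb])
        in_a <- all_samples %in% sa
        in_b <- all_samples %in% sb
        a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
        cc <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
        if (a == 0) next
        or_q <- function(q) {
          (a * q * d) / ((b + a * (1 - q) / 2) * (cc + a * (1 - q) / 2))
        }
        if (!is.finite(or_q(1)) || or_q(1) <= target) next
        q <- if (or_q(0) >= target) 0 else
          uniroot(function(q) or_q(q) - target, c(0, 1), tol = 1e-9)$root
        co <- all_samples[in_a & in_b]
        drop_side <- runif(length(co))
        drop_gene <- ifelse(runif(length(co)) < 0.5, ga, gb)
        for (m in seq_along(co)) {
          if (drop_side[m] < 1 - q) {
            mutations <- mutations[!(mutations$sample_id == co[m] &
                                       mutations$gene_id == drop_gene[m]), ]
          }
        }
      }
    })
  }
  mutations <- arrange(mutations, .data$sample_id, .data$gene_id,
                       .data$genomic_pos)
  list(mutations = mutations, metadata = metadata, genotypes = genotypes)
}

#' Simulate a population allele-frequency table
#'
#' Assigns population allele frequencies across four database columns
#' (emulating 1000 Genomes, ESP6500, dbSNP and ExAC) to the distinct
#' variants of a mutation table. A seeded `common_fraction` of variants is
#' made "common" (frequency > 0.005 in at least one column); the rest stay
#' at or below 0.005 or are absent (NA). The ground-truth flag is kept in
#' the `seeded_common` column so filters can be checked against it.
#'
#' @param mutations Mutation tibble (uses `chrom`, `genomic_pos`,
#'   `ref_allele`, `alt_allele`).
#' @param common_fraction Fraction of distinct variants to seed as common.
#' @param seed Integer seed.
#' @return A tibble with the variant key columns, four `af_*` columns and
#'   `seeded_common`.
#' @export
simulate_population_af <- function(mutations, common_fraction, seed = 1) {
  assert_scalar_number(common_fraction, "common_fraction", 0, 1)
  keys <- distinct(mutations, .data$chrom, .data$genomic_pos,
                   .data$ref_allele, .data$alt_allele)
  nv <- nrow(keys)
  n_common <- round(common_fraction * nv)
  withr::with_seed(child_seed(seed, 53), {
    common_idx <- sample.int(nv, n_common)
    af <- matrix(NA_real_, nrow = nv, ncol = 4)
    present <- matrix(runif(nv * 4) < 0.5, nrow = nv)
    af[present] <- runif(sum(present), 0, 0.005)
    for (i in common_idx) {
      cols <- which(runif(4) < 0.5)
      if (length(cols) == 0) cols <- sample.int(4, 1)
      af[i, cols] <- runif(length(cols), 0.006, 0.2)
    }
  })
  keys$af_1000g <- af[, 1]
  keys$af_esp6500 <- af[, 2]
  keys$af_dbsnp <- af[, 3]
  keys$af_exac <- af[, 4]
  keys$seeded_common <- seq_len(nv) %in% common_idx
  keys
}

#' Simulate a ground-truth peptide-binding model
#'
#' Generates, for every allele and peptide length 8-11, a position-specific
#' scoring matrix (PSSM) designated as the true generative binding model.
#' Anchor positions (position 2 and the C-terminus) receive elevated weight
#' dispersion scaled by `motif_strength`; with `motif_strength = 0` all
#' cells equal `baseline` and every peptide scores identically. Simulated
#' prediction tools observe this truth plus Gaussian noise (see
#' [simulate_tools()]).
#'
#' @param alleles Character vector of allele names.
#' @param motif_strength Non-negative scale on weight dispersion.
#' @param noise_sd Standard deviation of per-tool score noise (recorded in
#'   the object; applied by simulated tools).
#' @param seed Integer seed.
#' @param lengths Peptide lengths to cover (default 8:11).
#' @param baseline Center of the weight distribution; the 0.28 default puts
#'   a typical random peptide near IC50 ~2400 nM, so binders are a clear minority
#'   and per-sample neoantigen loads land in a realistic range.
#' @return An object of class `binding_truth`.
#' @export
simulate_binding_truth <- function(alleles, motif_strength = 1,
                                   noise_sd = 0.05, seed = 1,
                                   lengths = 8:11, baseline = 0.28) {
  if (length(alleles) == 0) {
    abort("`alleles` must be non-empty", class = "neocall_parameter_error")
  }
  assert_scalar_number(motif_strength, "motif_strength", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  pssms <- list()
  withr::with_seed(child_seed(seed, 59), {
    for (al in alleles) {
      for (L in lengths) {
        spread <- rep(0.3 * motif_strength, L)
        spread[c(2, L)] <- motif_strength
        w <- matrix(baseline, nrow = 20, ncol = L,
                    dimnames = list(AA_ALPHABET, NULL))
        for (j in seq_len(L)) {
          w[, j] <- pmin(1, pmax(0, baseline +
                                      spread[j] * (runif(20) - 0.5)))
        }
        pssms[[paste(al, L, sep = "|")]] <- new_pssm(al, L, w)
      }
    }
  })
  structure(list(pssms = pssms, alleles = alleles, lengths = lengths,
                 noise_sd = noise_sd, baseline = baseline),
            class = "binding_truth")
}

#' Plant a guaranteed strong binder in a ground-truth model
#'
#' Rewrites the truth PSSMs of the peptide's length so that `peptide`
#' scores exactly 1 (IC50 = 1 nM) for every allele, while the wild-type
#' residue it replaced scores 0 at the mutated column. Used to inject a
#' hotspot neoantigen whose detection downstream is certain for every
#' carrier, which makes prevalence-recovery tests possible.
#'
#' @param truth A `binding_truth` object.
#' @param peptide The mutant peptide string to promote.
#' @param wt_aa Wild-type residue replaced by the mutation.
#' @param mut_offset 1-based position of the mutated residue within
#'   `peptide`.
#' @return The modified `binding_truth` object.
#' @export
promote_binder <- function(truth, peptide, wt_aa, mut_offset) {
  stopifnot(inherits(truth, "binding_truth"))
  L <- nchar(peptide)
  if (!(L %in% truth$lengths)) {
    abort("peptide length not covered by truth model",
          class = "neocall_parameter_error")
  }
  res <- strsplit(peptide, "")[[1]]
  for (al in truth$alleles) {
    key <- paste(al, L, sep = "|")
    w <- truth$pssms[[key]]$weights
    for (j in seq_len(L)) w[res[j], j] <- 1
    w[wt_aa, mut_offset] <- 0
    truth$pssms[[key]]$weights <- w
  }
  truth
}

# evaluate the ground-truth score of peptides (all of one length) under an
# allele; internal fast path shared by simulated tools
truth_score <- function(truth, peptides, allele) {
  if (length(peptides) == 0) return(numeric(0))
  L <- nchar(peptides[1])
  key <- paste(allele, L, sep = "|")
  pssm <- truth$pssms[[key]]
  if (is.null(pssm)) {
    abort(sprintf("no ground-truth PSSM for allele %s length %d", allele, L),
          class = "neocall_coverage_error")
  }
  score_peptide(pssm, peptides)
}
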