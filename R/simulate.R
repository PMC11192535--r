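#' Synthetic study configuration
#'
#' Defines the generative model for every pipeline input, with planted
#' ground truth: tissue-specialized effector genes (a fold-change applied
#' to their focal-tissue samples over a log-normal TPM baseline), secreted
#' proteins with tryptic-peptide detection, one expanded domain family in
#' the focal species, and parasitism/choice/dissection assay outcomes with
#' stated effect structure.
#'
#' Defaults emulate the study conditions at desk scale: an 18-sample
#' multi-tissue panel (six tissue/stage/sex groups x 3 replicates), 5,000
#' genes, 30 venom-gland-specialized genes at fold 8 of which 20 are
#' secreted with peptide support at detection probability 0.8, 10
#' teratocyte-specialized digestion genes at fold 8, one domain planted at
#' 29 focal copies against 13 comparator species at Poisson(2), and a
#' parasitism design over host ages 1-4 days x mono/super modes whose
#' 4-day-old cell plants the mono (0.3, 0.2) vs super (0.66, 0.64)
#' probabilities, i.e. true 2.2x parasitism and 3.2x emergence recovery.
#'
#' @param n_genes Number of genes.
#' @param sample_design Data frame (`tissue`, `stage`, `sex`,
#'   `n_replicates`) describing the expression panel.
#' @param baseline_log2_mean,baseline_log2_sd Baseline TPM values are drawn
#'   i.i.d. as 2^Normal(mean, sd) per gene x sample cell.
#' @param planted_specialized Data frame (`gene_id`, `focal_tissue`,
#'   `fold_factor`); the gene's focal-tissue samples are multiplied by the
#'   fold (>= 1; 1 is the null).
#' @param planted_secreted Gene ids (subset of `planted_specialized`) whose
#'   protein products receive proteomic peptide evidence.
#' @param peptide_detection_prob Per-eligible-peptide detection probability.
#' @param min_peptide_length Peptides shorter than this are not detectable
#'   (default 6 residues, a practical MS detectability floor).
#' @param n_decoy_proteins Non-secreted proteins included in the FASTA.
#' @param protein_length_mean,protein_length_sd Protein length distribution.
#' @param planted_domain List (`accession`, `focal_count`,
#'   `other_count_lambda`).
#' @param n_domains,n_other_species Size of the domain-count table.
#' @param assay_probs Data frame (`host_age`, `mode`, `p_parasitism`,
#'   `p_emergence`) covering every design cell.
#' @param n_assay_replicates,n_hosts Parasitism assay size per cell.
#' @param choice_ages,choice_durations,n_choice_replicates Two-choice design.
#' @param choice_intensity Expected eggs per side; `side_preference`
#'   multiplies the left (1-day-old) side (1 = no bias).
#' @param side_preference See above.
#' @param dissection_probs Named probabilities of egg presence per group
#'   (`NH` non-parasitized, `PH` previously parasitized hosts).
#' @param n_dissected,n_dissection_replicates Dissection assay size.
#' @param lambda_spectra Spectral counts per detected peptide are
#'   1 + Poisson(lambda_spectra).
#' @param host_species Host species label in assay records.
#' @param seed Master seed; one independent random stream per output table
#'   is derived from it, so changing one design block never perturbs the
#'   draws of another.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_genes = 5000,
    sample_design = default_sample_design(),
    baseline_log2_mean = 4,
    baseline_log2_sd = 1,
    planted_specialized = default_planted_specialized(n_genes),
    planted_secreted = default_planted_secreted(planted_specialized),
    peptide_detection_prob = 0.8,
    min_peptide_length = 6,
    n_decoy_proteins = 480,
    protein_length_mean = 300,
    protein_length_sd = 40,
    planted_domain = list(accession = "IPR900001", focal_count = 29,
                          other_count_lambda = 2),
    n_domains = 200,
    n_other_species = 13,
    assay_probs = default_assay_probs(),
    n_assay_replicates = 6,
    n_hosts = 20,
    choice_ages = 1:4,
    choice_durations = c(2, 4),
    n_choice_replicates = 5,
    choice_intensity = 30,
    side_preference = 1,
    dissection_probs = c(NH = 0.85, PH = 0.15),
    n_dissected = 20,
    n_dissection_replicates = 6,
    lambda_spectra = 2,
    host_species = "drosophilid_host",
    seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  sd_ <- cfg$sample_design
  stopifnot(all(c("tissue", "stage", "sex", "n_replicates") %in% names(sd_)))
  ps <- cfg$planted_specialized
  if (nrow(ps) > 0) {
    if (cfg$n_genes < nrow(ps))
      stop("config error: n_genes must be >= number of planted genes",
           call. = FALSE)
    if (any(ps$fold_factor < 1))
      stop("config error: fold_factor must be >= 1 (1 is the null)",
           call. = FALSE)
    bad <- setdiff(ps$focal_tissue, sd_$tissue)
    if (length(bad))
      stop("config error: planted focal tissue(s) absent from sample design: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (length(setdiff(cfg$planted_secreted, ps$gene_id)))
      stop("config error: planted_secreted must be a subset of planted_specialized",
           call. = FALSE)
  } else if (length(cfg$planted_secreted)) {
    stop("config error: planted_secreted without planted_specialized",
         call. = FALSE)
  }
  probs <- c(cfg$peptide_detection_prob, cfg$assay_probs$p_parasitism,
             cfg$assay_probs$p_emergence, cfg$dissection_probs)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  if (any(cfg$assay_probs$p_emergence > cfg$assay_probs$p_parasitism))
    stop("config error: p_emergence > p_parasitism (a host cannot yield a wasp without being parasitized)",
         call. = FALSE)
  if (cfg$planted_domain$focal_count < 0)
    stop("config error: planted focal_count must be >= 0", call. = FALSE)
  if (cfg$n_other_species < 1)
    stop("config error: n_other_species must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @rdname simulation_config
#' @export
default_sample_design <- function() {
  data.frame(
    tissue = c("venom_gland", "teratocyte", "ovipositor", "antenna",
               "whole_body", "whole_body"),
    stage = c("adult", "parasitic_stage", "adult", "adult", "larva", "adult"),
    sex = c("female", "mixed", "female", "female", "mixed", "male"),
    n_replicates = 3L,
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_config
#' @export
default_planted_specialized <- function(n_genes = 5000) {
  if (n_genes < 40) return(data.frame(gene_id = character(0),
                                      focal_tissue = character(0),
                                      fold_factor = numeric(0)))
  ids <- gene_ids(n_genes)
  data.frame(
    gene_id = ids[1:40],
    focal_tissue = rep(c("venom_gland", "teratocyte"), c(30, 10)),
    fold_factor = 8,
    stringsAsFactors = FALSE
  )
}

#' @rdname simulation_config
#' @export
default_planted_secreted <- function(planted_specialized) {
  vg <- planted_specialized$gene_id[
    planted_specialized$focal_tissue == "venom_gland"]
  utils::head(vg, 20)
}

#' @rdname simulation_config
#' @export
default_assay_probs <- function() {
  data.frame(
    host_age = rep(1:4, 2),
    mode = rep(c("mono", "super"), each = 4),
    p_parasitism = c(0.90, 0.80, 0.55, 0.30, 0.92, 0.88, 0.80, 0.66),
    p_emergence = c(0.75, 0.60, 0.35, 0.20, 0.80, 0.75, 0.70, 0.64),
    stringsAsFactors = FALSE
  )
}

gene_ids <- function(n) {
  if (n == 0) return(character(0))
  sprintf(paste0("g%0", max(4, nchar(n)), "d"), seq_len(n))
}

sim_streams <- function(cfg) {
  s <- derive_seeds(cfg$seed, 6L)
  names(s) <- c("expression", "proteins", "peptides", "domains", "assays",
                "annotation")
  s
}

#' Simulate the gene x sample expression matrix
#'
#' Baseline TPM values are drawn i.i.d. as 2^Normal(baseline_log2_mean,
#' baseline_log2_sd); each planted gene's focal-tissue samples are then
#' multiplied by its fold factor. Identical seeds give identical matrices.
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` (an [expression_matrix()], or `NULL` when
#'   `n_genes` is 0) and `truth` (per-gene labels: `specialized`,
#'   `focal_tissue`, `fold_factor`, `secreted`).
#' @export
simulate_expression <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(sim_streams(cfg)[["expression"]])
  sdsn <- cfg$sample_design
  meta <- do.call(rbind, lapply(seq_len(nrow(sdsn)), function(i) {
    data.frame(
      sample_id = paste(sdsn$tissue[i], sdsn$stage[i], sdsn$sex[i],
                        paste0("r", seq_len(sdsn$n_replicates[i])), sep = "."),
      tissue = sdsn$tissue[i], stage = sdsn$stage[i], sex = sdsn$sex[i],
      replicate = seq_len(sdsn$n_replicates[i]), stringsAsFactors = FALSE)
  }))
  ids <- gene_ids(cfg$n_genes)
  truth <- data.frame(gene_id = ids,
                      specialized = rep(FALSE, length(ids)),
                      focal_tissue = rep(NA_character_, length(ids)),
                      fold_factor = rep(1, length(ids)),
                      secreted = rep(FALSE, length(ids)),
                      stringsAsFactors = FALSE)
  if (cfg$n_genes == 0) {
    m0 <- matrix(numeric(0), nrow = 0, ncol = nrow(meta),
                 dimnames = list(character(0), meta$sample_id))
    return(list(matrix = expression_matrix(m0, meta), truth = truth))
  }
  m <- matrix(2^stats::rnorm(cfg$n_genes * nrow(meta),
                             cfg$baseline_log2_mean, cfg$baseline_log2_sd),
              nrow = cfg$n_genes, ncol = nrow(meta),
              dimnames = list(ids, meta$sample_id))
  ps <- cfg$planted_specialized
  for (i in seq_len(nrow(ps))) {
    cols <- meta$sample_id[meta$tissue == ps$focal_tissue[i]]
    m[ps$gene_id[i], cols] <- m[ps$gene_id[i], cols] * ps$fold_factor[i]
  }
  truth$specialized[match(ps$gene_id, truth$gene_id)] <- ps$fold_factor > 1
  truth$focal_tissue[match(ps$gene_id, truth$gene_id)] <- ps$focal_tissue
  truth$fold_factor[match(ps$gene_id, truth$gene_id)] <- ps$fold_factor
  truth$secreted[truth$gene_id %in% cfg$planted_secreted] <- TRUE
  list(matrix = expression_matrix(m, meta), truth = truth)
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminally of every lysine (K) or arginine
#' (R) that is not followed by proline (P), with zero missed cleavages, so
#' the peptides form an exact partition: their concatenation equals the
#' input.
#'
#' @param protein_sequence Non-empty uppercase amino-acid sequence.
#' @return Character vector of peptides, in order.
#' @export
digest_tryptic <- function(protein_sequence) {
  if (length(protein_sequence) != 1 || is.na(protein_sequence) ||
      nchar(protein_sequence) == 0)
    stop("input error: protein sequence must be a single non-empty string",
         call. = FALSE)
  ok <- strsplit(protein_sequence, "")[[1]] %in% AA_ALPHABET
  if (!all(ok))
    stop(sprintf("input error: illegal character at position %d", which(!ok)[1]),
         call. = FALSE)
  strsplit(protein_sequence, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

# Background amino-acid frequencies for random proteins (K + R ~ 11% so
# tryptic peptides average ~9 residues).
AA_FREQ <- c(A = 0.08, C = 0.015, D = 0.055, E = 0.065, F = 0.04, G = 0.07,
             H = 0.022, I = 0.055, K = 0.06, L = 0.09, M = 0.022, N = 0.042,
             P = 0.046, Q = 0.04, R = 0.05, S = 0.068, T = 0.055, V = 0.068,
             W = 0.012, Y = 0.035)

#' Simulate the protein FASTA
#'
#' Random protein sequences for every planted secreted gene plus
#' `n_decoy_proteins` non-secreted genes. The FASTA covers the
#' venom-candidate proteome, not all genes: the proteomic search space of
#' a venom LC-MS/MS experiment is the candidate secretome, and the decoys
#' exercise the specificity of peptide matching.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth table from [simulate_expression()].
#' @return Named character vector of protein sequences (names are gene
#'   ids).
#' @export
simulate_proteins <- function(cfg, truth) {
  set.seed(sim_streams(cfg)[["proteins"]])
  secreted <- truth$gene_id[truth$secreted]
  pool <- setdiff(truth$gene_id, cfg$planted_specialized$gene_id)
  decoys <- utils::tail(pool, min(cfg$n_decoy_proteins, length(pool)))
  ids <- c(secreted, decoys)
  lens <- pmax(100L, round(stats::rnorm(length(ids), cfg$protein_length_mean,
                                        cfg$protein_length_sd)))
  seqs <- vapply(lens, function(L)
    paste(sample(names(AA_FREQ), L, replace = TRUE, prob = AA_FREQ),
          collapse = ""), character(1))
  names(seqs) <- ids
  seqs
}

#' Simulate proteomic peptide evidence
#'
#' Each tryptic peptide of length >= `min_peptide_length` from a secreted
#' protein is detected independently with `peptide_detection_prob`;
#' non-secreted proteins contribute nothing, so the distinct-peptide count
#' of a secreted protein is Binomial(#eligible peptides, p). Detected
#' peptides carry a simulated spectral count.
#'
#' @param proteins Named character vector from [simulate_proteins()].
#' @param truth Truth table from [simulate_expression()].
#' @param cfg A [simulation_config()].
#' @return Data frame with columns `peptide`, `spectrum_count`.
#' @export
simulate_peptide_evidence <- function(proteins, truth, cfg) {
  set.seed(sim_streams(cfg)[["peptides"]])
  secreted <- truth$gene_id[truth$secreted]
  miss <- setdiff(secreted, names(proteins))
  if (length(miss))
    stop("config error: secreted gene(s) missing from protein set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(secreted, function(id) {
    peps <- digest_tryptic(proteins[[id]])
    peps <- unique(peps[nchar(peps) >= cfg$min_peptide_length])
    if (length(peps) == 0) return(NULL)
    hit <- stats::runif(length(peps)) < cfg$peptide_detection_prob
    if (!any(hit)) return(NULL)
    data.frame(peptide = peps[hit],
               spectrum_count = 1L + stats::rpois(sum(hit), cfg$lambda_spectra),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide = character(0), spectrum_count = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate the species x domain count table
#'
#' Every (species, domain) count is drawn i.i.d. Poisson(other_count_lambda),
#' including for the focal species, except the planted domain's focal count
#' which is set exactly to `focal_count`.
#'
#' @param cfg A [simulation_config()].
#' @param focal_species Name of the focal species row.
#' @return Integer matrix, species x domains.
#' @export
simulate_domain_counts <- function(cfg, focal_species = "focal_sp") {
  validate_simulation_config(cfg)
  set.seed(sim_streams(cfg)[["domains"]])
  species <- c(focal_species,
               sprintf("comparator_%02d", seq_len(cfg$n_other_species)))
  domains <- c(cfg$planted_domain$accession,
               sprintf("IPR%06d", seq_len(cfg$n_domains - 1)))
  m <- matrix(stats::rpois(length(species) * length(domains),
                           cfg$planted_domain$other_count_lambda),
              nrow = length(species), dimnames = list(species, domains))
  m[focal_species, cfg$planted_domain$accession] <-
    cfg$planted_domain$focal_count
  storage.mode(m) <- "integer"
  m
}

#' Simulate assay records
#'
#' Parasitism records couple the two outcome counts within one host cohort:
#' each of `n_hosts` hosts is parasitized with probability p_parasitism; a
#' parasitized host yields a wasp with probability p_emergence/p_parasitism;
#' an unparasitized host ecloses as a host adult. Marginally, emerged host
#' adults ~ Binomial(n, 1 - p_parasitism) and emerged wasps ~ Binomial(n,
#' p_emergence), and adults + wasps <= n always holds. Choice records draw
#' per-side egg totals Poisson(choice_intensity x side preference);
#' dissection records draw egg presence Binomial(n_dissected, p) per group.
#'
#' @param cfg A [simulation_config()].
#' @return List with data frames `parasitism`, `choice`, `dissection`.
#' @export
simulate_assays <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(sim_streams(cfg)[["assays"]])
  ap <- cfg$assay_probs
  par_rows <- lapply(seq_len(nrow(ap)), function(i) {
    p_par <- ap$p_parasitism[i]
    p_cond <- if (p_par > 0) ap$p_emergence[i] / p_par else 0
    parasitized <- stats::rbinom(cfg$n_assay_replicates, cfg$n_hosts, p_par)
    wasps <- stats::rbinom(cfg$n_assay_replicates, parasitized, p_cond)
    data.frame(replicate = seq_len(cfg$n_assay_replicates),
               host_species = cfg$host_species,
               host_age_days = ap$host_age[i], mode = ap$mode[i],
               n_hosts = cfg$n_hosts,
               n_emerged_host_adults = cfg$n_hosts - parasitized,
               n_emerged_wasps = wasps, stringsAsFactors = FALSE)
  })
  design <- expand.grid(age_x = cfg$choice_ages,
                        duration_h = cfg$choice_durations)
  choice_rows <- lapply(seq_len(nrow(design)), function(i) {
    data.frame(replicate = seq_len(cfg$n_choice_replicates),
               age_x = design$age_x[i],
               n1 = stats::rpois(cfg$n_choice_replicates,
                                 cfg$choice_intensity * cfg$side_preference),
               nx = stats::rpois(cfg$n_choice_replicates, cfg$choice_intensity),
               duration_h = design$duration_h[i], stringsAsFactors = FALSE)
  })
  diss_rows <- lapply(names(cfg$dissection_probs), function(g) {
    data.frame(replicate = seq_len(cfg$n_dissection_replicates), group = g,
               n_dissected = cfg$n_dissected,
               n_with_eggs = stats::rbinom(cfg$n_dissection_replicates,
                                           cfg$n_dissected,
                                           cfg$dissection_probs[[g]]),
               stringsAsFactors = FALSE)
  })
  list(parasitism = do.call(rbind, par_rows),
       choice = do.call(rbind, choice_rows),
       dissection = do.call(rbind, diss_rows))
}

#' Simulate the functional annotation table
#'
#' Planted teratocyte genes receive digestion-related annotations
#' (trypsin-like proteases); planted venom genes receive venom-protein
#' annotations; the remainder draw from a pool of ribosomal, immune,
#' housekeeping and uncharacterized descriptions.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth table from [simulate_expression()].
#' @return Data frame with `gene_id`, `domain_accessions`, `function_text`.
#' @export
simulate_annotation <- function(cfg, truth) {
  set.seed(sim_streams(cfg)[["annotation"]])
  n <- nrow(truth)
  pool <- c("40S ribosomal protein S3", "60S ribosomal protein L10",
            "elongation factor 1-alpha", "defensin precursor", "lysozyme c",
            "cytochrome P450 6a2", "odorant receptor 42b", "actin-5C",
            "tubulin alpha chain", "heat shock protein 70",
            "uncharacterized protein", "hypothetical protein",
            "zinc finger protein", "ATP synthase subunit beta")
  txt <- sample(pool, n, replace = TRUE)
  tera <- truth$specialized & !is.na(truth$focal_tissue) &
    truth$focal_tissue == "teratocyte"
  txt[tera] <- "trypsin-like serine protease"
  venom <- truth$specialized & !is.na(truth$focal_tissue) &
    truth$focal_tissue == "venom_gland"
  txt[venom] <- "venom protein precursor"
  dom <- ifelse(stats::runif(n) < 0.6,
                sprintf("IPR%06d", sample.int(999999, n, replace = TRUE)), "")
  data.frame(gene_id = truth$gene_id, domain_accessions = dom,
             function_text = txt, stringsAsFactors = FALSE)
}

#' Emit all synthetic pipeline inputs to a directory
#'
#' Writes the exact file dialects the readers consume — expression.tsv +
#' samples.tsv, proteins.fasta, peptides.tsv, annotation.tsv,
#' domain_counts.tsv, parasitism.csv, choice.csv, dissection.csv — plus
#' `truth.json` with the planted ground truth. Identical configurations
#' produce byte-identical files.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the truth object.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- simulate_expression(cfg)
  proteins <- simulate_proteins(cfg, expr$truth)
  peptides <- simulate_peptide_evidence(proteins, expr$truth, cfg)
  annotation <- simulate_annotation(cfg, expr$truth)
  domains <- simulate_domain_counts(cfg)
  assays <- simulate_assays(cfg)
  p <- function(f) file.path(dir, f)
  write_expression_table(expr$matrix, p("expression.tsv"), p("samples.tsv"))
  write_fasta(proteins, p("proteins.fasta"))
  utils::write.table(peptides, p("peptides.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_domain_counts(domains, p("domain_counts.tsv"))
  utils::write.csv(assays$parasitism, p("parasitism.csv"), row.names = FALSE)
  utils::write.csv(assays$choice, p("choice.csv"), row.names = FALSE)
  utils::write.csv(assays$dissection, p("dissection.csv"), row.names = FALSE)
  truth <- list(
    genes = expr$truth,
    planted_domain = cfg$planted_domain,
    assay_probs = cfg$assay_probs,
    dissection_probs = as.list(cfg$dissection_probs),
    side_preference = cfg$side_preference,
    focal_species = "focal_sp"
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    paths = list(expression = p("expression.tsv"), samples = p("samples.tsv"),
                 proteins = p("proteins.fasta"), peptides = p("peptides.tsv"),
                 annotation = p("annotation.tsv"),
                 domain_counts = p("domain_counts.tsv"),
                 parasitism = p("parasitism.csv"), choice = p("choice.csv"),
                 dissection = p("dissection.csv"), truth = p("truth.json")),
    truth = truth
  ))
}
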