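#' Run the full effector-discovery pipeline
#'
#' Executes the four analysis stages over one set of input files —
#' expression profiling (N99 thresholds per sample group, specialization
#' indices, sample ordination), effector calling (venom proteins from
#' expression + peptide evidence, highly expressed venom proteins,
#' teratocyte effectors), gene-family expansion ranking, and ecology
#' statistics — and returns a result bundle with a provenance block.
#' Identical seed and inputs give identical payloads.
#'
#' @param config A [run_config()].
#' @param input_dir Directory containing the input files as written by
#'   [write_synthetic_inputs()] (`expression.tsv`, `samples.tsv`,
#'   `proteins.fasta`, `peptides.tsv`, `annotation.tsv`,
#'   `domain_counts.tsv`, `parasitism.csv`, `choice.csv`,
#'   `dissection.csv`). When `NULL`, synthetic inputs are generated into a
#'   temporary directory from `sim_config`.
#' @param sim_config A [simulation_config()] used only when `input_dir` is
#'   `NULL`; defaults to `simulation_config(seed = config$seed)`.
#' @param focal_species Focal species row of the domain-count table.
#' @return An object of class `result_bundle`.
#' @export
run_pipeline <- function(config = run_config(), input_dir = NULL,
                         sim_config = NULL, focal_species = "focal_sp") {
  validate_run_config(config)
  if (is.null(input_dir)) {
    input_dir <- tempfile("effectorscan_inputs_")
    if (is.null(sim_config)) sim_config <- simulation_config(seed = config$seed)
    run_stage("simulate", write_synthetic_inputs(sim_config, input_dir))
  }
  paths <- file.path(input_dir,
                     c("expression.tsv", "samples.tsv", "proteins.fasta",
                       "peptides.tsv", "annotation.tsv", "domain_counts.tsv",
                       "parasitism.csv", "choice.csv", "dissection.csv"))
  names(paths) <- c("expression", "samples", "proteins", "peptides",
                    "annotation", "domain_counts", "parasitism", "choice",
                    "dissection")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input error: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  em <- run_stage("read", read_expression_table(paths["expression"],
                                                paths["samples"]))
  proteins <- run_stage("read", read_fasta(paths["proteins"]))
  peptides <- run_stage("read", read_peptide_table(paths["peptides"]))
  annotation <- run_stage("read", read_annotation_table(paths["annotation"]))
  domain_counts <- run_stage("read", read_domain_counts(paths["domain_counts"]))
  par_rec <- run_stage("read", read_assay_records(paths["parasitism"], "parasitism"))
  choice_rec <- run_stage("read", read_assay_records(paths["choice"], "choice"))
  diss_rec <- run_stage("read", read_assay_records(paths["dissection"], "dissection"))

  profile <- run_stage("profile", {
    gm <- group_mean_matrix(em)
    thresholds <- do.call(rbind, lapply(colnames(gm), function(g) {
      thr <- compute_n99(gm[, g], config$n99_fraction, config$expressed_rule)
      data.frame(group = g, threshold = thr$threshold,
                 n_expressed = thr$n_expressed, stringsAsFactors = FALSE)
    }))
    vg_samples <- samples_of_tissue(em, config$vg_tissue)
    tc_samples <- samples_of_tissue(em, config$teratocyte_tissue)
    spec_vg <- if (length(vg_samples))
      specialization_index(em, vg_samples, pseudocount = config$pseudocount)
    else NULL
    spec_tc <- if (length(tc_samples))
      specialization_index(em, tc_samples, pseudocount = config$pseudocount)
    else NULL
    proj <- if (ncol(em$values) >= 2 && nrow(em$values) >= 1)
      project_samples(em) else NULL
    list(thresholds = thresholds, specialization_vg = spec_vg,
         specialization_teratocyte = spec_tc, projection = proj)
  })

  effectors <- run_stage("call-effectors", {
    vg_samples <- samples_of_tissue(em, config$vg_tissue)
    if (length(vg_samples) == 0)
      stop("venom-gland tissue '", config$vg_tissue, "' absent from metadata")
    vg_expressed <- call_expressed(em, vg_samples, config$n99_fraction,
                                   config$expressed_rule)
    supports <- peptide_support(proteins, peptides, config$il_equivalence)
    venom <- call_venom_proteins(vg_expressed, supports, config$min_peptides,
                                 gene_universe = rownames(em$values))
    vg_mean <- rowMeans(em$values[, vg_samples, drop = FALSE])
    high_vps <- if (nrow(venom) >= 3)
      tryCatch(call_highly_expressed_vps(venom, vg_mean, config$alpha),
               error = function(e) NULL)
    else NULL
    keywords <- default_function_keywords()
    keywords$digestion <- config$digestion_keywords
    tc_samples <- samples_of_tissue(em, config$teratocyte_tissue)
    teratocyte <- if (length(tc_samples))
      call_teratocyte_effectors(em, tc_samples, annotation, config$alpha,
                                config$n99_fraction, config$expressed_rule,
                                keywords)
    else NULL
    list(vg_expressed = vg_expressed, venom_proteins = venom,
         highly_expressed_vps = high_vps, teratocyte = teratocyte)
  })

  expansion <- run_stage("expansion", {
    ranked <- rank_expansions(domain_counts, focal_species)
    if (nrow(ranked) >= 5) flag_outliers(ranked, config$outlier_cutoff)
    else ranked
  })

  ecology <- run_stage("ecology", {
    cond <- summarize_conditions(par_rec)
    folds <- NULL
    both <- intersect(cond$host_age_days[cond$mode == "mono"],
                      cond$host_age_days[cond$mode == "super"])
    if (length(both)) {
      age <- max(both)
      folds <- tryCatch(
        c(age = age,
          fold_recovery(cond[cond$mode == "mono" & cond$host_age_days == age, ],
                        cond[cond$mode == "super" & cond$host_age_days == age, ])),
        error = function(e) NULL)
    }
    choice <- suppressWarnings(summarize_choice(choice_rec))
    dissection <- summarize_dissection(diss_rec)
    list(conditions = cond, fold_recovery = folds,
         choice_summary = choice$summary, dissection_summary = dissection$summary,
         dissection_test = dissection$test)
  })

  bundle <- list(
    profile = profile, effectors = effectors, expansion = expansion,
    ecology = ecology,
    provenance = list(
      config = unclass(config),
      input_checksums = as.list(tools::md5sum(paths)),
      package_version = as.character(utils::packageVersion("effectorscan"))
    )
  )
  class(bundle) <- "result_bundle"
  bundle
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Serialize / read a result bundle
#'
#' The bundle round-trips losslessly through JSON (full numeric precision,
#' no timestamps), so byte comparison of two serializations is a
#' determinism check.
#'
#' @param bundle A `result_bundle` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `write_result_bundle`: invisibly, `path`;
#'   `read_result_bundle`: the parsed bundle (plain lists/data frames).
#' @export
write_result_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_result_bundle
#' @export
read_result_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("effector-screen result bundle\n")
  cat(sprintf("  venom-gland expressed genes: %d (N%g threshold %.3f TPM)\n",
              length(x$effectors$vg_expressed$genes),
              100 * x$provenance$config$n99_fraction,
              x$effectors$vg_expressed$threshold))
  cat(sprintf("  venom proteins: %d; highly expressed: %d\n",
              nrow(x$effectors$venom_proteins),
              if (is.null(x$effectors$highly_expressed_vps)) 0L
              else nrow(x$effectors$highly_expressed_vps)))
  if (!is.null(x$effectors$teratocyte))
    cat(sprintf("  teratocyte expressed: %d; significantly high: %d\n",
                length(x$effectors$teratocyte$expressed$genes),
                sum(x$effectors$teratocyte$calls$category == "teratocyte_high")))
  if (!is.null(x$expansion$outlier))
    cat(sprintf("  expansion outliers: %d (top: %s, score %g)\n",
                sum(x$expansion$outlier), x$expansion$domain[1],
                x$expansion$score[1]))
  invisible(x)
}
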