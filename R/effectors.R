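#' Match proteomic peptides to a protein
#'
#' A peptide supports a protein iff it can be fully aligned to it, i.e. it
#' occurs as an exact contiguous substring of the protein sequence.
#' Distinct peptide sequences are counted once regardless of how many
#' spectra observed them. With `il_equivalence` on, isoleucine and leucine
#' are treated as interchangeable (both are rewritten before matching);
#' off by default, since search engines distinguish them by context.
#'
#' @param protein Protein sequence (uppercase).
#' @param peptides Character vector of peptide observations (uppercase).
#' @param il_equivalence Treat I and L as the same residue.
#' @return List with `n_distinct_matched`, `matched` (distinct matched
#'   peptide sequences, in first-seen order).
#' @export
match_peptides <- function(protein, peptides, il_equivalence = FALSE) {
  if (length(peptides) && any(!nzchar(peptides)))
    stop("input error: empty peptide sequence in input", call. = FALSE)
  pep <- unique(peptides)
  if (length(pep) == 0)
    return(list(n_distinct_matched = 0L, matched = character(0)))
  prot_c <- if (il_equivalence) chartr("L", "I", protein) else protein
  pep_c <- if (il_equivalence) chartr("L", "I", pep) else pep
  hit <- vapply(pep_c, function(p) grepl(p, prot_c, fixed = TRUE), logical(1))
  list(n_distinct_matched = as.integer(sum(hit)),
       matched = unname(pep[hit]))
}

#' Peptide support counts for a protein collection
#'
#' Counts, for every protein, the distinct peptides from an evidence table
#' that fully align to it. A peptide matching several proteins supports
#' each of them (no parsimony/razor assignment), which can inflate support
#' for close paralogs; the shared-peptide count is reported so downstream
#' users can see it.
#'
#' @param proteins Named character vector of protein sequences.
#' @param peptide_table Data frame with columns `peptide`, `spectrum_count`
#'   (as from [read_peptide_table()]).
#' @param il_equivalence Treat I and L as interchangeable.
#' @return Data frame with `protein_id`, `n_distinct_matched`,
#'   `n_shared_peptides` (matched peptides that also match another
#'   protein), `total_spectra`.
#' @export
peptide_support <- function(proteins, peptide_table, il_equivalence = FALSE) {
  if (any(!nzchar(peptide_table$peptide)))
    stop("input error: empty peptide sequence in input", call. = FALSE)
  peps <- unique(peptide_table$peptide)
  spectra <- vapply(split(peptide_table$spectrum_count, peptide_table$peptide),
                    sum, numeric(1))[peps]
  prot_c <- if (il_equivalence) chartr("L", "I", proteins) else proteins
  peps_c <- if (il_equivalence) chartr("L", "I", peps) else peps
  # peptides x proteins hit matrix; grepl vectorizes over the protein set
  hits <- matrix(FALSE, length(peps), length(proteins),
                 dimnames = list(peps, names(proteins)))
  for (i in seq_along(peps_c))
    hits[i, ] <- grepl(peps_c[i], prot_c, fixed = TRUE)
  shared <- rowSums(hits) > 1
  data.frame(
    protein_id = names(proteins),
    n_distinct_matched = as.integer(colSums(hits)),
    n_shared_peptides = as.integer(colSums(hits & shared)),
    total_spectra = as.numeric(colSums(hits * spectra)),
    stringsAsFactors = FALSE
  )
}

#' Call venom proteins from expression and peptide evidence
#'
#' A gene is a venom protein iff it is expressed in the venom gland (its
#' TPM passes the venom-gland N99 threshold) AND at least `min_peptides`
#' distinct proteomic peptides fully align to its protein product.
#'
#' @param vg_expressed Result of [call_expressed()] on the venom-gland
#'   group, or a character vector of venom-gland-expressed gene ids.
#' @param supports Data frame from [peptide_support()].
#' @param min_peptides Minimum distinct matched peptides (default 3,
#'   boundary inclusive).
#' @param gene_universe Optional character vector of all known gene ids;
#'   support rows referencing genes outside it are an input error.
#' @return Data frame of calls: `gene_id`, `category` ("venom_protein"),
#'   `vg_expressed`, `threshold`, `n_distinct_matched`, `total_spectra`.
#' @export
call_venom_proteins <- function(vg_expressed, supports, min_peptides = 3,
                                gene_universe = NULL) {
  expressed_genes <- if (is.list(vg_expressed)) vg_expressed$genes else vg_expressed
  threshold <- if (is.list(vg_expressed)) vg_expressed$threshold else NA_real_
  if (!is.null(gene_universe)) {
    unknown <- setdiff(supports$protein_id, gene_universe)
    if (length(unknown))
      stop("input error: peptide support references unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  called <- supports$protein_id %in% expressed_genes &
    supports$n_distinct_matched >= min_peptides
  out <- supports[called, , drop = FALSE]
  if (nrow(out) == 0)
    return(data.frame(gene_id = character(0), category = character(0),
                      vg_expressed = logical(0), threshold = numeric(0),
                      n_distinct_matched = integer(0),
                      total_spectra = numeric(0), stringsAsFactors = FALSE))
  data.frame(gene_id = out$protein_id, category = "venom_protein",
             vg_expressed = TRUE, threshold = threshold,
             n_distinct_matched = out$n_distinct_matched,
             total_spectra = out$total_spectra,
             stringsAsFactors = FALSE)
}

#' Promote venom proteins with significantly high expression
#'
#' Applies the high-expression Z test ([call_high_expression()]) over the
#' venom-protein set's venom-gland expression and promotes significant
#' genes to the `highly_expressed_vp` category.
#'
#' @param venom_calls Data frame from [call_venom_proteins()].
#' @param vg_expression Named numeric vector of venom-gland (group-mean) TPM
#'   covering at least the venom-protein genes.
#' @param alpha Significance level (default 0.05).
#' @return Data frame of promoted calls with `gene_id`, `category`
#'   ("highly_expressed_vp"), `z`, `p`.
#' @export
call_highly_expressed_vps <- function(venom_calls, vg_expression, alpha = 0.05) {
  genes <- venom_calls$gene_id
  if (length(genes) < 3)
    stop("input error: need at least 3 venom proteins for the Z test, got ",
         length(genes), call. = FALSE)
  miss <- setdiff(genes, names(vg_expression))
  if (length(miss))
    stop("input error: venom-gland expression missing for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  hz <- call_high_expression(vg_expression[genes], alpha = alpha)
  hz <- hz[hz$called, , drop = FALSE]
  data.frame(gene_id = hz$gene_id, category = "highly_expressed_vp",
             z = hz$z, p = hz$p, stringsAsFactors = FALSE)
}

#' Classify gene function from free-text annotation
#'
#' First-matching-keyword assignment against lowercased annotation text with
#' fixed class priority digestion > ribosome > immunity. Text with no
#' keyword hit is classed `other`, or `unknown` when the annotation is
#' empty or an uncharacterized/hypothetical placeholder.
#'
#' @param annotation Data frame with `gene_id` and `function_text` (as from
#'   [read_annotation_table()]).
#' @param keywords Named list of keyword vectors; see
#'   [default_function_keywords()]. The `digestion` entry may be overridden
#'   independently via a run config's `digestion_keywords`.
#' @return Data frame with `gene_id`, `class`, `matched_keyword`.
#' @export
classify_function <- function(annotation, keywords = default_function_keywords()) {
  txt <- tolower(annotation$function_text)
  classes <- c("digestion", "ribosome", "immunity")
  cls <- rep("other", length(txt))
  kw <- rep(NA_character_, length(txt))
  for (cl in classes) {
    open <- cls == "other"           # not yet claimed by a higher-priority class
    if (!any(open)) break
    for (k in tolower(keywords[[cl]])) {
      hit <- open & is.na(kw) & grepl(k, txt, fixed = TRUE)
      kw[hit] <- k
    }
    cls[open & !is.na(kw)] <- cl
  }
  blank <- !nzchar(trimws(txt)) |
    grepl("uncharacterized|hypothetical protein|unknown function", txt)
  cls[cls == "other" & blank] <- "unknown"
  data.frame(gene_id = annotation$gene_id, class = cls,
             matched_keyword = kw, stringsAsFactors = FALSE)
}

#' Call teratocyte effectors
#'
#' The teratocyte-expressed gene set is defined by the N99 threshold on the
#' teratocyte sample group; the significantly highly expressed subset by
#' the Z test over the expressed set; functional classes are attached from
#' the annotation table.
#'
#' @param em An [expression_matrix()] containing teratocyte samples.
#' @param teratocyte_group Character vector of teratocyte sample ids.
#' @param annotation Data frame from [read_annotation_table()], or `NULL`.
#' @param alpha Z-test significance level.
#' @param fraction,expressed_rule Passed to [call_expressed()].
#' @param keywords Functional keyword taxonomy.
#' @return List with `expressed` (the [call_expressed()] result) and
#'   `calls`, a data frame with `gene_id`, `category`
#'   ("teratocyte_effector" or "teratocyte_high"), `tpm`, `z`, `p`, `class`.
#' @export
call_teratocyte_effectors <- function(em, teratocyte_group, annotation = NULL,
                                      alpha = 0.05, fraction = 0.99,
                                      expressed_rule = "inclusive_ge",
                                      keywords = default_function_keywords()) {
  if (length(teratocyte_group) == 0 ||
      !all(teratocyte_group %in% colnames(em$values)))
    stop("input error: teratocyte sample group missing from matrix",
         call. = FALSE)
  expressed <- call_expressed(em, teratocyte_group, fraction, expressed_rule)
  if (length(expressed$genes) == 0)
    return(list(expressed = expressed,
                calls = data.frame(gene_id = character(0),
                                   category = character(0), tpm = numeric(0),
                                   z = numeric(0), p = numeric(0),
                                   class = character(0),
                                   stringsAsFactors = FALSE)))
  gv <- rowMeans(em$values[expressed$genes, teratocyte_group, drop = FALSE])
  high <- character(0)
  zs <- ps <- stats::setNames(rep(NA_real_, length(gv)), names(gv))
  if (length(gv) >= 3 && stats::sd(log2(gv + 1)) > 0) {
    hz <- call_high_expression(gv, alpha = alpha)
    high <- hz$gene_id[hz$called]
    zs[hz$gene_id] <- hz$z
    ps[hz$gene_id] <- hz$p
  }
  cls <- rep(NA_character_, length(gv))
  names(cls) <- names(gv)
  if (!is.null(annotation)) {
    fc <- classify_function(annotation, keywords)
    hit <- intersect(names(cls), fc$gene_id)
    cls[hit] <- fc$class[match(hit, fc$gene_id)]
  }
  calls <- data.frame(
    gene_id = names(gv),
    category = ifelse(names(gv) %in% high, "teratocyte_high",
                      "teratocyte_effector"),
    tpm = unname(gv), z = unname(zs), p = unname(ps),
    class = unname(cls), stringsAsFactors = FALSE)
  calls <- calls[order(-calls$tpm, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  list(expressed = expressed, calls = calls)
}
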