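#' Gene-by-sample TPM expression container
#'
#' Thin validated container pairing a numeric gene x sample matrix of TPM
#' values with per-sample metadata (tissue, developmental stage, sex,
#' replicate). All expression statistics in the package operate on this
#' object.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values finite and >= 0.
#' @param metadata Data frame with columns `sample_id`, `tissue`, `stage`,
#'   `sex`, `replicate`; one row per column of `values`.
#'
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, metadata) {
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) || is.null(colnames(values)))
    stop("input error: expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("input error: duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("input error: duplicate sample identifiers", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("input error: expression values must all be finite numbers", call. = FALSE)
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("input error: negative TPM value at gene '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  req <- c("sample_id", "tissue", "stage", "sex", "replicate")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("input error: metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  only_matrix <- setdiff(colnames(values), metadata$sample_id)
  only_meta <- setdiff(metadata$sample_id, colnames(values))
  if (length(only_matrix) || length(only_meta))
    stop("input error: sample sets of matrix and metadata differ; orphans: ",
         paste(c(only_matrix, only_meta), collapse = ", "), call. = FALSE)
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tissue/stage/sex groups)\n",
              nrow(x$values), ncol(x$values),
              length(unique(group_keys(x)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Group key of each sample: one tissue/stage/sex combination = one group
# (replicates collapse within a group).
group_keys <- function(em) {
  with(em$metadata, paste(tissue, stage, sex, sep = "|"))
}

#' Sample identifiers belonging to a tissue
#'
#' @param em An [expression_matrix()].
#' @param tissue Tissue label to select.
#' @return Character vector of sample ids.
#' @export
samples_of_tissue <- function(em, tissue) {
  em$metadata$sample_id[em$metadata$tissue == tissue]
}

#' Read an expression table and its sample metadata
#'
#' Expects a TSV with a header row, the gene identifier in a first column
#' named `gene_id` and one column per sample, plus a companion metadata TSV
#' mapping `sample_id` to tissue, stage, sex and replicate. Genes are rows,
#' samples are columns — one fixed orientation avoids silent transposition.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("input error: first column of ", path, " must be named 'gene_id'",
         call. = FALSE)
  genes <- as.character(tab$gene_id)
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("input error: non-numeric or negative TPM at gene '%s', sample '%s' (value '%s')",
                   genes[bad[1]], names(vals)[j], as.character(vals[[j]][bad[1]])),
           call. = FALSE)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_matrix(m, meta)
}

#' Write an expression table and its metadata
#'
#' @param em An [expression_matrix()].
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, `em`.
#' @export
write_expression_table <- function(em, path, metadata_path = NULL) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(em$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(em)
}

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read a protein FASTA
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet plus X; duplicate identifiers and illegal characters are
#' rejected with the offending position.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids))
    stop("input error: duplicate FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    ok <- strsplit(seqs[[i]], "")[[1]] %in% AA_ALPHABET
    if (!all(ok))
      stop(sprintf("input error: illegal character in sequence '%s' at position %d",
                   ids[i], which(!ok)[1]), call. = FALSE)
    if (nchar(seqs[[i]]) == 0)
      stop("input error: empty sequence for '", ids[i], "'", call. = FALSE)
  }
  seqs
}

#' Write a protein FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read a proteomic peptide evidence table
#'
#' TSV with columns `peptide` (uppercase amino-acid sequence per observation)
#' and `spectrum_count`. Rows with the same peptide sequence are distinct
#' observations; distinctness is resolved at matching time.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `peptide`, `spectrum_count`.
#' @export
read_peptide_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "spectrum_count") %in% names(tab)))
    stop("input error: peptide table needs columns 'peptide' and 'spectrum_count'",
         call. = FALSE)
  tab$peptide <- toupper(as.character(tab$peptide))
  if (any(!nzchar(tab$peptide)))
    stop("input error: empty peptide sequence in ", path, call. = FALSE)
  tab
}

#' Read a functional annotation table
#'
#' TSV with columns `gene_id`, `domain_accessions` (semicolon-joined) and
#' `function_text`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain_accessions", "function_text")
  if (!all(need %in% names(tab)))
    stop("input error: annotation table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  tab$function_text[is.na(tab$function_text)] <- ""
  tab
}

#' Read a species x domain gene-copy count table
#'
#' Long TSV with columns `species`, `domain`, `count`; missing pairs are 0.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, species in rows, domain accessions in columns.
#' @export
read_domain_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "domain", "count") %in% names(tab)))
    stop("input error: domain-count table needs columns species, domain, count",
         call. = FALSE)
  if (any(tab$count < 0 | tab$count != round(tab$count)))
    stop("input error: domain counts must be non-negative integers", call. = FALSE)
  species <- sort(unique(tab$species))
  domains <- sort(unique(tab$domain))
  m <- matrix(0L, length(species), length(domains),
              dimnames = list(species, domains))
  m[cbind(match(tab$species, species), match(tab$domain, domains))] <-
    as.integer(tab$count)
  m
}

#' Write a species x domain count matrix as a long TSV
#' @param counts Matrix as returned by [read_domain_counts()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_counts <- function(counts, path) {
  long <- data.frame(
    species = rep(rownames(counts), times = ncol(counts)),
    domain = rep(colnames(counts), each = nrow(counts)),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$species, long$domain), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read replicate-level assay record CSVs
#'
#' Three schemas: parasitism (`replicate, host_species, host_age_days, mode,
#' n_hosts, n_emerged_host_adults, n_emerged_wasps`), two-choice oviposition
#' (`replicate, age_x, n1, nx, duration_h`) and dissection
#' (`replicate, group, n_dissected, n_with_eggs`). Count invariants are
#' validated on read.
#'
#' @param path Path to the CSV.
#' @param type One of `"parasitism"`, `"choice"`, `"dissection"`.
#' @return Data frame of validated records.
#' @export
read_assay_records <- function(path, type = c("parasitism", "choice", "dissection")) {
  type <- match.arg(type)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- switch(type,
    parasitism = c("replicate", "host_species", "host_age_days", "mode",
                   "n_hosts", "n_emerged_host_adults", "n_emerged_wasps"),
    choice = c("replicate", "age_x", "n1", "nx", "duration_h"),
    dissection = c("replicate", "group", "n_dissected", "n_with_eggs"))
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("input error: ", type, " records missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (type == "parasitism") {
    with(tab, {
      if (any(n_emerged_host_adults < 0 | n_emerged_host_adults > n_hosts) ||
          any(n_emerged_wasps < 0 | n_emerged_wasps > n_hosts) ||
          any(n_emerged_host_adults + n_emerged_wasps > n_hosts))
        stop("input error: parasitism record counts violate 0 <= adults, wasps, adults+wasps <= n_hosts",
             call. = FALSE)
      if (!all(mode %in% c("mono", "super")))
        stop("input error: parasitism mode must be 'mono' or 'super'", call. = FALSE)
    })
  } else if (type == "choice") {
    if (any(tab$n1 < 0 | tab$nx < 0))
      stop("input error: choice egg counts must be >= 0", call. = FALSE)
  } else {
    if (any(tab$n_with_eggs < 0 | tab$n_with_eggs > tab$n_dissected))
      stop("input error: dissection counts violate 0 <= n_with_eggs <= n_dissected",
           call. = FALSE)
  }
  tab
}
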