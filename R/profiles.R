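#' N99 cumulative-abundance expression threshold
#'
#' The expression threshold of a sample (or replicate-averaged sample group)
#' is the TPM value at which the cumulative abundance of genes, sorted in
#' descending order, first reaches `fraction` (default 99%) of the total:
#' genes at or above this value jointly account for 99% of the summarized
#' transcripts, and are called expressed.
#'
#' @param values Named numeric vector of per-gene TPM in one sample or group;
#'   all values must be >= 0.
#' @param fraction Cumulative fraction defining the threshold (default 0.99).
#' @param expressed_rule `"inclusive_ge"` (default) counts genes with TPM at
#'   or above the threshold as expressed; `"strict_gt"` requires strictly
#'   above. The threshold-defining gene itself is expressed under the
#'   inclusive rule.
#' @return List with `threshold` (a TPM value attained by some gene, or 0
#'   for an all-zero group), `n_expressed`, `fraction`, `expressed_rule`.
#' @export
compute_n99 <- function(values, fraction = 0.99,
                        expressed_rule = c("inclusive_ge", "strict_gt")) {
  expressed_rule <- match.arg(expressed_rule)
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stop("input error: values must be finite and >= 0", call. = FALSE)
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("parameter error: fraction must lie strictly between 0 and 1",
         call. = FALSE)
  total <- sum(values)
  if (total <= 0)
    return(list(threshold = 0, n_expressed = 0L, fraction = fraction,
                expressed_rule = expressed_rule))
  s <- sort(values, decreasing = TRUE)
  k <- which(cumsum(s) >= fraction * total)[1]
  thr <- s[[k]]
  n_exp <- if (expressed_rule == "inclusive_ge") sum(values >= thr)
           else sum(values > thr)
  list(threshold = unname(thr), n_expressed = as.integer(n_exp),
       fraction = fraction, expressed_rule = expressed_rule)
}

#' Call expressed genes in a sample group
#'
#' Averages TPM across the group's samples, computes the group's N99
#' threshold and returns the genes passing the expressed rule.
#'
#' @param em An [expression_matrix()].
#' @param sample_group Character vector of sample ids forming the group.
#' @param fraction,expressed_rule Passed to [compute_n99()].
#' @return List with `genes` (character vector), `threshold`, `n_expressed`.
#' @export
call_expressed <- function(em, sample_group, fraction = 0.99,
                           expressed_rule = c("inclusive_ge", "strict_gt")) {
  expressed_rule <- match.arg(expressed_rule)
  if (length(sample_group) == 0)
    stop("input error: sample_group must be non-empty", call. = FALSE)
  unknown <- setdiff(sample_group, colnames(em$values))
  if (length(unknown))
    stop("input error: unknown sample(s) in group: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  gv <- rowMeans(em$values[, sample_group, drop = FALSE])
  thr <- compute_n99(gv, fraction, expressed_rule)
  genes <- if (thr$n_expressed == 0) character(0)
           else if (expressed_rule == "inclusive_ge") names(gv)[gv >= thr$threshold]
           else names(gv)[gv > thr$threshold]
  list(genes = genes, threshold = thr$threshold,
       n_expressed = thr$n_expressed, fraction = fraction,
       expressed_rule = expressed_rule)
}

# Replicate-averaged mean TPM per tissue/stage/sex group; returns a gene x
# group matrix.
group_mean_matrix <- function(em) {
  keys <- group_keys(em)
  groups <- unique(keys)
  out <- vapply(groups, function(k)
    rowMeans(em$values[, keys == k, drop = FALSE]),
    numeric(nrow(em$values)))
  dimnames(out) <- list(rownames(em$values), groups)
  out
}

#' Tissue-specialization index
#'
#' Ratio of a gene's mean expression in a focal sample group to the mean of
#' the other tissue/stage group means. Replicates of each non-focal group
#' are averaged first, then the group means are averaged, so heavily
#' replicated groups do not dominate the denominator. A zero numerator over
#' a positive denominator gives 0; a positive numerator over a zero
#' denominator gives `Inf`; 0/0 gives `NaN`. An optional pseudocount
#' stabilizes rankings when zeros occur.
#'
#' @param em An [expression_matrix()].
#' @param focal_group Character vector of sample ids (e.g. the venom-gland
#'   replicates).
#' @param genes Genes to score (default all).
#' @param pseudocount Added to numerator and denominator (default 0).
#' @return Data frame with `gene_id`, `focal_mean`, `other_mean`, `index`.
#' @export
specialization_index <- function(em, focal_group, genes = NULL,
                                 pseudocount = 0) {
  if (length(focal_group) == 0)
    stop("input error: focal_group must be non-empty", call. = FALSE)
  unknown <- setdiff(focal_group, colnames(em$values))
  if (length(unknown))
    stop("input error: unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(genes)) genes <- rownames(em$values)
  missing_genes <- setdiff(genes, rownames(em$values))
  if (length(missing_genes))
    stop("input error: gene(s) absent from matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  keys <- group_keys(em)
  focal_idx <- colnames(em$values) %in% focal_group
  other_groups <- unique(keys[!focal_idx])
  # a sample group counts as non-focal only if none of its samples is focal
  other_groups <- setdiff(other_groups, unique(keys[focal_idx]))
  if (length(other_groups) == 0)
    stop("input error: no non-focal sample group exists", call. = FALSE)
  num <- rowMeans(em$values[genes, focal_group, drop = FALSE])
  gm <- vapply(other_groups, function(k)
    rowMeans(em$values[genes, keys == k & !focal_idx, drop = FALSE]),
    numeric(length(genes)))
  if (is.null(dim(gm))) gm <- matrix(gm, ncol = length(other_groups))
  den <- rowMeans(gm)
  n <- num + pseudocount
  d <- den + pseudocount
  idx <- ifelse(d > 0, n / d, ifelse(n > 0, Inf, NaN))
  data.frame(gene_id = genes, focal_mean = unname(num),
             other_mean = unname(den), index = unname(idx),
             stringsAsFactors = FALSE)
}

#' Z test for significantly high expression
#'
#' Standardizes log2(TPM + 1) across a candidate set with the sample
#' (n - 1) standard deviation and computes a one-sided upper-tail
#' standard-normal probability per candidate; genes with p below `alpha`
#' are called significantly highly expressed. TPM is heavy-tailed, hence
#' the log transform; the usage is directional ("significantly high"),
#' hence the one-sided tail. Both choices, and alpha, are arguments.
#'
#' @param values Named numeric vector of TPM per candidate gene (>= 3
#'   candidates).
#' @param alpha Significance level (default 0.05).
#' @param log_transform Apply log2(TPM + 1) first (default `TRUE`; set
#'   `FALSE` if `values` are already on the transformed scale).
#' @return Data frame with `gene_id`, `value`, `z`, `p`, `called`, sorted by
#'   decreasing `z`.
#' @export
call_high_expression <- function(values, alpha = 0.05, log_transform = TRUE) {
  if (length(values) < 3)
    stop("input error: need at least 3 candidates for the Z test, got ",
         length(values), call. = FALSE)
  if (is.null(names(values)))
    names(values) <- paste0("candidate_", seq_along(values))
  x <- if (log_transform) log2(values + 1) else values
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate-distribution error: candidate values have zero spread; ",
         "no high-expression call is possible", call. = FALSE)
  z <- (x - mean(x)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  out <- data.frame(gene_id = names(values), value = unname(values),
                    z = unname(z), p = unname(p),
                    called = unname(p < alpha), stringsAsFactors = FALSE)
  out[order(-out$z, out$gene_id), , drop = FALSE]
}

#' Order genes by expression-pattern similarity
#'
#' Standardizes each gene's profile to z-scores across samples and clusters
#' with average-linkage agglomeration on the 1 - Pearson correlation
#' distance. Genes are sorted lexicographically before clustering so that
#' ties resolve deterministically and the result is invariant to input
#' order; zero-variance genes cannot be standardized and are appended after
#' the clustered leaves.
#'
#' @param em An [expression_matrix()] or a numeric gene x sample matrix.
#' @param genes Gene subset to cluster (default all).
#' @return List with `order` (leaf order, a permutation of `genes`),
#'   `heights` (merge heights), `hclust` (the tree, or `NULL` for < 2
#'   clusterable genes), `constant` (zero-variance genes).
#' @export
cluster_profiles <- function(em, genes = NULL) {
  m <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (is.null(genes)) genes <- rownames(m)
  genes <- sort(genes)
  m <- m[genes, , drop = FALSE]
  if (length(genes) == 1)
    return(list(order = genes, heights = numeric(0), hclust = NULL,
                constant = character(0)))
  sds <- apply(m, 1, stats::sd)
  const <- genes[sds == 0]
  live <- genes[sds > 0]
  if (length(live) < 2)
    return(list(order = c(live, const), heights = numeric(0), hclust = NULL,
                constant = const))
  zs <- t(scale(t(m[live, , drop = FALSE])))
  d <- stats::as.dist(1 - stats::cor(t(zs)))
  hc <- stats::hclust(d, method = "average")
  list(order = c(live[hc$order], const), heights = hc$height, hclust = hc,
       constant = const)
}

#' Project samples by principal component analysis
#'
#' PCA of samples on log2(TPM + 1), genes centered. The sign of each axis is
#' fixed by requiring the largest-magnitude gene loading on that axis to be
#' positive, so projections are reproducible across platforms.
#'
#' @param em An [expression_matrix()] or numeric gene x sample matrix.
#' @return List with `coordinates` (samples x axes), `var_fraction`
#'   (non-increasing, sums to <= 1 over retained axes), `loadings`.
#' @export
project_samples <- function(em) {
  m <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (ncol(m) < 2)
    stop("input error: need at least 2 samples for ordination", call. = FALSE)
  x <- log2(m + 1)
  pr <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, k]))
    if (pr$rotation[j, k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  keep <- seq_len(ncol(pr$x))
  list(coordinates = pr$x[, keep, drop = FALSE],
       var_fraction = vf[keep], loadings = pr$rotation[, keep, drop = FALSE])
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes the fold change of a target transcript in a sample condition
#' relative to a control condition, each normalized to a reference
#' transcript (e.g. tubulin): dCt = Ct_target - Ct_reference per condition,
#' ddCt = dCt_sample - dCt_control, fold change = 2^-ddCt.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the sample condition.
#' @param ct_target_control,ct_ref_control Ct values in the control.
#' @return Fold change (1 when the Ct pattern is identical).
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)))
    stop("input error: all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
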