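# Independent brute-force oracles used to cross-check the implementation.

# Sort-and-scan N99 oracle: explicit running sum, no cumsum().
naive_n99 <- function(values, fraction = 0.99, rule = "inclusive_ge") {
  total <- sum(values)
  if (total <= 0) return(list(threshold = 0, n_expressed = 0L))
  s <- sort(values, decreasing = TRUE)
  run <- 0
  thr <- s[length(s)]
  for (i in seq_along(s)) {
    run <- run + s[i]
    if (run >= fraction * total) { thr <- s[i]; break }
  }
  n <- if (rule == "inclusive_ge") sum(values >= thr) else sum(values > thr)
  list(threshold = unname(thr), n_expressed = as.integer(n))
}

# Quadratic-time naive substring scan.
naive_substring_match <- function(protein, peptide, il_equivalence = FALSE) {
  if (il_equivalence) {
    protein <- chartr("L", "I", protein)
    peptide <- chartr("L", "I", peptide)
  }
  np <- nchar(peptide); n <- nchar(protein)
  if (np == 0 || np > n) return(FALSE)
  for (i in 1:(n - np + 1))
    if (substr(protein, i, i + np - 1) == peptide) return(TRUE)
  FALSE
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
signed_rank_enum_p <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings,
# computing U by pairwise comparison (independent of rank sums).
mw_enum_p <- function(a, b) {
  comb <- c(a, b)
  na <- length(a)
  u_obs <- sum(outer(a, b, ">"))
  sets <- utils::combn(length(comb), na)
  u_all <- apply(sets, 2, function(ix)
    sum(outer(comb[ix], comb[-ix], ">")))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Exhaustive pairwise-comparison sort oracle for expansion ranking.
naive_rank_expansions <- function(counts, focal) {
  others <- counts[setdiff(rownames(counts), focal), , drop = FALSE]
  rows <- lapply(colnames(counts), function(d) {
    mo <- max(others[, d])
    data.frame(domain = d, score = counts[focal, d] - mo,
               ratio = (counts[focal, d] + 1) / (mo + 1),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # selection sort with the stated comparison: score desc, ratio desc,
  # accession asc
  better <- function(i, j) {
    if (df$score[i] != df$score[j]) return(df$score[i] > df$score[j])
    if (df$ratio[i] != df$ratio[j]) return(df$ratio[i] > df$ratio[j])
    df$domain[i] < df$domain[j]
  }
  idx <- seq_len(nrow(df))
  out <- integer(0)
  while (length(idx)) {
    best <- idx[1]
    for (j in idx[-1]) if (better(j, best)) best <- j
    out <- c(out, best)
    idx <- setdiff(idx, best)
  }
  df[out, , drop = FALSE]
}

# Small expression matrix fixture: 2 tissues x 2 replicates + 2 more groups.
tiny_em <- function(values = NULL, n_genes = 4) {
  meta <- data.frame(
    sample_id = c("vg.r1", "vg.r2", "tc.r1", "tc.r2", "wb.r1", "ov.r1"),
    tissue = c("venom_gland", "venom_gland", "teratocyte", "teratocyte",
               "whole_body", "ovipositor"),
    stage = c("adult", "adult", "parasitic_stage", "parasitic_stage",
              "larva", "adult"),
    sex = c("female", "female", "mixed", "mixed", "mixed", "female"),
    replicate = c(1, 2, 1, 2, 1, 1), stringsAsFactors = FALSE)
  if (is.null(values)) {
    set.seed(42)
    values <- matrix(round(2^rnorm(n_genes * 6, 4, 1), 3), n_genes, 6,
                     dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                     meta$sample_id))
  }
  expression_matrix(values, meta)
}

# Small simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 1, ...) {
  simulation_config(
    n_genes = 300,
    planted_specialized = data.frame(
      gene_id = sprintf("g%04d", 1:8),
      focal_tissue = rep(c("venom_gland", "teratocyte"), c(6, 2)),
      fold_factor = 8, stringsAsFactors = FALSE),
    planted_secreted = sprintf("g%04d", 1:4),
    n_decoy_proteins = 30,
    n_domains = 40, n_other_species = 5,
    n_assay_replicates = 4, n_choice_replicates = 3,
    seed = seed, ...)
}
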