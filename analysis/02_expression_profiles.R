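#!/usr/bin/env Rscript

# Stage 2: expression profiling.
#
# Per-group N99 expression thresholds, venom-gland and teratocyte
# specialization indices, the high-expression Z test over venom-gland
# expressed genes, expression-pattern clustering of the most specialized
# genes, and a PCA of all samples.

library(effectorscan)

in_dir <- "results/synthetic"
if (!file.exists(file.path(in_dir, "expression.tsv")))
  stop("run analysis/01_simulate.R first")

em <- read_expression_table(file.path(in_dir, "expression.tsv"),
                            file.path(in_dir, "samples.tsv"))
cfg <- run_config(seed = 101L)

# N99 threshold per tissue/stage/sex group
gm <- effectorscan:::group_mean_matrix(em)
thresholds <- do.call(rbind, lapply(colnames(gm), function(g) {
  t <- compute_n99(gm[, g], cfg$n99_fraction, cfg$expressed_rule)
  data.frame(group = g, n99_threshold_tpm = t$threshold,
             n_expressed = t$n_expressed)
}))
write.table(thresholds, "results/thresholds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("per-group N99 thresholds (TPM):\n")
print(thresholds, row.names = FALSE)

# specialization indices for the two effector-producing tissues
for (tissue in c("venom_gland", "teratocyte")) {
  si <- specialization_index(em, samples_of_tissue(em, tissue))
  si <- si[order(-si$index), ]
  write.table(si, sprintf("results/specialization_%s.tsv", tissue),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n%s: %d genes with specialization index > 4 (top gene %s, index %.1f)\n",
              tissue, sum(si$index > 4, na.rm = TRUE), si$gene_id[1], si$index[1]))
}

# high-expression Z test over the venom-gland expressed set
vg <- samples_of_tissue(em, "venom_gland")
vg_expressed <- call_expressed(em, vg, cfg$n99_fraction, cfg$expressed_rule)
vg_mean <- rowMeans(em$values[vg_expressed$genes, vg, drop = FALSE])
hz <- call_high_expression(vg_mean, alpha = cfg$alpha)
write.table(hz, "results/high_expression_vg.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nvenom gland: %d expressed genes (threshold %.2f TPM), %d significantly high (Z test, p < %.2f)\n",
            length(vg_expressed$genes), vg_expressed$threshold,
            sum(hz$called), cfg$alpha))

# cluster the 50 most venom-gland-specialized genes by expression pattern
si_vg <- read.delim("results/specialization_venom_gland.tsv")
top <- head(si_vg$gene_id[is.finite(si_vg$index)], 50)
cl <- cluster_profiles(em, top)
writeLines(cl$order, "results/cluster_order_top_specialized.txt")
cat(sprintf("clustered top %d specialized genes; first leaves: %s\n",
            length(top), paste(head(cl$order, 5), collapse = ", ")))

# sample ordination
pr <- project_samples(em)
proj <- data.frame(sample_id = rownames(pr$coordinates),
                   round(pr$coordinates[, 1:3], 4))
write.table(proj, "results/sample_projection.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PCA: first three axes explain %.1f%%, %.1f%%, %.1f%% of variance\n",
            100 * pr$var_fraction[1], 100 * pr$var_fraction[2],
            100 * pr$var_fraction[3]))
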