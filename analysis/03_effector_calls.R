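#!/usr/bin/env Rscript

# Stage 3: effector calling.
#
# Venom proteins = venom-gland-expressed genes (N99 rule) whose protein
# product is fully aligned by >= 3 distinct proteomic peptides; highly
# expressed venom proteins by the Z test over the venom-protein set.
# Teratocyte effectors = teratocyte-expressed genes, with the
# significantly high subset and functional classes. Calls are scored
# against the planted truth.

library(effectorscan)

in_dir <- "results/synthetic"
if (!file.exists(file.path(in_dir, "expression.tsv")))
  stop("run analysis/01_simulate.R first")

cfg <- run_config(seed = 101L)
bundle <- run_pipeline(cfg, input_dir = in_dir)
write_result_bundle(bundle, "results/result_bundle.json")

venom <- bundle$effectors$venom_proteins
write.table(venom, "results/effector_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tera <- bundle$effectors$teratocyte
write.table(tera$calls, "results/teratocyte_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(in_dir, "truth.json"),
                             simplifyVector = TRUE)$genes
secreted <- truth$gene_id[truth$secreted]
tp <- sum(venom$gene_id %in% secreted)

print(bundle)
cat(sprintf("\nvenom-protein calls vs planted truth: %d/%d true positives, %d false positives\n",
            tp, length(secreted), nrow(venom) - tp))
high_tc <- tera$calls[tera$calls$category == "teratocyte_high", ]
cat(sprintf("teratocyte high set: %d genes; class breakdown: %s\n",
            nrow(high_tc),
            paste(names(table(high_tc$class)), table(high_tc$class),
                  sep = "=", collapse = ", ")))
planted_tc <- truth$gene_id[truth$specialized &
                              !is.na(truth$focal_tissue) &
                              truth$focal_tissue == "teratocyte"]
cat(sprintf("planted teratocyte digestion genes recovered in high set: %d/%d\n",
            sum(planted_tc %in% high_tc$gene_id), length(planted_tc)))
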