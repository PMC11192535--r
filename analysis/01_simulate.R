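#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study.
#
# Emits every input the pipeline consumes — the 18-sample multi-tissue TPM
# matrix with 30 venom-gland-specialized genes (fold 8) and 10
# teratocyte-specialized digestion genes, the candidate proteome with 20
# secreted proteins backed by tryptic-peptide evidence, the species x domain
# copy-number table with one family planted at 29 focal copies, and the
# parasitism / two-choice / dissection assay records — plus truth.json with
# the planted ground truth.

library(effectorscan)

seed <- 101L
out_dir <- "results/synthetic"

cfg <- simulation_config(seed = seed)
res <- write_synthetic_inputs(cfg, out_dir)

truth <- res$truth$genes
cat(sprintf("synthetic study written to %s (seed %d)\n", out_dir, seed))
cat(sprintf("  genes: %d; planted specialized: %d (%d venom-gland, %d teratocyte)\n",
            cfg$n_genes, sum(truth$specialized),
            sum(truth$focal_tissue == "venom_gland", na.rm = TRUE),
            sum(truth$focal_tissue == "teratocyte", na.rm = TRUE)))
cat(sprintf("  secreted with peptide support: %d (detection prob %.2f)\n",
            sum(truth$secreted), cfg$peptide_detection_prob))
cat(sprintf("  planted domain %s: %d focal copies vs Poisson(%g) in %d comparators\n",
            cfg$planted_domain$accession, cfg$planted_domain$focal_count,
            cfg$planted_domain$other_count_lambda, cfg$n_other_species))
cat(sprintf("  assay design: ages 1-4 x mono/super, %d replicates x %d hosts\n",
            cfg$n_assay_replicates, cfg$n_hosts))
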