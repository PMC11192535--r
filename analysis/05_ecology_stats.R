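#!/usr/bin/env Rscript

# Stage 5: behavioral and parasitism statistics.
#
# Replicate-level parasitism and emergence rates by host age and mode with
# the superparasitism fold recovery; oviposition preference indices with
# signed-rank tests against zero; and the interspecific-competition
# dissection comparison (Mann-Whitney U).

library(effectorscan)

in_dir <- "results/synthetic"
if (!file.exists(file.path(in_dir, "parasitism.csv")))
  stop("run analysis/01_simulate.R first")

par_rec <- read_assay_records(file.path(in_dir, "parasitism.csv"), "parasitism")
choice_rec <- read_assay_records(file.path(in_dir, "choice.csv"), "choice")
diss_rec <- read_assay_records(file.path(in_dir, "dissection.csv"), "dissection")

cond <- summarize_conditions(par_rec)
write.table(cond, "results/rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("parasitism / emergence rates (mean % +/- SEM) by host age and mode:\n")
print(within(cond, {
  parasitism <- sprintf("%.1f+/-%.1f", mean_parasitism_rate, sem_parasitism_rate)
  emergence <- sprintf("%.1f+/-%.1f", mean_emergence_rate, sem_emergence_rate)
})[, c("host_age_days", "mode", "parasitism", "emergence")], row.names = FALSE)

f <- fold_recovery(cond[cond$mode == "mono" & cond$host_age_days == 4, ],
                   cond[cond$mode == "super" & cond$host_age_days == 4, ])
cat(sprintf("\nsuperparasitism recovery on 4-day-old hosts: %.2f-fold (parasitism), %.2f-fold (emergence)\n",
            f$parasitism_fold, f$emergence_fold))

choice <- summarize_choice(choice_rec)
write.table(choice$summary, "results/oviposition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\noviposition indices (1-day-old vs X-day-old hosts), signed-rank test vs 0:\n")
print(choice$summary[, c("age_x", "duration_h", "mean_index", "signed_rank_p")],
      row.names = FALSE)

diss <- summarize_dissection(diss_rec)
write.table(diss$summary, "results/competition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\ncompetition avoidance: NH %.1f%% vs PH %.1f%% hosts with eggs (Mann-Whitney p = %.3g)\n",
            diss$summary$mean_rate[diss$summary$group == "NH"],
            diss$summary$mean_rate[diss$summary$group == "PH"],
            diss$test$p))

tests <- list(
  oviposition_signed_rank = choice$summary[, c("age_x", "duration_h",
                                               "signed_rank_p", "method_detail")],
  competition_mann_whitney = unclass(diss$test),
  fold_recovery = f
)
jsonlite::write_json(tests, "results/tests.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("\ntest details written to results/tests.json\n")
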