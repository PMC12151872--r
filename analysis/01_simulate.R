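#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input used by the downstream
# analyses, with ground truth, under results/data/.  All later scripts
# read these files back through the package's readers, so the file
# contracts are exercised end to end.

suppressPackageStartupMessages(library(longescreen))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("— knockout compendium + lifespan phenotypes (200 strains x 500 genes, 5 drivers)")
scr <- simulate_screen_dataset(M = 200, G = 500, n_drivers = 5, seed = seed)
write_phenotypes(scr$phenotypes, file.path(out, "phenotypes.tsv"))
write_compendium(scr$compendium, file.path(out, "compendium.tsv"))
write_tsv(data.frame(gene_id = scr$truth$drivers,
                     true_slope = unname(scr$truth$slopes)),
          file.path(out, "screen_truth.tsv"))

message("— lifespan cohorts at the reported group means (control 23.92, knockdown 28.10; n = 150)")
cohort <- simulate_lifespan_cohort(c(control = 23.92, knockdown = 28.10),
                                   ns = 150, seed = seed + 1L)
write_lifespans(cohort, file.path(out, "lifespans.tsv"))

message("— dose-response cohorts (RNAi fractions 0..100%, peak mean 19.43 at 50%)")
doses <- seq(0, 100, by = 12.5)
dose_means <- c(16.35, 17.2, 18.1, 18.9, 19.43, 18.9, 18.2, 17.6, 17.0)
dr <- simulate_lifespan_cohort(setNames(dose_means, paste0("dose", doses)),
                               ns = 150, seed = seed + 2L)
write_lifespans(dr, file.path(out, "dose_lifespans.tsv"))

message("— replicate FPKM experiment (1500 genes, 4+4 replicates, 50 up / 50 down planted)")
sim <- simulate_expression_experiment(G = 1500, n_reps = 4, seed = seed + 3L)
write_expression(sim$experiment, file.path(out, "expression.tsv"),
                 control_label = "gLacZ", treatment_label = "gTOP2B")
write_tsv(sim$promoter, file.path(out, "promoter_states.tsv"))
write_tsv(sim$terms, file.path(out, "gene_terms.tsv"))
write_tsv(data.frame(gene_id = names(sim$truth$true_log2fc),
                     true_log2fc = unname(sim$truth$true_log2fc)),
          file.path(out, "expression_truth.tsv"))

message("done: inputs + truth tables under ", out)
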