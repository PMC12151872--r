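#!/usr/bin/env Rscript

# Stage 2: the longevity screen.  Regresses per-strain lifespan change
# on each gene's expression log2 fold change, weighting strains by
# n/(n+50) of their dissected cell count, and ranks genes by the
# p-value of the slope.  Reports how many planted drivers reach the
# top 10.

suppressPackageStartupMessages(library(longescreen))

phen <- read_phenotypes("results/data/phenotypes.tsv")
comp <- read_compendium("results/data/compendium.tsv")
truth <- read.delim("results/data/screen_truth.tsv")

scr <- screen_genes(comp, phen, offset = 50, min_strains = 10)
write_screen_results(scr, "results/screen_results.tsv")

top <- head(scr$results, 10)
message(sprintf("screened %d genes across %d strains", nrow(scr$results),
                scr$n_strains))
message(sprintf("planted drivers in top 10: %d/%d",
                sum(truth$gene_id %in% top$gene_id), nrow(truth)))
hits <- merge(truth, scr$results, by = "gene_id")
message("driver slope recovery (true vs. estimated):")
for (i in seq_len(nrow(hits)))
  message(sprintf("  %s: true %+0.2f, fitted %+0.2f (rank %d, p = %.2e)",
                  hits$gene_id[i], hits$true_slope[i], hits$slope[i],
                  hits$rank[i], hits$p_value[i]))
message("full ranking written to results/screen_results.tsv")
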