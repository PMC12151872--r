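#!/usr/bin/env Rscript

# Stage 4: transcriptome stratification.  Calls DEGs at |log2FC| > 1
# and BH-adjusted p < 0.05, then asks *which* genes move: promoter
# transcriptional state of up vs. down DEGs, up/down ratio across
# abundance bins (extremely-high = total control FPKM > 5000), and
# Fisher-exact term enrichment of the down-regulated set.

suppressPackageStartupMessages(library(longescreen))

expr <- read_expression("results/data/expression.tsv", control = "gLacZ")
promoter <- read_promoter_states("results/data/promoter_states.tsv")
terms <- read_gene_terms("results/data/gene_terms.tsv")
truth <- read.delim("results/data/expression_truth.tsv")

stats_df <- compute_deg_stats(expr)
write_tsv(stats_df, "results/deg_stats.tsv")
degs <- call_degs(stats_df, lfc_cut = 1, alpha = 0.05, tissue = "muscle")
message(sprintf("DEGs: %d up, %d down (of %d genes)", length(degs$up),
                length(degs$down), nrow(stats_df)))
planted <- truth$gene_id[truth$true_log2fc != 0]
message(sprintf("recall of planted DEGs: %.2f",
                mean(planted %in% c(degs$up, degs$down))))

prom <- promoter_state_enrichment(degs, promoter)
write_tsv(data.frame(prop_active_up = prom$prop_active_up,
                     prop_active_down = prom$prop_active_down,
                     chi_square = prom$chi_square, p_value = prom$p_value),
          "results/promoter_enrichment.tsv")
message(sprintf(
  "active promoters: %.0f%% of down DEGs vs %.0f%% of up DEGs (chi-sq %.1f, p = %.2e)",
  100 * prom$prop_active_down, 100 * prom$prop_active_up,
  prom$chi_square, prom$p_value))

totals <- rowSums(expr$fpkm_control)
bins <- assign_abundance_bins(totals, extreme_fpkm = 5000)
ratios <- updown_ratio_by_bin(degs, bins)
write_tsv(ratios, "results/abundance_ratios.tsv")
message("up/down ratio by abundance bin:")
for (i in seq_len(nrow(ratios)))
  message(sprintf("  %-15s %2d up / %2d down  ratio %s", ratios$bin[i],
                  ratios$n_up[i], ratios$n_down[i],
                  ifelse(is.na(ratios$ratio[i]), "undefined",
                         sprintf("%.2f", ratios$ratio[i]))))

enr <- fisher_enrichment(degs$down, terms, background = expr$genes)
write_tsv(enr, "results/enrichment_down.tsv")
message(sprintf("top down-set term: %s (overlap %d/%d, q = %.2e)",
                enr$term_id[1], enr$overlap[1], enr$term_size[1],
                enr$q_value[1]))
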