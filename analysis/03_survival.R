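#!/usr/bin/env Rscript

# Stage 3: lifespan-assay statistics.  Group summaries and percent
# extension, Kaplan-Meier curves, the two-group log-rank test, and the
# LOESS dose-response of knockdown level against lifespan extension.

suppressPackageStartupMessages(library(longescreen))

cohort <- read_lifespans("results/data/lifespans.tsv")
groups <- unique(cohort$group)

sums <- do.call(rbind, lapply(groups, function(g)
  summarize_group(cohort, g, unit = "divisions")))
ctrl <- sums$mean[sums$group == "control"]
sums$pct_extension_vs_control <-
  vapply(sums$mean, function(m) percent_extension(m, ctrl), 0)
write_tsv(sums, "results/survival_summary.tsv")
for (i in seq_len(nrow(sums)))
  message(sprintf("%s: mean %.2f (n = %d), extension %+0.1f%%",
                  sums$group[i], sums$mean[i], sums$n[i],
                  round(sums$pct_extension_vs_control[i], 1)))

km <- do.call(rbind, lapply(groups, function(g)
  cbind(group = g, kaplan_meier(cohort[cohort$group == g, ]))))
write_tsv(km, "results/km_curves.tsv")

lr <- log_rank_test(cohort[cohort$group == "control", ],
                    cohort[cohort$group == "knockdown", ])
write_tsv(data.frame(chi_square = lr$chi_square, p_value = lr$p_value),
          "results/log_rank.tsv")
message(sprintf("log-rank: chi-square %.2f, p = %.3g", lr$chi_square,
                lr$p_value))

dr_rec <- read_lifespans("results/data/dose_lifespans.tsv")
dose <- as.numeric(sub("dose", "", dr_rec$group))
d0 <- mean(dr_rec$lifespan[dose == 0 & dr_rec$observed])
ext <- vapply(sort(unique(dose)), function(d)
  percent_extension(mean(dr_rec$lifespan[dose == d & dr_rec$observed]), d0),
  0)
pts <- data.frame(dose = sort(unique(dose)), response = ext)
fit <- loess_dose_response(pts, span = 0.75)
write_tsv(fit$points, "results/dose_response_points.tsv")
write_tsv(fit$grid, "results/dose_response_fit.tsv")
best <- fit$grid$dose[which.max(fit$grid$fit)]
message(sprintf(
  "dose-response: smoothed extension peaks at %.0f%% knockdown (%.1f%%)",
  best, max(fit$grid$fit)))
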