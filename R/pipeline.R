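# End-to-end synthetic pipeline: simulate -> screen; cohorts ->
# survival statistics and dose-response; experiment -> DEGs ->
# stratification -> enrichment.  Every run writes plain TSV results plus
# a deterministic JSON manifest (no timestamps), so identical
# config + seed reproduces identical bytes.

#' Build and validate a pipeline configuration
#'
#' Thresholds and sizes for [run_pipeline()].  Validation happens here,
#' before any computation.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed; per-stage seeds are derived as
#'   `seed`, `seed + 1`, ... (keep below 2^31 - 10).
#' @param lfc_cut,alpha DEG thresholds (defaults 1 and 0.05).
#' @param extreme_fpkm Strict lower edge of the extremely-high abundance
#'   class (default 5000).
#' @param weight_offset Screen weight-formula constant (default 50).
#' @param loess_span Dose-response LOESS span (default 0.75).
#' @param min_strains Minimum usable strains per screened gene.
#' @param screen List of sizes for the screen stage (`M`, `G`,
#'   `n_drivers`).
#' @param cohorts Named numeric vector of target mean lifespans for the
#'   survival stage; first entry is the control.
#' @param cohort_n Per-group cohort size.
#' @param doses,dose_means RNAi dose fractions and the target mean
#'   lifespan at each dose for the dose-response stage (dose 0 is the
#'   control).
#' @param experiment List of sizes for the expression stage (`G`,
#'   `n_reps`, `n_up`, `n_down`, `lfc`).
#' @param tissues Tissue labels for the multi-tissue expression stage
#'   (>= 2 so shared-DEG analysis runs).
#' @param n_shared_down How many planted down-regulated genes are shared
#'   across all tissues.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(
    out_dir,
    seed = 1,
    lfc_cut = 1, alpha = 0.05, extreme_fpkm = 5000,
    weight_offset = 50, loess_span = 0.75, min_strains = 10,
    screen = list(M = 120, G = 300, n_drivers = 5),
    cohorts = c(control = 23.92, knockdown = 28.10),
    cohort_n = 150,
    doses = seq(0, 100, by = 12.5),
    dose_means = c(16.35, 17.2, 18.1, 18.9, 19.43, 18.9, 18.2, 17.6, 17.0),
    experiment = list(G = 1500, n_reps = 4, n_up = 50, n_down = 50, lfc = 2),
    tissues = c("kidney", "lung", "muscle"),
    n_shared_down = 23) {
  check_number(seed, "seed", lower = 0, upper = 2^31 - 10)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(lfc_cut, "lfc_cut", lower = 0, strict_lower = TRUE)
  check_number(extreme_fpkm, "extreme_fpkm", lower = 0, strict_lower = TRUE)
  check_number(weight_offset, "weight_offset", lower = 0, strict_lower = TRUE)
  check_number(loess_span, "loess_span", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(min_strains, "min_strains", lower = 3)
  if (length(doses) != length(dose_means))
    stop_config("`doses` and `dose_means` must have equal length")
  if (length(cohorts) < 2L || is.null(names(cohorts)))
    stop_config("`cohorts` must be a named vector with >= 2 groups")
  if (anyDuplicated(tissues) || length(tissues) < 2L)
    stop_config("`tissues` must be >= 2 unique labels")
  if (n_shared_down > experiment$n_down)
    stop_config("`n_shared_down` cannot exceed the planted down count")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), lfc_cut = lfc_cut,
         alpha = alpha, extreme_fpkm = extreme_fpkm,
         weight_offset = weight_offset, loess_span = loess_span,
         min_strains = min_strains, screen = screen, cohorts = cohorts,
         cohort_n = cohort_n, doses = doses, dose_means = dose_means,
         experiment = experiment, tissues = tissues,
         n_shared_down = n_shared_down),
    class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes the simulate -> screen, survival, and expression ->
#' stratification -> enrichment stages from one validated configuration,
#' writing every result as TSV under `config$out_dir` plus a
#' deterministic `manifest.json` recording versions, seeds, thresholds
#' and per-stage record counts.
#'
#' @param config A `"pipeline_config"`.
#' @param quiet Suppress per-stage progress messages.
#' @return (Invisibly) list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop_input("`config` must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  put <- function(df, f) {
    write_tsv(df, path(f))
    files <<- c(files, f)
  }

  ## Stage 1: longevity screen on a simulated compendium
  say("[screen] simulating %d strains x %d genes",
      config$screen$M, config$screen$G)
  scr_data <- simulate_screen_dataset(
    M = config$screen$M, G = config$screen$G,
    n_drivers = config$screen$n_drivers, seed = config$seed)
  write_phenotypes(scr_data$phenotypes, path("phenotypes.tsv"))
  write_compendium(scr_data$compendium, path("compendium.tsv"))
  files <- c(files, "phenotypes.tsv", "compendium.tsv")
  put(data.frame(gene_id = scr_data$truth$drivers,
                 true_slope = unname(scr_data$truth$slopes)),
      "screen_truth.tsv")
  screen <- screen_genes(scr_data$compendium, scr_data$phenotypes,
                         offset = config$weight_offset,
                         min_strains = config$min_strains)
  write_screen_results(screen, path("screen_results.tsv"))
  files <- c(files, "screen_results.tsv")
  top10 <- utils::head(screen$results$gene_id, 10)
  n_recovered <- sum(scr_data$truth$drivers %in% top10)
  say("[screen] %d/%d planted drivers in the top 10",
      n_recovered, length(scr_data$truth$drivers))

  ## Stage 2: lifespan cohorts, KM, log-rank, percent extension
  say("[survival] cohorts: %s",
      paste(names(config$cohorts), collapse = ", "))
  cohort <- simulate_lifespan_cohort(config$cohorts,
                                     ns = config$cohort_n,
                                     seed = config$seed + 1L)
  write_lifespans(cohort, path("lifespans.tsv"))
  files <- c(files, "lifespans.tsv")
  groups <- names(config$cohorts)
  sums <- do.call(rbind, lapply(groups, function(g)
    summarize_group(cohort, g)))
  ctrl_mean <- sums$mean[sums$group == groups[1]]
  sums$pct_extension_vs_control <- vapply(
    sums$mean, function(m) percent_extension(m, ctrl_mean), 0)
  put(sums, "survival_summary.tsv")
  km <- do.call(rbind, lapply(groups, function(g) {
    k <- kaplan_meier(cohort[cohort$group == g, , drop = FALSE])
    cbind(group = g, k)
  }))
  put(km, "km_curves.tsv")
  lr <- log_rank_test(cohort[cohort$group == groups[1], ],
                      cohort[cohort$group == groups[2], ])
  put(data.frame(group_a = groups[1], group_b = groups[2],
                 chi_square = lr$chi_square, p_value = lr$p_value),
      "log_rank.tsv")
  say("[survival] log-rank chi-square %.2f (p = %.3g)",
      lr$chi_square, lr$p_value)

  ## Stage 3: dose-response of knockdown level vs. extension
  dr_means <- stats::setNames(config$dose_means,
                              paste0("dose", config$doses))
  dr_cohort <- simulate_lifespan_cohort(dr_means, ns = config$cohort_n,
                                        seed = config$seed + 2L)
  dr_ctrl <- mean(dr_cohort$lifespan[dr_cohort$group == "dose0" &
                                       dr_cohort$observed])
  ext <- vapply(paste0("dose", config$doses), function(g) {
    percent_extension(
      mean(dr_cohort$lifespan[dr_cohort$group == g & dr_cohort$observed]),
      dr_ctrl)
  }, 0)
  dr_points <- data.frame(dose = config$doses, response = unname(ext))
  dr <- loess_dose_response(dr_points, span = config$loess_span,
                            grid_n = 41)
  put(dr$points, "dose_response_points.tsv")
  put(dr$grid, "dose_response_fit.tsv")

  ## Stage 4: per-tissue expression experiments and stratification
  exp_seed <- config$seed + 3L
  first_truth <- NULL
  degsets <- list()
  shared_ids <- NULL
  strat_rows <- list()
  for (i in seq_along(config$tissues)) {
    tissue <- config$tissues[i]
    say("[expression] simulating tissue '%s'", tissue)
    planted <- list(n_up = config$experiment$n_up,
                    n_down = config$experiment$n_down,
                    lfc = config$experiment$lfc)
    if (i == 1L) {
      sim <- simulate_expression_experiment(
        G = config$experiment$G, n_reps = config$experiment$n_reps,
        planted = planted, seed = exp_seed)
      shared_ids <- sim$truth$down_ids[seq_len(config$n_shared_down)]
      first_truth <- sim$truth
    } else {
      planted$down_ids <- shared_ids
      sim <- simulate_expression_experiment(
        G = config$experiment$G, n_reps = config$experiment$n_reps,
        planted = planted, seed = exp_seed + i - 1L)
    }
    stats_df <- compute_deg_stats(sim$experiment)
    put(stats_df, sprintf("deg_stats_%s.tsv", tissue))
    degset <- call_degs(stats_df, lfc_cut = config$lfc_cut,
                        alpha = config$alpha, tissue = tissue)
    degsets[[tissue]] <- degset
    put(data.frame(
      gene_id = c(degset$up, degset$down),
      direction = rep(c("up", "down"),
                      c(length(degset$up), length(degset$down)))),
      sprintf("degs_%s.tsv", tissue))
    if (i == 1L) {
      # deeper stratification on the first tissue only
      prom <- promoter_state_enrichment(degset, sim$promoter)
      strat_rows$promoter <- data.frame(
        tissue = tissue,
        prop_active_up = prom$prop_active_up,
        prop_active_down = prom$prop_active_down,
        chi_square = prom$chi_square, p_value = prom$p_value,
        n_unannotated = prom$n_unannotated)
      totals <- rowSums(sim$experiment$fpkm_control)
      bins <- assign_abundance_bins(totals,
                                    extreme_fpkm = config$extreme_fpkm)
      ratios <- updown_ratio_by_bin(degset, bins)
      ratios <- cbind(tissue = tissue, ratios)
      put(ratios, "abundance_ratios.tsv")
      enr <- fisher_enrichment(degset$down, sim$terms,
                               background = sim$experiment$genes)
      put(enr, "enrichment_down.tsv")
      say("[expression] top enriched term: %s (q = %.3g)",
          enr$term_id[1], enr$q_value[1])
    }
  }
  put(strat_rows$promoter, "promoter_enrichment.tsv")
  shared <- shared_degs(unname(degsets))
  put(shared$up, "shared_degs_up.tsv")
  put(shared$down, "shared_degs_down.tsv")
  put(data.frame(gene_id = shared$shared_all_down), "shared_all_down.tsv")
  say("[expression] %d down-regulated genes shared across all tissues",
      length(shared$shared_all_down))

  manifest <- list(
    package = "longescreen",
    package_version = as.character(utils::packageVersion("longescreen")),
    seed = config$seed,
    thresholds = list(lfc_cut = config$lfc_cut, alpha = config$alpha,
                      extreme_fpkm = config$extreme_fpkm,
                      weight_offset = config$weight_offset,
                      loess_span = config$loess_span,
                      min_strains = config$min_strains),
    sizes = list(screen = config$screen, cohort_n = config$cohort_n,
                 experiment = config$experiment,
                 tissues = config$tissues,
                 n_shared_down = config$n_shared_down),
    counts = list(
      genes_tested = nrow(screen$results),
      genes_skipped = nrow(screen$skipped),
      drivers_in_top10 = n_recovered,
      lifespan_records = nrow(cohort),
      degs_per_tissue = lapply(degsets, function(d)
        list(up = length(d$up), down = length(d$down))),
      shared_all_down = length(shared$shared_all_down)),
    files = sort(unique(files)))
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, screen = screen, cohort = cohort,
                 survival_summary = sums, log_rank = lr,
                 dose_response = dr, degsets = degsets, shared = shared,
                 truth = list(screen = scr_data$truth,
                              expression = first_truth)))
}
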