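# Synthetic-data generators.  All randomness goes through R's default
# Mersenne-Twister generator seeded once per call (set.seed(seed)), so a
# given seed reproduces a dataset byte-for-byte across runs and
# platforms.

#' Simulate a knockout expression compendium with planted longevity
#' drivers
#'
#' Strain-by-gene expression log2 fold changes are iid standard normal.
#' Per-strain lifespan change (percent vs. wild type) is a linear
#' combination of a few "driver" genes' expression plus heteroscedastic
#' noise whose variance is `sigma^2 * (n + 50) / n` for a strain with
#' `n` dissected cells — so the screen's reliability weight
#' `w = n / (n + 50)` is exactly the inverse-variance weight.
#'
#' Default scales state a realistic world: driver slopes of 3-8 percent
#' lifespan change per unit log2 fold change, residual noise sigma = 5
#' percent, and 10-200 cells per assay.
#'
#' @param M Number of strains (>= 20).
#' @param G Number of genes (>= `n_drivers`).
#' @param n_drivers Number of planted driver genes (may be 0 for null
#'   datasets).
#' @param slope_range Range the true driver slopes are drawn from
#'   (uniform; a random sign is applied).
#' @param sigma Residual noise scale (percent lifespan change).
#' @param cellcount_range Integer range for per-strain cell counts.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return List: `compendium` (M x G matrix, strains x genes),
#'   `phenotypes` (data frame `strain_id`, `lifespan_change`,
#'   `n_cells`), `truth` (list: `drivers`, `slopes`, `sigma`,
#'   `cellcount_range`, `seed`).
#' @export
simulate_screen_dataset <- function(M = 200, G = 500, n_drivers = 5,
                                    slope_range = c(3, 8), sigma = 5,
                                    cellcount_range = c(10, 200),
                                    seed = 1) {
  check_number(M, "M", lower = 20)
  check_number(G, "G", lower = max(1, n_drivers))
  check_number(n_drivers, "n_drivers", lower = 0)
  check_number(sigma, "sigma", lower = 0)
  if (length(slope_range) != 2L || slope_range[1] > slope_range[2] ||
      any(slope_range < 0))
    stop_config("`slope_range` must be an increasing non-negative pair")
  if (length(cellcount_range) != 2L ||
      cellcount_range[1] > cellcount_range[2] || cellcount_range[1] < 1)
    stop_config("`cellcount_range` must be an increasing pair of counts >= 1")
  set.seed(seed)
  strains <- sprintf("strain%03d", seq_len(M))
  genes <- sprintf("gene%04d", seq_len(G))
  x <- matrix(stats::rnorm(M * G), nrow = M,
              dimnames = list(strains, genes))
  drivers <- sort(sample(genes, n_drivers))
  slopes <- stats::runif(n_drivers, slope_range[1], slope_range[2]) *
    sample(c(-1, 1), n_drivers, replace = TRUE)
  n_cells <- sample(seq(cellcount_range[1], cellcount_range[2]), M,
                    replace = TRUE)
  eps_sd <- sigma * sqrt((n_cells + 50) / n_cells)
  y <- as.numeric(x[, drivers, drop = FALSE] %*% slopes) +
    stats::rnorm(M, sd = eps_sd)
  list(
    compendium = x,
    phenotypes = data.frame(strain_id = strains, lifespan_change = y,
                            n_cells = n_cells, stringsAsFactors = FALSE),
    truth = list(drivers = drivers,
                 slopes = stats::setNames(slopes, drivers),
                 sigma = sigma, cellcount_range = cellcount_range,
                 seed = seed))
}

# Mean of a Gompertz(shape b, rate r) lifetime, S(t) = exp(-(r/b)(e^{bt}-1)).
gompertz_mean <- function(b, r) {
  stats::integrate(function(t) exp(-(r / b) * (expm1(b * t))),
                   lower = 0, upper = Inf, rel.tol = 1e-10)$value
}

# Solve the Gompertz rate so the mean lifetime equals `target` at shape b.
gompertz_rate_for_mean <- function(target, b) {
  f <- function(lr) gompertz_mean(b, exp(lr)) - target
  root <- tryCatch(
    stats::uniroot(f, lower = -40, upper = 20, extendInt = "downX",
                   tol = 1e-12),
    error = function(e)
      stop_config(sprintf(
        "no Gompertz rate achieves mean %.3g at shape %.3g", target, b)))
  exp(root$root)
}

#' Simulate lifespan cohorts with target group means
#'
#' Lifespans are drawn from a Gompertz distribution (the standard
#' demographic ageing model), parameterised so each group's
#' distributional mean equals its target: the shape is
#' `b = 1 / (dispersion * mean)` and the baseline hazard rate is solved
#' numerically.  `dispersion` is a dimensionless spread parameter; the
#' default 0.12 gives a coefficient of variation of roughly 0.15,
#' typical of laboratory survival cohorts.  Sampling uses the closed
#' inverse CDF.  With probability `censor_frac` a record is
#' right-censored at a uniform point before its death time.
#'
#' @param group_means Named positive numeric vector of target mean
#'   lifespans (names become group labels; unnamed vectors get
#'   `group1..k`).
#' @param ns Cohort sizes, recycled against `group_means`.
#' @param dispersion Dimensionless spread parameter (> 0).
#' @param censor_frac Probability a record is censored (default 0).
#' @param seed Integer seed.
#' @return Data frame of lifespan records: `group`, `lifespan`,
#'   `observed`.
#' @export
simulate_lifespan_cohort <- function(group_means, ns, dispersion = 0.12,
                                     censor_frac = 0, seed = 1) {
  if (!is.numeric(group_means) || length(group_means) == 0L ||
      any(group_means <= 0))
    stop_config("`group_means` must be positive")
  check_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  check_number(censor_frac, "censor_frac", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (any(ns < 1)) stop_config("`ns` must be >= 1")
  ns <- rep_len(ns, length(group_means))
  if (is.null(names(group_means)))
    names(group_means) <- paste0("group", seq_along(group_means))
  set.seed(seed)
  out <- lapply(seq_along(group_means), function(i) {
    m <- group_means[[i]]
    b <- 1 / (dispersion * m)
    r <- gompertz_rate_for_mean(m, b)
    u <- stats::runif(ns[i])
    t_death <- log1p(-(b / r) * log(u)) / b
    cens <- stats::runif(ns[i]) < censor_frac
    lifespan <- ifelse(cens, stats::runif(ns[i], 0, t_death), t_death)
    # guard against a zero-length censored lifespan
    lifespan <- pmax(lifespan, .Machine$double.eps)
    data.frame(group = names(group_means)[i], lifespan = lifespan,
               observed = !cens, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a two-group replicate FPKM experiment with planted structure
#'
#' Baseline per-gene FPKM is log-normal with a heavy right tail, so the
#' abundance spectrum reaches the extremely-high class (total control
#' FPKM > 5000).  Planted differentially expressed genes multiply the
#' treatment mean by `2^log2fc`; replicate noise is multiplicative
#' log-normal.  Promoter states are Bernoulli with an active probability
#' that increases with baseline abundance and is boosted for planted
#' down-regulated genes, mirroring the observation that knockdown of a
#' transcription-supporting machine preferentially hits active, highly
#' expressed genes.  One annotation term is planted enriched in the
#' down-regulated set.
#'
#' Planted effects are drawn among genes with baseline mean FPKM >=
#' `min_planted_baseline` so that they are quantifiable at the default
#' thresholds; by default one planted down gene is forced into the
#' extremely-high abundance class (`ensure_extreme_down`), emulating the
#' very highly expressed (e.g. ribosomal) down-regulated genes.
#'
#' @param G Number of genes.
#' @param n_reps Replicates per group (>= 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline mean FPKM (defaults meanlog 3, sdlog 2).
#' @param planted List: `n_up`, `n_down`, `lfc` (absolute planted log2
#'   fold change), optionally `down_ids`/`up_ids` to pin specific genes,
#'   and `down_abundance_bias`/`up_abundance_bias` (default 0): planted
#'   genes are sampled with probability proportional to
#'   `baseline^bias`, so a positive down bias concentrates
#'   down-regulation among abundant genes (the selective-repression
#'   pattern the stratification analyses look for).
#' @param noise_sdlog Replicate-level multiplicative noise (sd of log).
#' @param promoter_model List: `intercept`, `abundance_slope`,
#'   `down_boost` for the logistic active-promoter probability.
#' @param term_model List: `n_terms`, `size_range`, `planted_size`,
#'   `planted_in_down` controlling the annotation and the planted
#'   enriched term (`term_planted`).
#' @param min_planted_baseline Minimum baseline mean FPKM of planted
#'   genes.
#' @param ensure_extreme_down Force one planted down gene above the
#'   extremely-high abundance edge (default TRUE).
#' @param seed Integer seed.
#' @return List: `experiment` (list `genes`, `fpkm_control`,
#'   `fpkm_treatment`), `promoter` (data frame `gene_id`, `state`),
#'   `terms` (data frame `gene_id`, `term_id`), `truth` (list with
#'   planted ids, true log2fc, baselines, promoter probabilities,
#'   planted term, seed).
#' @export
simulate_expression_experiment <- function(
    G = 2000, n_reps = 4,
    baseline_meanlog = 3, baseline_sdlog = 2,
    planted = list(n_up = 50, n_down = 50, lfc = 2),
    noise_sdlog = 0.2,
    promoter_model = list(intercept = -0.8, abundance_slope = 1,
                          down_boost = 2.2),
    term_model = list(n_terms = 40, size_range = c(10, 50),
                      planted_size = 30, planted_in_down = 20),
    min_planted_baseline = 5,
    ensure_extreme_down = TRUE,
    seed = 1) {
  check_number(G, "G", lower = 10)
  check_number(n_reps, "n_reps", lower = 2)
  check_number(noise_sdlog, "noise_sdlog", lower = 0)
  n_up <- planted$n_up %||% 0
  n_down <- planted$n_down %||% 0
  lfc <- planted$lfc %||% 2
  if (n_up + n_down > G)
    stop_config("more planted DEGs than genes")
  if ((n_up + n_down) > 0 && lfc == 0)
    stop_config("planted log2fc must be non-zero for DEGs")
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(G))
  baseline <- stats::rlnorm(G, baseline_meanlog, baseline_sdlog)
  names(baseline) <- genes

  down_ids <- planted$down_ids %||% character(0)
  up_ids <- planted$up_ids %||% character(0)
  if (!all(c(down_ids, up_ids) %in% genes))
    stop_config("pinned planted gene ids must exist in the gene universe")
  # pinned genes (e.g. cross-tissue shared DEGs) must be quantifiable
  # here too, so they get the same baseline floor as sampled ones
  pinned <- c(down_ids, up_ids)
  if (length(pinned))
    baseline[pinned] <- pmax(baseline[pinned], min_planted_baseline)
  eligible <- genes[baseline >= min_planted_baseline]
  pool <- setdiff(eligible, c(down_ids, up_ids))
  need_down <- n_down - length(down_ids)
  need_up <- n_up - length(up_ids)
  if (need_down < 0 || need_up < 0 || need_down + need_up > length(pool))
    stop_config("not enough eligible genes to plant the requested DEGs")
  down_bias <- planted$down_abundance_bias %||% 0
  up_bias <- planted$up_abundance_bias %||% 0
  down_ids <- c(down_ids,
                sample(pool, need_down, prob = baseline[pool]^down_bias))
  up_pool <- setdiff(pool, down_ids)
  up_ids <- c(up_ids,
              sample(up_pool, need_up, prob = baseline[up_pool]^up_bias))
  if (ensure_extreme_down && length(down_ids)) {
    # lift one planted down gene so its control total clears 5000
    target <- down_ids[1]
    floor_mean <- 8000 / n_reps
    baseline[target] <- max(baseline[target], floor_mean)
  }
  true_lfc <- stats::setNames(rep(0, G), genes)
  true_lfc[up_ids] <- lfc
  true_lfc[down_ids] <- -lfc

  mu_t <- baseline * 2^true_lfc
  noise <- function(mu) {
    # mean-preserving multiplicative log-normal replicate noise
    matrix(stats::rlnorm(G * n_reps, meanlog = log(mu) - noise_sdlog^2 / 2,
                         sdlog = noise_sdlog),
           nrow = G)
  }
  fpkm_control <- noise(baseline)
  fpkm_treatment <- noise(mu_t)
  dimnames(fpkm_control) <- list(genes, paste0("ctrl", seq_len(n_reps)))
  dimnames(fpkm_treatment) <- list(genes, paste0("treat", seq_len(n_reps)))

  z <- log10(baseline + 1)
  lin <- promoter_model$intercept +
    promoter_model$abundance_slope * (z - mean(z)) / stats::sd(z) +
    promoter_model$down_boost * (genes %in% down_ids)
  p_active <- stats::plogis(lin)
  state <- ifelse(stats::runif(G) < p_active, "active", "inactive")
  promoter <- data.frame(gene_id = genes, state = state,
                         stringsAsFactors = FALSE)

  n_terms <- term_model$n_terms %||% 40
  size_range <- term_model$size_range %||% c(10, 50)
  planted_size <- min(term_model$planted_size %||% 30, G)
  planted_in_down <- min(term_model$planted_in_down %||% 20,
                         length(down_ids), planted_size)
  term_rows <- lapply(seq_len(n_terms), function(k) {
    sz <- sample(seq(size_range[1], size_range[2]), 1)
    data.frame(gene_id = sample(genes, min(sz, G)),
               term_id = sprintf("TERM%03d", k), stringsAsFactors = FALSE)
  })
  planted_term_genes <- c(
    sample(down_ids, planted_in_down),
    sample(setdiff(genes, down_ids), planted_size - planted_in_down))
  term_rows[[n_terms + 1L]] <- data.frame(
    gene_id = planted_term_genes, term_id = "TERM_PLANTED",
    stringsAsFactors = FALSE)
  terms <- do.call(rbind, term_rows)

  list(
    experiment = list(genes = genes, fpkm_control = fpkm_control,
                      fpkm_treatment = fpkm_treatment),
    promoter = promoter,
    terms = terms,
    truth = list(up_ids = sort(up_ids), down_ids = sort(down_ids),
                 true_log2fc = true_lfc, baseline = baseline,
                 p_active = stats::setNames(p_active, genes),
                 planted_term = "TERM_PLANTED",
                 planted_term_genes = sort(planted_term_genes),
                 seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
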