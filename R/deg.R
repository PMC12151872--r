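# Differential-expression thresholding and the stratification analyses:
# promoter-state enrichment, abundance-bin up/down ratios, cross-tissue
# shared DEGs, and Fisher-exact set enrichment.
#
# The DE engine of the original RNA-seq processing is intentionally
# pluggable: precomputed per-gene statistics (gene_id, log2fc, p_value,
# optionally q_value) are preferred; a Welch t test on log2(FPKM + 1) is
# the documented built-in fallback.

# Vectorised Welch two-sample t on log2(FPKM+1); rows are genes.
welch_log2_rows <- function(ctrl, treat) {
  zc <- log2(ctrl + 1)
  zt <- log2(treat + 1)
  n1 <- ncol(zc); n2 <- ncol(zt)
  m1 <- rowMeans(zc); m2 <- rowMeans(zt)
  v1 <- rowSums((zc - m1)^2) / (n1 - 1)
  v2 <- rowSums((zt - m2)^2) / (n2 - 1)
  lfc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  t_stat <- lfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  # zero-variance edges: identical groups -> p 1; separated constants -> p 0
  flat <- se2 == 0
  if (any(flat)) {
    t_stat[flat] <- ifelse(lfc[flat] == 0, 0, sign(lfc[flat]) * Inf)
    p[flat] <- ifelse(lfc[flat] == 0, 1, 0)
    df[flat] <- NA_real_
  }
  data.frame(log2fc = lfc, t_stat = t_stat, df = df, p_value = p)
}

#' Welch t test for one gene on the log2(FPKM + 1) scale
#'
#' The built-in differential-expression fallback when no precomputed
#' statistics are supplied: a Welch (unequal-variance) two-sample t test
#' comparing `log2(fpkm + 1)` between groups.  The reported fold change
#' is `mean(log2(treatment + 1)) - mean(log2(control + 1))`.
#'
#' @param fpkm_control,fpkm_treatment Non-negative FPKM replicate
#'   vectors, at least 2 replicates each.
#' @return List: `log2fc`, `t_stat`, `df`, `p_value`.
#' @export
two_group_gene_test <- function(fpkm_control, fpkm_treatment) {
  if (length(fpkm_control) < 2L || length(fpkm_treatment) < 2L)
    stop_insufficient(
      "need >= 2 replicates per group; supply precomputed p-values otherwise")
  if (anyNA(fpkm_control) || anyNA(fpkm_treatment) ||
      any(fpkm_control < 0) || any(fpkm_treatment < 0))
    stop_input("FPKM values must be non-negative and non-missing")
  res <- welch_log2_rows(matrix(fpkm_control, nrow = 1),
                         matrix(fpkm_treatment, nrow = 1))
  as.list(res[1, ])
}

#' Per-gene differential-expression statistics for an experiment
#'
#' Applies [two_group_gene_test()] to every gene of a two-group FPKM
#' experiment and appends Benjamini-Hochberg q-values.
#'
#' @param experiment List with `genes` (character), `fpkm_control` and
#'   `fpkm_treatment` (gene x replicate matrices), as produced by
#'   [simulate_expression_experiment()] or [read_expression()].
#' @return Data frame: `gene_id`, `log2fc`, `p_value`, `q_value`.
#' @export
compute_deg_stats <- function(experiment) {
  req <- c("genes", "fpkm_control", "fpkm_treatment")
  if (!is.list(experiment) || !all(req %in% names(experiment)))
    stop_input("`experiment` needs genes, fpkm_control, fpkm_treatment")
  ctrl <- experiment$fpkm_control
  treat <- experiment$fpkm_treatment
  if (ncol(ctrl) < 2L || ncol(treat) < 2L)
    stop_insufficient(
      "need >= 2 replicates per group; supply precomputed p-values otherwise")
  res <- welch_log2_rows(ctrl, treat)
  data.frame(gene_id = experiment$genes, log2fc = res$log2fc,
             p_value = res$p_value, q_value = bh_adjust(res$p_value),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate q-values with monotonicity enforcement;
#' elementwise `q >= p`, order-preserving, capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes at fold-change and FDR thresholds
#'
#' A gene is an up-regulated DEG when `log2fc > lfc_cut` and
#' `q_value < alpha`; down-regulated when `log2fc < -lfc_cut` and
#' `q_value < alpha` (defaults: |log2FC| > 1, adjusted p < 0.05).  If
#' `q_value` is absent it is computed from `p_value` by [bh_adjust()].
#'
#' @param stats_df Data frame with `gene_id`, `log2fc` and `q_value`
#'   (or `p_value`).
#' @param lfc_cut Absolute log2 fold-change threshold, default 1.
#' @param alpha Adjusted-p threshold, default 0.05.
#' @param tissue Optional label carried through.
#' @return List of class `"deg_set"`: `tissue`, `up`, `down` (sorted
#'   gene-id character vectors, always disjoint), `thresholds`.
#' @export
call_degs <- function(stats_df, lfc_cut = 1, alpha = 0.05, tissue = NA_character_) {
  if (!is.data.frame(stats_df) ||
      !all(c("gene_id", "log2fc") %in% names(stats_df)))
    stop_input("`stats_df` needs columns gene_id and log2fc")
  check_number(lfc_cut, "lfc_cut", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (anyDuplicated(stats_df$gene_id))
    stop_input("duplicate gene_id in `stats_df`")
  if (nrow(stats_df) == 0L) {
    q <- numeric(0)
  } else if ("q_value" %in% names(stats_df)) {
    q <- stats_df$q_value
  } else if ("p_value" %in% names(stats_df)) {
    q <- bh_adjust(stats_df$p_value)
  } else {
    stop_input("`stats_df` needs a q_value or p_value column")
  }
  up <- stats_df$gene_id[q < alpha & stats_df$log2fc > lfc_cut]
  down <- stats_df$gene_id[q < alpha & stats_df$log2fc < -lfc_cut]
  structure(
    list(tissue = tissue, up = sort(up), down = sort(down),
         thresholds = c(lfc_cut = lfc_cut, alpha = alpha)),
    class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("DEG set%s: %d up, %d down (|log2FC| > %g, q < %g)\n",
              if (is.na(x$tissue)) "" else paste0(" [", x$tissue, "]"),
              length(x$up), length(x$down),
              x$thresholds[["lfc_cut"]], x$thresholds[["alpha"]]))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form \eqn{N(ad - bc)^2 / (r_1 r_2 c_1 c_2)} with no continuity
#' correction, 1 df; invariant under transposition.
#'
#' @param a,b,c,d Non-negative cell counts (row-wise: a,b / c,d).
#' @return List: `statistic`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop_input("cell counts must be non-negative integers")
  # double arithmetic: the margin product overflows 32-bit integers
  cnt <- as.numeric(cnt)
  a <- cnt[1]; b <- cnt[2]; c <- cnt[3]; d <- cnt[4]
  n <- sum(cnt)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0))
    stop_degenerate("chi-square is undefined when a table margin is zero")
  stat <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Promoter transcriptional-state composition of up vs. down DEGs
#'
#' Computes the proportion of active promoters among up- and among
#' down-regulated DEGs and tests direction x state association with a
#' 2x2 Pearson chi-square.  Genes without an annotation are counted and
#' reported separately, not silently dropped.  When a table margin is
#' zero the proportions are still returned with `chi_square`/`p_value`
#' set to `NA` (with a warning).
#'
#' @param degset A `"deg_set"` from [call_degs()].
#' @param annotation Data frame `gene_id`, `state` with state in
#'   `{"active", "inactive"}` (one row per gene).
#' @return List: `prop_active_up`, `prop_active_down`, `counts` (2x2
#'   matrix direction x state), `n_unannotated`, `chi_square`, `p_value`.
#' @export
promoter_state_enrichment <- function(degset, annotation) {
  if (!inherits(degset, "deg_set"))
    stop_input("`degset` must come from call_degs()")
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "state") %in% names(annotation)))
    stop_input("`annotation` needs columns gene_id and state")
  if (anyDuplicated(annotation$gene_id))
    stop_input("one promoter state per gene: duplicate gene_id in annotation")
  if (!all(annotation$state %in% c("active", "inactive")))
    stop_input("promoter state must be 'active' or 'inactive'")
  st <- stats::setNames(annotation$state, annotation$gene_id)
  tab <- function(genes) {
    s <- st[genes]
    c(active = sum(s == "active", na.rm = TRUE),
      inactive = sum(s == "inactive", na.rm = TRUE),
      missing = sum(is.na(s)))
  }
  up <- tab(degset$up)
  down <- tab(degset$down)
  counts <- rbind(up = up[c("active", "inactive")],
                  down = down[c("active", "inactive")])
  prop <- function(x) {
    tot <- x[["active"]] + x[["inactive"]]
    if (tot == 0) NA_real_ else x[["active"]] / tot
  }
  chi <- tryCatch(
    chi_square_2x2(counts["up", "active"], counts["up", "inactive"],
                   counts["down", "active"], counts["down", "inactive"]),
    longescreen_degenerate_error = function(e) {
      warning("chi-square undefined (zero margin); proportions returned",
              call. = FALSE)
      list(statistic = NA_real_, p_value = NA_real_)
    })
  list(prop_active_up = prop(up), prop_active_down = prop(down),
       counts = counts,
       n_unannotated = unname(up[["missing"]] + down[["missing"]]),
       chi_square = chi$statistic, p_value = chi$p_value)
}

#' Bin genes by total control-group expression abundance
#'
#' Genes are grouped into low / middle / high / extremely_high abundance
#' classes by their total control FPKM (sum across control replicates).
#' The extremely-high class is `total > extreme_fpkm` (strictly; default
#' 5000).  The two inner edges default to the 25th and 75th percentile
#' of the sub-threshold totals and can be overridden.
#'
#' @param totals Named numeric vector: total control FPKM per gene.
#' @param inner_edges Length-2 increasing numeric vector splitting
#'   low/middle/high, or `NULL` for the percentile default.
#' @param extreme_fpkm Strict lower bound of the extremely-high class.
#' @return Named factor (levels `low`, `middle`, `high`,
#'   `extremely_high`) with the edges in `attr(, "edges")`.
#' @export
assign_abundance_bins <- function(totals, inner_edges = NULL,
                                  extreme_fpkm = 5000) {
  if (!is.numeric(totals) || is.null(names(totals)))
    stop_input("`totals` must be a named numeric vector")
  if (anyNA(totals) || any(totals < 0))
    stop_input("total FPKM must be non-negative and non-missing")
  check_number(extreme_fpkm, "extreme_fpkm", lower = 0, strict_lower = TRUE)
  if (is.null(inner_edges)) {
    sub <- totals[totals <= extreme_fpkm]
    inner_edges <- unname(stats::quantile(sub, c(0.25, 0.75), names = FALSE))
  }
  edges <- c(inner_edges, extreme_fpkm)
  if (length(edges) != 3L || is.unsorted(edges, strictly = TRUE))
    stop_config("bin edges must be strictly increasing below the extreme edge")
  lv <- c("low", "middle", "high", "extremely_high")
  idx <- 1L + (totals > edges[1]) + (totals > edges[2]) + (totals > edges[3])
  out <- factor(lv[idx], levels = lv)
  names(out) <- names(totals)
  attr(out, "edges") <- edges
  out
}

#' Up/down DEG ratio within each abundance bin
#'
#' For each abundance bin, counts up- and down-regulated DEGs and their
#' ratio `n_up / n_down` (`NA` when the bin has no down-regulated DEGs).
#' A ratio below 1 means the bin is dominated by down-regulation.
#'
#' @param degset A `"deg_set"`.
#' @param bins Named factor from [assign_abundance_bins()]; must cover
#'   every DEG.
#' @return Data frame: `bin`, `n_up`, `n_down`, `ratio`.
#' @export
updown_ratio_by_bin <- function(degset, bins) {
  if (!inherits(degset, "deg_set"))
    stop_input("`degset` must come from call_degs()")
  degs <- c(degset$up, degset$down)
  if (!all(degs %in% names(bins)))
    stop_input("`bins` must cover every DEG in the set")
  lv <- levels(bins)
  n_up <- table(factor(bins[degset$up], levels = lv))
  n_down <- table(factor(bins[degset$down], levels = lv))
  data.frame(
    bin = lv,
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    ratio = ifelse(as.integer(n_down) == 0, NA_real_,
                   as.integer(n_up) / as.integer(n_down)),
    stringsAsFactors = FALSE)
}

#' Cross-tissue shared DEGs (Venn table)
#'
#' Exact set intersections across tissues, separately for up- and
#' down-regulated DEGs.  For every non-empty tissue subset the table
#' reports both the number of genes differential in at least those
#' tissues (`n_intersection`) and the exclusive Venn-region count
#' (`n_exclusive`); exclusive regions partition the union.
#'
#' @param degsets List of `"deg_set"` objects with distinct tissue
#'   labels (at least 2).
#' @return List with data frames `up` and `down` (columns `tissues`,
#'   `n_tissues`, `n_intersection`, `n_exclusive`) and character vectors
#'   `shared_all_up`, `shared_all_down` of genes shared by every tissue.
#' @export
shared_degs <- function(degsets) {
  if (!is.list(degsets) || length(degsets) < 2L ||
      !all(vapply(degsets, inherits, TRUE, "deg_set")))
    stop_input("`degsets` must be a list of >= 2 deg_set objects")
  tissues <- vapply(degsets, function(d) as.character(d$tissue), "")
  if (anyNA(tissues) || anyDuplicated(tissues))
    stop_input("tissue labels must be present and unique")
  venn_one <- function(sets) {
    union_genes <- sort(unique(unlist(sets)))
    member <- vapply(sets, function(s) union_genes %in% s,
                     logical(length(union_genes)))
    if (length(union_genes) == 1L) member <- matrix(member, nrow = 1)
    k <- length(sets)
    rows <- list()
    for (mask in seq_len(2^k - 1L)) {
      in_sub <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      inter <- if (length(union_genes))
        rowSums(member[, in_sub, drop = FALSE]) == sum(in_sub) else logical(0)
      excl <- inter & (if (length(union_genes))
        rowSums(member[, !in_sub, drop = FALSE]) == 0 else logical(0))
      rows[[mask]] <- data.frame(
        tissues = paste(tissues[in_sub], collapse = "+"),
        n_tissues = sum(in_sub),
        n_intersection = sum(inter),
        n_exclusive = sum(excl),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out[order(out$n_tissues, out$tissues), , drop = FALSE]
  }
  ups <- lapply(degsets, `[[`, "up")
  downs <- lapply(degsets, `[[`, "down")
  list(up = venn_one(ups), down = venn_one(downs),
       shared_all_up = sort(Reduce(intersect, ups)),
       shared_all_down = sort(Reduce(intersect, downs)))
}

#' Fisher-exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher exact test per term: the p-value is the
#' upper hypergeometric tail of the query/term overlap given the
#' background universe.  Benjamini-Hochberg q-values are computed across
#' all tested terms and results are sorted by p-value.
#'
#' @param query Character vector of genes of interest (must lie within
#'   `background`).
#' @param annotation Data frame `gene_id`, `term_id` (multi-row per
#'   gene); genes outside the background are ignored.
#' @param background Character vector: the gene universe.
#' @return Data frame: `term_id`, `overlap`, `term_size`, `set_size`,
#'   `background_size`, `odds_ratio`, `p_value`, `q_value`.
#' @export
fisher_enrichment <- function(query, annotation, background) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    stop_input("every query gene must belong to the background universe")
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "term_id") %in% names(annotation)))
    stop_input("`annotation` needs columns gene_id and term_id")
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  terms <- split(ann$gene_id, ann$term_id)
  if (length(terms) == 0L)
    return(data.frame(term_id = character(), overlap = integer(),
                      term_size = integer(), set_size = integer(),
                      background_size = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  n_bg <- length(background)
  n_q <- length(query)
  res <- lapply(names(terms), function(tm) {
    tg <- terms[[tm]]
    k <- length(tg)
    a <- sum(query %in% tg)
    b <- n_q - a
    cc <- k - a
    d <- n_bg - k - b
    or <- if (b == 0 || cc == 0) {
      if (a == 0) 0 else Inf
    } else a * d / (b * cc)
    p <- stats::phyper(a - 1, k, n_bg - k, n_q, lower.tail = FALSE)
    data.frame(term_id = tm, overlap = a, term_size = k, set_size = n_q,
               background_size = n_bg, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
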