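#' Reliability weight for a lifespan measurement
#'
#' Replicative-lifespan estimates from micro-dissection assays are more
#' reliable when more mother cells were followed.  Each strain's lifespan
#' measurement receives the weight
#' \deqn{w = n / (n + \mathrm{offset})}
#' where \eqn{n} is the number of cells dissected.  With the default
#' offset of 50 a 50-cell assay gets weight 0.5 and the weight approaches
#' 1 as \eqn{n} grows; a strain with no cells measured contributes
#' nothing.
#'
#' @param n_cells Non-negative integer vector: cells dissected per strain.
#' @param offset Positive constant in the denominator (default 50).
#' @return Numeric vector of weights in `[0, 1)`.
#' @examples
#' lifespan_weight(c(0, 50, 150))  # 0.0 0.5 0.75
#' @export
lifespan_weight <- function(n_cells, offset = 50) {
  check_number(offset, "offset", lower = 0, strict_lower = TRUE)
  if (!is.numeric(n_cells) || anyNA(n_cells) || any(!is.finite(n_cells)))
    stop_input("`n_cells` must be finite and non-missing")
  if (any(n_cells < 0))
    stop_input("`n_cells` must be non-negative")
  if (any(n_cells != floor(n_cells)))
    stop_input("`n_cells` must be whole numbers")
  n_cells / (n_cells + offset)
}

#' Weighted least-squares line fit with t-based inference on the slope
#'
#' Minimises the weighted cost
#' \deqn{\sum_i w_i (y_i - \beta_0 - \beta_1 x_i)^2}
#' by the closed-form weighted normal equations (x is centred at its
#' weighted mean for numerical stability).  Inference uses
#' precision-weight conventions: \eqn{\hat\sigma^2 = RSS_w / (n - 2)},
#' \eqn{\mathrm{Var}(\hat\beta_1) = \hat\sigma^2 / \sum_i w_i (x_i -
#' \bar x_w)^2}, and a two-sided t test with \eqn{n - 2} degrees of
#' freedom.  The fit is invariant to rescaling all weights by a positive
#' constant.
#'
#' Degenerate edges are resolved deterministically: a perfect fit with
#' zero slope (constant y) yields `t_stat = 0`, `p_value = 1`; a perfect
#' fit with non-zero slope yields an infinite t and `p_value = 0`.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points).
#' @param w Positive weights, same length.
#' @return List of class `"wls_fit"`: `intercept`, `slope`, `slope_se`,
#'   `t_stat`, `p_value`, `df`, `weighted_rss`, `n`.
#' @examples
#' fit_weighted_line(c(0, 1, 2), c(1, 3, 5), c(1, 1, 1))$slope  # 2
#' @export
fit_weighted_line <- function(x, y, w = rep(1, length(x))) {
  if (length(x) != length(y) || length(x) != length(w))
    stop_input("`x`, `y` and `w` must have equal length")
  if (length(x) < 3L)
    stop_insufficient("at least 3 points are required to fit a weighted line")
  if (anyNA(x) || anyNA(y) || anyNA(w) ||
      any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(w)))
    stop_input("`x`, `y` and `w` must be finite and non-missing")
  if (any(w <= 0))
    stop_input("all weights must be strictly positive")

  sw <- sum(w)
  xw <- sum(w * x) / sw
  yw <- sum(w * y) / sw
  xc <- x - xw
  sxx <- sum(w * xc * xc)
  if (sxx == 0)
    stop_degenerate("all `x` values are identical: slope is not identifiable")
  slope <- sum(w * xc * (y - yw)) / sxx
  intercept <- yw - slope * xw

  res <- y - (intercept + slope * x)
  rss <- sum(w * res * res)
  df <- length(x) - 2L
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  if (se == 0) {
    t_stat <- if (slope == 0) 0 else sign(slope) * Inf
    p <- if (slope == 0) 1 else 0
  } else {
    t_stat <- slope / se
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  }
  structure(
    list(intercept = intercept, slope = slope, slope_se = se,
         t_stat = t_stat, p_value = p, df = df, weighted_rss = rss,
         n = length(x)),
    class = "wls_fit")
}

#' Screen every gene for association between expression change and
#' lifespan change
#'
#' For each gene in the expression compendium, regresses per-strain
#' lifespan change (percent, relative to wild type) on that gene's
#' expression log2 fold change across knockout strains, weighting each
#' strain by [lifespan_weight()] of its dissected cell count.  Only
#' strains present in both the compendium and the phenotype table are
#' used; per gene, strains with a missing expression value are dropped
#' (complete-case).  Genes with fewer than `min_strains` usable strains
#' are reported as skipped.  Benjamini-Hochberg q-values are added across
#' all tested genes; ranking is by raw p-value (see [rank_by_p()]).
#'
#' @param compendium Numeric matrix, strains in rows, genes in columns
#'   (dimnames required): expression log2 fold change vs. wild type.
#'   `NA` marks missing values.
#' @param phenotypes Data frame with columns `strain_id`,
#'   `lifespan_change` (percent vs. wild type) and `n_cells`.
#' @param offset Weight-formula constant, default 50.
#' @param min_strains Minimum usable strains per gene (default 10).
#' @return List of class `"screen_result"` with elements `results` (data
#'   frame: `rank`, `gene_id`, `slope`, `intercept`, `slope_se`,
#'   `t_stat`, `p_value`, `q_value`, `n_strains_used`), `skipped` (data
#'   frame: `gene_id`, `reason`), `n_strains`, `offset`, `min_strains`.
#' @export
screen_genes <- function(compendium, phenotypes, offset = 50,
                         min_strains = 10) {
  if (!is.matrix(compendium) || !is.numeric(compendium))
    stop_input("`compendium` must be a numeric matrix (strains x genes)")
  if (is.null(rownames(compendium)) || is.null(colnames(compendium)))
    stop_input("`compendium` must carry strain rownames and gene colnames")
  if (anyDuplicated(rownames(compendium)) || anyDuplicated(colnames(compendium)))
    stop_input("strain and gene identifiers must be unique")
  req <- c("strain_id", "lifespan_change", "n_cells")
  if (!is.data.frame(phenotypes) || !all(req %in% names(phenotypes)))
    stop_input("`phenotypes` needs columns strain_id, lifespan_change, n_cells")
  if (anyDuplicated(phenotypes$strain_id))
    stop_input("duplicate strain_id in `phenotypes`")
  check_number(min_strains, "min_strains", lower = 3)

  common <- intersect(rownames(compendium), phenotypes$strain_id)
  if (length(common) == 0L)
    stop_join("no strains are shared between the compendium and phenotypes")
  ph <- phenotypes[match(common, phenotypes$strain_id), , drop = FALSE]
  if (any(!is.finite(ph$lifespan_change)))
    stop_input("`lifespan_change` must be finite for all joined strains")
  expr <- compendium[common, , drop = FALSE]
  w_all <- lifespan_weight(ph$n_cells, offset = offset)
  y_all <- ph$lifespan_change

  genes <- colnames(expr)
  out <- vector("list", length(genes))
  skipped <- list()
  for (j in seq_along(genes)) {
    xj <- expr[, j]
    ok <- is.finite(xj) & w_all > 0
    n_used <- sum(ok)
    if (n_used < min_strains) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = genes[j],
                   reason = sprintf("only %d usable strains (min %d)",
                                    n_used, as.integer(min_strains)),
                   stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(
      fit_weighted_line(xj[ok], y_all[ok], w_all[ok]),
      longescreen_degenerate_error = function(e) NULL)
    if (is.null(fit)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_id = genes[j], reason = "degenerate design (constant x)",
                   stringsAsFactors = FALSE)
      next
    }
    out[[j]] <- data.frame(
      gene_id = genes[j], slope = fit$slope, intercept = fit$intercept,
      slope_se = fit$slope_se, t_stat = fit$t_stat, p_value = fit$p_value,
      n_strains_used = n_used, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(gene_id = character(), slope = numeric(),
                      intercept = numeric(), slope_se = numeric(),
                      t_stat = numeric(), p_value = numeric(),
                      n_strains_used = integer(), stringsAsFactors = FALSE)
  res$q_value <- bh_adjust(res$p_value)
  res <- rank_by_p(res)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(
    list(results = res, skipped = skipped, n_strains = length(common),
         offset = offset, min_strains = min_strains),
    class = "screen_result")
}

#' Rank screen results by p-value
#'
#' Ascending raw p-value; ties broken by larger absolute slope, then
#' lexicographic gene id, so the ordering is deterministic.  Ranks are
#' `1..K` without gaps.
#'
#' @param results Data frame with at least `gene_id`, `p_value`, `slope`.
#' @return The same data frame, sorted, with a `rank` column first.
#' @export
rank_by_p <- function(results) {
  if (!is.data.frame(results) ||
      !all(c("gene_id", "p_value", "slope") %in% names(results)))
    stop_input("`results` needs columns gene_id, p_value, slope")
  if (anyNA(results$p_value))
    stop_input("`p_value` must be populated before ranking")
  ord <- order(results$p_value, -abs(results$slope), results$gene_id)
  res <- results[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  front <- c("rank", "gene_id")
  res[, c(front, setdiff(names(res), front)), drop = FALSE]
}

#' @export
print.screen_result <- function(x, n = 10, ...) {
  cat(sprintf(
    "Longevity screen: %d genes tested across %d strains (offset %g)\n",
    nrow(x$results), x$n_strains, x$offset))
  if (nrow(x$skipped))
    cat(sprintf("  %d genes skipped (fewer than %d usable strains)\n",
                nrow(x$skipped), as.integer(x$min_strains)))
  print(utils::head(x$results, n), ...)
  invisible(x)
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted line fit (n = %d): y = %.4g + %.4g x; se(slope) = %.4g, t = %.3g, p = %.3g\n",
    x$n, x$intercept, x$slope, x$slope_se, x$t_stat, x$p_value))
  invisible(x)
}
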