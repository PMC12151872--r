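test_that("Welch test on log2(FPKM+1) handles edge and generic cases", {
  same <- two_group_gene_test(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_value, 1)

  set.seed(1)
  jit <- abs(rnorm(8, 0, 1e-8))
  shift <- two_group_gene_test(c(10, 10, 10, 10) + jit[1:4],
                               c(40, 40, 40, 40) + jit[5:8])
  expect_equal(shift$log2fc, log2(41 / 11), tolerance = 1e-6)

  for (i in 1:20) {
    a <- rlnorm(4, 3, 1); b <- rlnorm(4, 3.5, 1)
    got <- two_group_gene_test(a, b)
    ref <- t.test(log2(b + 1), log2(a + 1))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
  }
  expect_error(two_group_gene_test(c(1, 2), 3),
               class = "longescreen_insufficient_data_error")
})

test_that("BH adjustment matches the direct step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(4)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_equal(q, bh_oracle(p))
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  expect_error(bh_adjust(c(0.5, 1.2)), class = "longescreen_input_error")
})

test_that("DEG calling applies strict fold-change and FDR thresholds", {
  df <- data.frame(gene_id = c("up1", "small", "notsig", "down1"),
                   log2fc = c(1.5, 0.5, -2, -2),
                   q_value = c(0.01, 0.001, 0.2, 0.01))
  ds <- call_degs(df)
  expect_equal(ds$up, "up1")
  expect_equal(ds$down, "down1")
  expect_length(intersect(ds$up, ds$down), 0)

  empty <- call_degs(df[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)

  # order invariance
  shuf <- call_degs(df[c(3, 1, 4, 2), ])
  expect_equal(shuf$up, ds$up)
  expect_equal(shuf$down, ds$down)

  # q computed from p when absent
  dp <- data.frame(gene_id = c("a", "b"), log2fc = c(2, 2),
                   p_value = c(0.001, 0.9))
  expect_equal(call_degs(dp)$up, "a")
})

test_that("planted DEGs are recovered with controlled FDR", {
  sim <- simulate_expression_experiment(G = 1500, seed = 17)
  stats_df <- compute_deg_stats(sim$experiment)
  ds <- call_degs(stats_df)
  truth_deg <- c(sim$truth$up_ids, sim$truth$down_ids)
  called <- c(ds$up, ds$down)
  recall <- mean(truth_deg %in% called)
  fdr <- if (length(called)) mean(!called %in% truth_deg) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
  # direction is recovered, not just membership
  expect_true(all(ds$down %in% sim$truth$down_ids |
                    !ds$down %in% truth_deg))
})

test_that("2x2 chi-square equals the closed form and transposes", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$p_value, 1)
  expect_equal(chi_square_2x2(20, 10, 10, 20)$statistic, 20 / 3,
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:25) {
    tb <- rmultinom(1, sample(40:400, 1), runif(4, 0.05, 1))
    if (any(c(tb[1] + tb[2], tb[3] + tb[4],
              tb[1] + tb[3], tb[2] + tb[4]) == 0)) next
    got <- chi_square_2x2(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got$statistic, chisq_2x2_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
    tr <- chi_square_2x2(tb[1], tb[3], tb[2], tb[4])
    expect_equal(got$statistic, tr$statistic, tolerance = 1e-12)
    ref <- suppressWarnings(
      chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4),
               class = "longescreen_degenerate_error")
})

test_that("promoter-state composition and association are recovered", {
  mk_ann <- function(up_a, up_i, down_a, down_i) {
    data.frame(
      gene_id = c(sprintf("u%03d", seq_len(up_a + up_i)),
                  sprintf("d%03d", seq_len(down_a + down_i))),
      state = c(rep(c("active", "inactive"), c(up_a, up_i)),
                rep(c("active", "inactive"), c(down_a, down_i))))
  }
  mk_set <- function(n_up, n_down) {
    structure(list(tissue = "t", up = sprintf("u%03d", seq_len(n_up)),
                   down = sprintf("d%03d", seq_len(n_down)),
                   thresholds = c(lfc_cut = 1, alpha = 0.05)),
              class = "deg_set")
  }
  even <- promoter_state_enrichment(mk_set(20, 20), mk_ann(10, 10, 10, 10))
  expect_equal(even$prop_active_up, even$prop_active_down)
  expect_equal(even$chi_square, 0)

  contingency <- promoter_state_enrichment(mk_set(17, 17),
                                           mk_ann(12, 5, 3, 14))
  expect_equal(contingency$chi_square, chisq_2x2_oracle(12, 5, 3, 14),
               tolerance = 1e-12)

  # planted active fractions: 0.3 among up, 0.8 among down, 150 each
  set.seed(33)
  n <- 150
  up_a <- rbinom(1, n, 0.3); down_a <- rbinom(1, n, 0.8)
  res <- promoter_state_enrichment(
    mk_set(n, n), mk_ann(up_a, n - up_a, down_a, n - down_a))
  expect_lt(abs(res$prop_active_up - 0.3), 1.96 * sqrt(0.3 * 0.7 / n))
  expect_lt(abs(res$prop_active_down - 0.8), 1.96 * sqrt(0.8 * 0.2 / n))
  expect_lt(res$p_value, 0.001)

  # zero margin: proportions survive, statistic is NA
  expect_warning(
    zm <- promoter_state_enrichment(mk_set(5, 5), mk_ann(5, 0, 5, 0)))
  expect_true(is.na(zm$chi_square))
  expect_equal(zm$prop_active_up, 1)

  # unannotated DEGs are counted, not dropped
  part <- promoter_state_enrichment(mk_set(25, 20), mk_ann(10, 10, 10, 10))
  expect_equal(part$n_unannotated, 5)
})

test_that("abundance bins honour the strict 5000 edge", {
  totals <- c(a = 6000, b = 5000, c = 0, d = 10, e = 100, f = 800,
              g = 2000, h = 4000)
  bins <- assign_abundance_bins(totals, inner_edges = c(50, 1000))
  expect_equal(as.character(bins[["a"]]), "extremely_high")
  expect_equal(as.character(bins[["b"]]), "high")  # exactly 5000 is not extreme
  expect_equal(as.character(bins[["c"]]), "low")
  expect_equal(as.character(bins[["e"]]), "middle")

  zero <- assign_abundance_bins(setNames(rep(0, 5), letters[1:5]),
                                inner_edges = c(10, 100))
  expect_true(all(zero == "low"))

  expect_error(assign_abundance_bins(totals, inner_edges = c(1000, 50)),
               class = "longescreen_config_error")
  # default inner edges: quartiles of the sub-threshold totals
  defb <- assign_abundance_bins(totals)
  ed <- attr(defb, "edges")
  sub <- totals[totals <= 5000]
  expect_equal(ed[1:2], unname(quantile(sub, c(0.25, 0.75), names = FALSE)))
})

test_that("up/down ratios per bin report undefined cases", {
  ds <- structure(list(tissue = "t",
                       up = c("a", "b", "c", "d"),
                       down = c("e", "f", "g", "h", "i", "j", "k", "l"),
                       thresholds = c(lfc_cut = 1, alpha = 0.05)),
                  class = "deg_set")
  bins <- factor(setNames(rep(c("low", "high"), c(12, 0)), letters[1:12]),
                 levels = c("low", "middle", "high", "extremely_high"))
  rt <- updown_ratio_by_bin(ds, bins)
  expect_equal(rt$ratio[rt$bin == "low"], 0.5)
  expect_equal(rt$n_up[rt$bin == "middle"], 0)
  expect_true(is.na(rt$ratio[rt$bin == "middle"]))
})

test_that("a planted abundance-dependent down-bias shows up as decreasing ratios", {
  sim <- simulate_expression_experiment(
    G = 2500, seed = 11,
    planted = list(n_up = 80, n_down = 80, lfc = 2,
                   down_abundance_bias = 1, up_abundance_bias = -1))
  ds <- call_degs(compute_deg_stats(sim$experiment))
  bins <- assign_abundance_bins(rowSums(sim$experiment$fpkm_control))
  rt <- updown_ratio_by_bin(ds, bins)
  r <- setNames(rt$ratio, rt$bin)
  expect_gt(r[["middle"]], r[["high"]])
  expect_gt(r[["high"]], r[["extremely_high"]])
})

test_that("shared DEG Venn counts match brute-force enumeration", {
  mk <- function(tissue, up, down)
    structure(list(tissue = tissue, up = up, down = down,
                   thresholds = c(lfc_cut = 1, alpha = 0.05)),
              class = "deg_set")
  s <- shared_degs(list(mk("t1", character(0), c("a", "b", "c")),
                        mk("t2", character(0), c("b", "c", "d")),
                        mk("t3", character(0), c("c", "e"))))
  all3 <- s$down[s$down$tissues == "t1+t2+t3", ]
  expect_equal(all3$n_intersection, 1)
  expect_equal(s$shared_all_down, "c")
  expect_equal(sum(s$down$n_exclusive), 5)  # union is {a,b,c,d,e}

  ident <- shared_degs(list(mk("x", c("p", "q"), "z"),
                            mk("y", c("p", "q"), "z")))
  expect_equal(ident$up$n_intersection[ident$up$tissues == "x+y"], 2)
  expect_equal(ident$shared_all_down, "z")

  set.seed(14)
  pool <- sprintf("g%02d", 1:30)
  sets <- lapply(1:3, function(i) sample(pool, 12))
  s2 <- shared_degs(list(mk("a", sets[[1]], character(0)),
                         mk("b", sets[[2]], character(0)),
                         mk("c", sets[[3]], character(0))))
  # brute-force every region by explicit membership
  for (r in seq_len(nrow(s2$up))) {
    tis <- strsplit(s2$up$tissues[r], "+", fixed = TRUE)[[1]]
    idx <- match(tis, c("a", "b", "c"))
    inter <- Reduce(intersect, sets[idx])
    excl <- setdiff(inter, unlist(sets[-idx]))
    expect_equal(s2$up$n_intersection[r], length(inter))
    expect_equal(s2$up$n_exclusive[r], length(excl))
  }
  expect_equal(sum(s2$up$n_exclusive), length(unique(unlist(sets))))

  expect_error(shared_degs(list(mk("t", "a", "b"), mk("t", "a", "b"))),
               class = "longescreen_input_error")
})

test_that("Fisher enrichment matches hypergeometric tail summation", {
  bg <- sprintf("g%03d", 1:400)
  query <- bg[1:20]
  ann <- rbind(
    data.frame(gene_id = c(bg[1:8], bg[101:122]), term_id = "partial"),
    data.frame(gene_id = query, term_id = "exact"),
    data.frame(gene_id = bg[201:230], term_id = "disjoint"))
  res <- fisher_enrichment(query, ann, bg)
  expect_equal(res$term_id[1], "exact")  # identical term is most significant
  d <- res[res$term_id == "disjoint", ]
  expect_equal(d$odds_ratio, 0)
  expect_equal(d$p_value, 1)
  p8 <- res[res$term_id == "partial", ]
  expect_equal(p8$overlap, 8)
  expect_equal(p8$p_value, fisher_tail_oracle(8, 30, 20, 400),
               tolerance = 1e-12)
  # cross-check against fisher.test one-sided
  ft <- fisher.test(matrix(c(8, 12, 22, 358), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(p8$p_value, ft$p.value, tolerance = 1e-9)

  expect_error(fisher_enrichment(c("nope"), ann, bg),
               class = "longescreen_input_error")
})
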