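test_that("lifespan weights follow n/(n+offset) and its contract", {
  expect_equal(lifespan_weight(50), 0.5)
  expect_equal(lifespan_weight(0), 0)
  expect_equal(lifespan_weight(150), 0.75)
  expect_equal(lifespan_weight(100, offset = 25), 0.8)

  n <- 0:500
  w <- lifespan_weight(n)
  expect_true(all(diff(w) > 0))       # strictly increasing
  expect_true(all(w >= 0 & w < 1))    # bounded in [0, 1)
  expect_error(lifespan_weight(-1), class = "longescreen_input_error")
  expect_error(lifespan_weight(10, offset = 0),
               class = "longescreen_input_error")
})

test_that("weighted line fit solves exact and degenerate designs", {
  fit <- fit_weighted_line(c(0, 1, 2), c(1, 3, 5), c(0.2, 5, 1.7))
  expect_equal(fit$intercept, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$weighted_rss, 0)
  expect_equal(fit$p_value, 0)   # perfect non-zero slope

  flat <- fit_weighted_line(1:5, rep(3, 5), runif(5, 0.5, 2))
  expect_equal(flat$slope, 0)
  expect_equal(flat$t_stat, 0)
  expect_equal(flat$p_value, 1)

  expect_error(fit_weighted_line(rep(1, 4), rnorm(4), rep(1, 4)),
               class = "longescreen_degenerate_error")
  expect_error(fit_weighted_line(1:2, 1:2, c(1, 1)),
               class = "longescreen_insufficient_data_error")
  expect_error(fit_weighted_line(1:4, 1:4, c(1, 1, 0, 1)),
               class = "longescreen_input_error")
})

test_that("weighted fit agrees with lm(weights=) and a numerical cost minimiser", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    x <- rnorm(n)
    y <- 1.5 - 2 * x + rnorm(n)
    w <- runif(n, 0.1, 3)
    fit <- fit_weighted_line(x, y, w)
    lmfit <- lm(y ~ x, weights = w)
    expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
    expect_equal(fit$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
    sm <- summary(lmfit)
    expect_equal(fit$slope_se, sm$coefficients["x", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(fit$p_value, sm$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-10)
    num <- wls_numeric_oracle(x, y, w)
    expect_equal(fit$intercept, num$intercept, tolerance = 1e-8)
    expect_equal(fit$slope, num$slope, tolerance = 1e-8)
  }
})

test_that("an 8-point instance matches grid search and normal equations", {
  set.seed(7)
  x <- rnorm(8); y <- 2 + 0.8 * x + rnorm(8, sd = 0.5)
  w <- runif(8, 0.2, 4)
  fit <- fit_weighted_line(x, y, w)
  grid <- wls_grid_oracle(x, y, w, center = c(fit$intercept, fit$slope),
                          half_width = 0.5, step = 0.01)
  expect_lt(abs(fit$intercept - grid$intercept), 0.011)
  expect_lt(abs(fit$slope - grid$slope), 0.011)
  expect_lte(fit$weighted_rss, grid$value + 1e-12)
})

test_that("fit is invariant to weight rescaling and reduces to OLS", {
  set.seed(11)
  x <- rnorm(12); y <- 1 + x + rnorm(12); w <- runif(12, 0.5, 2)
  f1 <- fit_weighted_line(x, y, w)
  f2 <- fit_weighted_line(x, y, w * 17.3)
  for (fld in c("intercept", "slope", "slope_se", "t_stat", "p_value"))
    expect_equal(f1[[fld]], f2[[fld]], tolerance = 1e-10)

  ols <- fit_weighted_line(x, y, rep(2, 12))
  lmfit <- summary(lm(y ~ x))
  expect_equal(ols$slope, lmfit$coefficients["x", "Estimate"],
               tolerance = 1e-10)
  expect_equal(ols$slope_se, lmfit$coefficients["x", "Std. Error"],
               tolerance = 1e-10)
})

test_that("screen ranks a perfect planted driver first and skips unusable genes", {
  set.seed(3)
  M <- 30
  strains <- sprintf("s%02d", 1:M)
  genes <- c("driver", sprintf("noise%02d", 1:8), "allmiss")
  x <- matrix(rnorm(M * length(genes)), nrow = M,
              dimnames = list(strains, genes))
  x[, "allmiss"] <- NA
  ph <- data.frame(strain_id = strains,
                   lifespan_change = 2 * x[, "driver"],
                   n_cells = sample(20:100, M, replace = TRUE))
  scr <- screen_genes(x, ph, min_strains = 10)
  expect_equal(scr$results$gene_id[scr$results$rank == 1], "driver")
  expect_equal(scr$results$slope[scr$results$rank == 1], 2, tolerance = 1e-8)
  expect_true("allmiss" %in% scr$skipped$gene_id)
  expect_false("allmiss" %in% scr$results$gene_id)
  expect_equal(scr$results$q_value, bh_oracle(scr$results$p_value))
  expect_true(all(scr$results$n_strains_used <= scr$n_strains))

  ph_bad <- ph
  ph_bad$strain_id <- paste0("other", seq_len(M))
  expect_error(screen_genes(x, ph_bad), class = "longescreen_join_error")
})

test_that("ranking sorts by p with |slope| then gene_id tie-breaks", {
  df <- data.frame(gene_id = c("a", "b", "c"),
                   p_value = c(0.01, 0.5, 0.0001),
                   slope = c(1, 1, 1))
  expect_equal(rank_by_p(df)$gene_id, c("c", "a", "b"))

  tie <- data.frame(gene_id = c("g1", "g2"), p_value = c(0.2, 0.2),
                    slope = c(1, -3))
  expect_equal(rank_by_p(tie)$gene_id, c("g2", "g1"))

  lex <- data.frame(gene_id = c("zz", "aa"), p_value = c(0.2, 0.2),
                    slope = c(2, -2))
  expect_equal(rank_by_p(lex)$gene_id, c("aa", "zz"))

  set.seed(5)
  big <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    p_value = runif(50), slope = rnorm(50))
  shuf <- big[sample(50), ]
  expect_equal(rank_by_p(shuf), rank_by_p(big))
  expect_equal(rank_by_p(big)$rank, 1:50)
})

test_that("planted-driver slope estimates are unbiased over replicates", {
  # noise variance is proportional to (n+50)/n, matching the weights
  set.seed(1234)
  n_rep <- 200
  M <- 60
  beta <- 4
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(M)
    n_cells <- sample(10:200, M, replace = TRUE)
    y <- beta * x + rnorm(M, sd = 5 * sqrt((n_cells + 50) / n_cells))
    w <- lifespan_weight(n_cells)
    est[r] <- fit_weighted_line(x, y, w)$slope
  }
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - beta), 3 * mc_se)
})

test_that("null screens are calibrated at p < 0.05", {
  sim <- simulate_screen_dataset(M = 50, G = 2000, n_drivers = 0, seed = 99)
  scr <- screen_genes(sim$compendium, sim$phenotypes)
  frac <- mean(scr$results$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se)
})
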