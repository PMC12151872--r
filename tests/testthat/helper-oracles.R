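# Independent oracles.  Each one recomputes a quantity by a route the
# implementation does not take: numerical minimisation of the literal
# cost, brute-force definitions, hand tabulations, permutations.

# Minimise the literal weighted cost sum(w * (y - b0 - b1 x)^2)
# numerically (BFGS from an OLS-free start); no normal equations.
wls_numeric_oracle <- function(x, y, w) {
  cost <- function(b) sum(w * (y - b[1] - b[2] * x)^2)
  start <- c(mean(y), 0)
  fit <- stats::optim(start, cost, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
  # Newton polish from finite differences of the literal cost (exact for
  # a quadratic up to roundoff); still touches only the cost function
  par <- fit$par
  h <- 1e-4
  for (it in 1:3) {
    g <- numeric(2); H <- matrix(0, 2, 2)
    for (i in 1:2) {
      ei <- c(0, 0); ei[i] <- h
      g[i] <- (cost(par + ei) - cost(par - ei)) / (2 * h)
      H[i, i] <- (cost(par + ei) - 2 * cost(par) + cost(par - ei)) / h^2
    }
    H[1, 2] <- H[2, 1] <-
      (cost(par + c(h, h)) - cost(par + c(h, -h)) -
         cost(par + c(-h, h)) + cost(par + c(-h, -h))) / (4 * h^2)
    par <- par - solve(H, g)
  }
  list(intercept = par[1], slope = par[2], value = cost(par))
}

# Coarse grid search of the same literal cost (grid resolution `step`).
wls_grid_oracle <- function(x, y, w, center, half_width, step) {
  b0s <- seq(center[1] - half_width, center[1] + half_width, by = step)
  b1s <- seq(center[2] - half_width, center[2] + half_width, by = step)
  best <- c(NA, NA); best_val <- Inf
  for (b0 in b0s) {
    r0 <- y - b0
    for (b1 in b1s) {
      v <- sum(w * (r0 - b1 * x)^2)
      if (v < best_val) { best_val <- v; best <- c(b0, b1) }
    }
  }
  list(intercept = best[1], slope = best[2], value = best_val)
}

# Benjamini-Hochberg from the direct definition: m*p/i with a cumulative
# minimum from the largest rank, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# One-sided Fisher enrichment p by explicit hypergeometric tail
# summation: P(overlap >= a) for a term of size k, query of size n_q,
# background n_bg.
fisher_tail_oracle <- function(a, k, n_q, n_bg) {
  upper <- min(k, n_q)
  if (a > upper) return(0)
  sum(vapply(a:upper, function(i) {
    exp(lchoose(k, i) + lchoose(n_bg - k, n_q - i) - lchoose(n_bg, n_q))
  }, 0))
}

# Pearson 2x2 chi-square closed form.
chisq_2x2_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Two-group log-rank statistic tabulated directly over the pooled event
# times (observed minus expected in group 1, hypergeometric variance).
logrank_hand_oracle <- function(time, event, group1) {
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(event & time == tt)
    d1 <- sum(event & time == tt & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Permutation p-value of the log-rank statistic under label shuffles.
logrank_perm_oracle <- function(time, event, group1, n_perm = 10000) {
  obs <- logrank_hand_oracle(time, event, group1)
  n1 <- sum(group1)
  n <- length(time)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    g <- logical(n)
    g[sample.int(n, n1)] <- TRUE
    if (logrank_hand_oracle(time, event, g) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# Independent tricube local-linear smoother with q = floor(span * n)
# neighbours, evaluated at each input x.
loess_tricube_oracle <- function(x, y, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(x, function(x0) {
    d <- abs(x - x0)
    dq <- sort(d)[q]
    w <- if (dq == 0) as.numeric(d == 0) else (1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    cf <- stats::lm.wfit(cbind(1, x[keep] - x0), y[keep], w[keep])$coefficients
    unname(cf[1])
  }, 0)
}

# Convenience: lifespan record data frame.
lifespan_df <- function(lifespan, observed = TRUE, group = "g") {
  data.frame(group = group, lifespan = lifespan,
             observed = rep_len(observed, length(lifespan)),
             stringsAsFactors = FALSE)
}
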