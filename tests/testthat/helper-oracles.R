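# Independent brute-force oracles used to cross-check the package's
# statistics.  These deliberately share no code with the implementation.

# OLS by explicit normal equations
brute_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  s2 <- sum(resid^2) / (n - p)
  list(coef = drop(beta), resid = drop(resid),
       se = sqrt(diag(solve(XtX)) * s2), df = n - p)
}

# one-way ANOVA F via explicit sums of squares on a dummy design
brute_anova_f <- function(values, group) {
  X <- stats::model.matrix(~ factor(group))
  fit0 <- brute_ols(values, X[, 1, drop = FALSE])
  fit1 <- brute_ols(values, X)
  rss0 <- sum(fit0$resid^2)
  rss1 <- sum(fit1$resid^2)
  df1 <- ncol(X) - 1
  df2 <- length(values) - ncol(X)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(statistic = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# quantile-regression slope by exhaustive enumeration of basic solutions
# (every line through two data points with distinct x); valid for tiny n
brute_rq_slope <- function(y, x, tau) {
  n <- length(y)
  best <- Inf
  best_b <- NA_real_
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      r <- y - a - b * x
      obj <- sum(r * (tau - (r < 0)))
      if (obj < best - 1e-12) {
        best <- obj
        best_b <- b
      }
    }
  }
  best_b
}

# independent greedy clumping: straightforward restatement used as an
# exhaustive oracle on small panels
brute_clump <- function(ids, p, G, p_thr, r2_thr) {
  ord <- order(p, ids)
  kept <- character(0)
  for (k in ord) {
    if (p[k] >= p_thr) next
    ok <- TRUE
    for (v in kept) {
      r2 <- stats::cor(G[, ids[k]], G[, v])^2
      if (!is.na(r2) && r2 >= r2_thr) ok <- FALSE
    }
    if (ok) kept <- c(kept, ids[k])
  }
  kept
}

# deviations fixture: residual-like values with per-group spread
make_deviations <- function(n_per_group, sds, seed = 1) {
  set.seed(seed)
  grp <- rep(seq_along(n_per_group) - 1L, n_per_group)
  e <- stats::rnorm(sum(n_per_group), sd = rep(sds, n_per_group))
  group_median_deviations(e, group = grp)
}
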