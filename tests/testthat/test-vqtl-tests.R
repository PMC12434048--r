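test_that("KW statistic reproduces hand-computed rank sums", {
  r <- kw_test(c(1, 2, 3, 4), group = c(0, 0, 1, 1))
  expect_equal(r$statistic, 2.4)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(2.4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(r$group_counts), c(2L, 2L, 0L))

  # identical multisets of deviations in the two groups: no rank signal
  r2 <- kw_test(c(1, 2, 3, 1, 2, 3), group = rep(0:1, each = 3))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  # constant deviations are degenerate, not an error
  r3 <- kw_test(rep(2, 6), group = rep(0:1, each = 3))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
})

test_that("KW agrees with the reference rank test on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:60, 1)
    grp <- sample(0:2, n, replace = TRUE)
    if (length(unique(grp)) < 2) next
    d <- abs(round(rnorm(n), 1))    # rounding forces ties
    ours <- kw_test(d, group = grp)
    ref <- kruskal.test(d, factor(grp))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BF statistic reproduces hand-computed sums of squares", {
  r <- bf_test(c(1, 2, 3, 4), group = c(0, 0, 1, 1))
  expect_equal(r$statistic, 8)
  expect_equal(r$df, c(1L, 2L))
  expect_equal(r$p_value, pf(8, 1, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # equal group means: F = 0
  r2 <- bf_test(c(1, 3, 1, 3), group = c(0, 0, 1, 1))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
})

test_that("BF equals the one-way ANOVA F oracle and leveneTest", {
  skip_if_not_installed("car")
  for (s in 1:20) {
    set.seed(100 + s)
    n <- sample(15:80, 1)
    grp <- sample(0:2, n, replace = TRUE)
    if (min(table(grp)) < 2 || length(unique(grp)) < 2) next
    e <- rnorm(n, sd = 1 + 0.5 * grp)
    dev <- group_median_deviations(e, group = grp)
    ours <- bf_test(dev)
    oracle <- brute_anova_f(dev$values, dev$group)
    expect_equal(ours$statistic, oracle$statistic, tolerance = 1e-10)
    expect_equal(ours$p_value, oracle$p, tolerance = 1e-10)
    lev <- car::leveneTest(e, factor(grp), center = median)
    expect_equal(ours$statistic, lev[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p_value, lev[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("DRM slope test matches hand OLS and handles degenerate input", {
  r <- drm_test(c(1, 2, 3, 4), group = c(0, 0, 1, 1))
  expect_equal(r$effect, 2)
  expect_equal(r$statistic, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p_value, 2 * pt(2 * sqrt(2), 2, lower.tail = FALSE),
               tolerance = 1e-12)

  r2 <- drm_test(rep(3, 8), group = rep(0:1, each = 4))
  expect_equal(r2$effect, 0)
  expect_equal(r2$p_value, 1)

  expect_error(drm_test(rnorm(5), group = rep(1, 5)), "constant")
})

test_that("DRM equals an independent normal-equations fit", {
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 50
    grp <- sample(0:2, n, replace = TRUE)
    dev <- make_deviations(c(20, 20, 10), sds = c(1, 1.3, 1.6), seed = s)
    ours <- drm_test(dev)
    X <- cbind(1, as.numeric(dev$group))
    oracle <- brute_ols(dev$values, X)
    expect_equal(ours$effect, oracle$coef[2], tolerance = 1e-10)
    expect_equal(ours$statistic, unname(oracle$coef[2] / oracle$se[2]),
                 tolerance = 1e-10)
  }
})

test_that("tests are invariant to phenotype shift and covariate rescale", {
  set.seed(77)
  n <- 600
  g <- sample(0:2, n, replace = TRUE, prob = c(.49, .42, .09))
  z <- rnorm(n)
  y <- 0.2 * g + 0.5 * z + rnorm(n, sd = 1 + 0.2 * g)

  p_of <- function(y, z_scale) {
    res <- residualize(y, g, covariates = cbind(z = z * z_scale))
    dev <- group_median_deviations(res)
    c(kw = kw_test(dev)$p_value, bf = bf_test(dev)$p_value,
      drm = drm_test(dev)$p_value, dglm = dglm_test(res)$p_value,
      quail = quail_test(res, K = 20, estimate_effect = FALSE)$p_value)
  }
  base <- p_of(y, 1)
  shifted <- p_of(y + 100, 1)
  rescaled <- p_of(y, 1000)
  expect_equal(base, shifted, tolerance = 1e-6)
  expect_equal(base, rescaled, tolerance = 1e-6)
})

test_that("rank-based paths are invariant to monotone transforms", {
  set.seed(88)
  n <- 300
  grp <- sample(0:2, n, replace = TRUE)
  e <- rnorm(n, sd = 1 + 0.3 * grp)
  dev <- group_median_deviations(e, group = grp)
  mono <- function(x) x^3 + 2 * x        # strictly increasing

  kw1 <- kw_test(dev)
  kw2 <- kw_test(mono(dev$values), group = dev$group)
  expect_equal(kw1$statistic, kw2$statistic, tolerance = 1e-12)

  # INT consumes only ranks, so DGLM_INT is transform-invariant too
  d1 <- dglm_test(e, group = grp, apply_int = TRUE)
  d2 <- dglm_test(mono(e), group = grp, apply_int = TRUE)
  expect_equal(d1$statistic, d2$statistic, tolerance = 1e-8)

  q1 <- quail_test(e, group = grp, K = 10, estimate_effect = FALSE)
  q2 <- quail_test(mono(e), group = grp, K = 10, estimate_effect = FALSE)
  expect_equal(q1$p_value, q2$p_value, tolerance = 1e-10)
})
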