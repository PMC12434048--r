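test_that("residualize removes exact covariate and genotype main effects", {
  set.seed(10)
  g <- rep(c(0L, 1L, 2L), each = 10)
  z <- rnorm(30)

  # phenotype equal to a covariate column: perfect fit, residuals all 0
  r <- residualize(z, g, covariates = cbind(z = z))
  expect_lt(max(abs(r$values)), 1e-10)

  # pure genotype main effect: fully absorbed, zero group means
  r2 <- residualize(1.0 * g, g)
  expect_lt(max(abs(r2$values)), 1e-10)
  expect_lt(max(abs(tapply(r2$values, r2$group, mean))), 1e-10)
})

test_that("residualize matches an independent normal-equations solve", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c(0L, 0L, 1L, 1L, 2L, 2L)
  z <- c(1, 0, 1, 0, 1, 0)
  r <- residualize(y, g, covariates = cbind(z = z))
  X <- cbind(1, as.numeric(g == 1), as.numeric(g == 2), z)
  oracle <- brute_ols(y, X)
  expect_equal(r$values, oracle$resid, tolerance = 1e-10)

  # random instances: residuals orthogonal to every design column
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    g <- sample(0:2, n, replace = TRUE)
    Z <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("a", "b")))
    y <- 0.3 * g + Z %*% c(1, -2) + rnorm(n)
    r <- residualize(y, g, covariates = Z)
    X <- cbind(1, as.numeric(g == 1), as.numeric(g == 2), Z)
    expect_lt(max(abs(crossprod(X, r$values))), 1e-8 * n * sd(y))
    expect_lt(abs(sum(r$values)), 1e-8 * n)
  }
})

test_that("residualize applies listwise deletion and validates input", {
  y <- c(NA, rnorm(29))
  g <- c(0L, rep(c(0L, 1L, 2L), length.out = 28), NA)
  z <- c(rnorm(29), NA)
  r <- residualize(y, g, covariates = cbind(z = z))
  expect_equal(r$n_dropped, 2L)
  expect_length(r$values, 28L)

  expect_error(residualize(rnorm(10), rep(0.5, 10)), "dosage")
  expect_error(residualize(rnorm(10), rep(0L, 10)), "monomorphic")
  g2 <- rep(c(0L, 1L), 10)
  expect_error(
    residualize(rnorm(20), g2,
                covariates = cbind(ok = rnorm(20), bad = rep(2, 20))),
    "bad")
})

test_that("group median deviations subtract group medians and take abs", {
  d <- group_median_deviations(c(1, 2, 3), group = c(0, 0, 0))
  expect_equal(d$values, c(1, 0, 1))

  d2 <- group_median_deviations(c(-1, 1, -5, 5), group = c(0, 0, 1, 1))
  expect_equal(d2$values, c(1, 1, 5, 5))

  # signed deviations have within-group median exactly 0; absolute
  # deviations invariant to per-group location shifts
  set.seed(2)
  e <- rnorm(101)
  grp <- sample(0:2, 101, replace = TRUE)
  med <- ave(e, grp, FUN = median)
  expect_true(all(abs(tapply(e - med, grp, median)) < 1e-12))
  d3 <- group_median_deviations(e, group = grp)
  d4 <- group_median_deviations(e + c(5, -3, 100)[grp + 1], group = grp)
  expect_equal(d3$values, d4$values, tolerance = 1e-12)
})

test_that("mean absolute deviation approaches the half-normal mean", {
  dev <- make_deviations(c(10000, 10000, 10000), sds = c(1, 2, 0.5),
                         seed = 33)
  m <- tapply(dev$values, dev$group, mean)
  expected <- c(1, 2, 0.5) * sqrt(2 / pi)
  expect_true(all(abs(m - expected) / expected < 0.05))
})

test_that("inverse normal transform follows the Blom convention", {
  out <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(out[2], 0)
  expect_equal(out[1], -out[3])

  x <- sort(rnorm(5))
  expect_equal(inverse_normal_transform(x),
               qnorm(((1:5) - 0.375) / 5.25))

  set.seed(5)
  x2 <- rnorm(50)
  expect_false(is.unsorted(inverse_normal_transform(sort(x2))))

  expect_error(inverse_normal_transform(rep(1, 10)), "degenerate")
  expect_error(inverse_normal_transform(1), "at least 2")
})

test_that("inverse normal transform output is close to normal at large N", {
  set.seed(8)
  x <- rchisq(20000, df = 2)   # strongly skewed input
  z <- inverse_normal_transform(x)
  skew <- mean(z^3) / sd(z)^3
  exkurt <- mean(z^4) / sd(z)^4 - 3
  expect_lt(abs(skew), 0.05)
  expect_lt(abs(exkurt), 0.1)
})
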