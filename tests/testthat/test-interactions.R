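test_that("clumping keeps the best of perfectly correlated variants", {
  set.seed(40)
  g <- simulate_genotypes(200, 0.3)
  G <- cbind(a = g, b = g, c = simulate_genotypes(200, 0.3))
  res <- data.frame(id = c("a", "b", "c"), p = c(1e-10, 1e-12, 1e-9))
  kept <- clump(res, G, p_threshold = 1e-6, r2_threshold = 0.01)
  expect_true("b" %in% kept)      # smaller p of the duplicated pair
  expect_false("a" %in% kept)
  expect_true("c" %in% kept)

  # mutually independent significant variants are all kept
  set.seed(41)
  G2 <- sapply(1:5, function(i) simulate_genotypes(5000, 0.3))
  colnames(G2) <- letters[1:5]
  res2 <- data.frame(id = letters[1:5], p = 10^-(10:6))
  expect_setequal(clump(res2, G2, 1e-5, 0.01), letters[1:5])

  expect_error(clump(data.frame(id = "zz", p = 1e-10), G2, 1e-5, 0.01),
               "zz")
})

test_that("greedy clumping matches exhaustive oracle on a block panel", {
  set.seed(42)
  n <- 300
  base1 <- simulate_genotypes(n, 0.3)
  base2 <- simulate_genotypes(n, 0.4)
  corrupt <- function(g, k) {          # partial copy: correlated variant
    i <- sample(n, k)
    g[i] <- simulate_genotypes(k, 0.3)
    g
  }
  G <- cbind(v01 = base1, v02 = corrupt(base1, 30), v03 = corrupt(base1, 60),
             v04 = base2, v05 = corrupt(base2, 40),
             v06 = simulate_genotypes(n, 0.2),
             v07 = simulate_genotypes(n, 0.5),
             v08 = corrupt(base2, 20),
             v09 = simulate_genotypes(n, 0.1),
             v10 = corrupt(base1, 10))
  p <- c(1e-9, 1e-8, 1e-7, 1e-10, 1e-6, 1e-5, 0.5, 1e-11, 1e-4, 1e-8)
  res <- data.frame(id = colnames(G), p = p)
  for (r2_thr in c(0.01, 0.2, 0.8)) {
    expect_identical(clump(res, G, 1e-3, r2_thr),
                     brute_clump(colnames(G), p, G, 1e-3, r2_thr))
  }

  # equal-p tie resolved by id, so input order is irrelevant
  res_tie <- data.frame(id = colnames(G), p = rep(1e-9, 10))
  shuffled <- res_tie[sample(nrow(res_tie)), ]
  expect_identical(clump(res_tie, G, 1e-3, 0.01),
                   clump(shuffled, G, 1e-3, 0.01))
})

test_that("GxE scan fits every pair and recovers a planted interaction", {
  set.seed(50)
  n <- 10000
  V <- sapply(1:3, function(i) simulate_genotypes(n, 0.3))
  colnames(V) <- c("rs1", "rs2", "rs3")
  E <- data.frame(AGE = rnorm(n, 50, 8), SEX = rbinom(n, 1, 0.5),
                  BMI = rnorm(n, 24, 3))
  pcs <- matrix(rnorm(2 * n), n)
  y <- 0.4 * V[, "rs1"] + 0.1 * E$BMI + 0.3 * V[, "rs1"] * E$SEX + rnorm(n)

  fits <- gxe_scan(y, V, E, pcs = pcs)
  expect_equal(nrow(fits), 3 * 3)
  hit <- fits[fits$vqtl == "rs1" & fits$partner == "SEX", ]
  expect_lt(abs(hit$beta_int - 0.3) / hit$se_int, 3)
  expect_equal(abs(hit$signed_log10p), -log10(hit$p_int))
  # exacerbation: both main and interaction positive
  expect_gt(hit$signed_log10p, 0)
})

test_that("interaction fits match the normal-equations oracle", {
  set.seed(51)
  n <- 400
  g <- simulate_genotypes(n, 0.3)
  E <- data.frame(e1 = rnorm(n), e2 = rbinom(n, 1, 0.4))
  y <- 0.2 * g + 0.3 * E$e1 - 0.25 * g * E$e1 + rnorm(n)
  fits <- gxe_scan(y, cbind(snp = g), E)
  row <- fits[fits$partner == "e1", ]
  X <- cbind(1, g, E$e1, E$e2, g * E$e1)
  oracle <- brute_ols(y, X)
  expect_equal(row$beta_int, unname(oracle$coef[5]), tolerance = 1e-8)
  expect_equal(row$se_int, unname(oracle$se[5]), tolerance = 1e-8)
  expect_equal(row$beta_g, unname(oracle$coef[2]), tolerance = 1e-8)

  # flipping allele coding flips signs but not significance
  fits_flip <- gxe_scan(y, cbind(snp = 2 - g), E)
  row_f <- fits_flip[fits_flip$partner == "e1", ]
  expect_equal(row_f$beta_int, -row$beta_int, tolerance = 1e-8)
  expect_equal(abs(row_f$signed_log10p), abs(row$signed_log10p),
               tolerance = 1e-8)
})

test_that("GxG scan enumerates unordered pairs and recovers effects", {
  set.seed(52)
  n <- 10000
  V30 <- sapply(1:30, function(i) simulate_genotypes(200, 0.3))
  colnames(V30) <- sprintf("rs%02d", 1:30)
  y30 <- rnorm(200)
  fits30 <- gxg_scan(y30, V30)
  expect_equal(nrow(fits30), choose(30, 2))
  expect_equal(nrow(fits30), 435L)

  V <- sapply(1:2, function(i) simulate_genotypes(n, 0.3))
  colnames(V) <- c("rsA", "rsB")
  E <- data.frame(e1 = rnorm(n))
  y <- 0.3 * V[, 1] + 0.2 * V[, 2] + 0.5 * V[, 1] * V[, 2] + rnorm(n)
  fit <- gxg_scan(y, V, E)
  expect_equal(nrow(fit), 1L)
  expect_lt(abs(fit$beta_int - 0.5) / fit$se_int, 3)
  expect_true(all((V[, 1] * V[, 2]) %in% c(0, 1, 2, 4)))
})

test_that("signed matrices pivot GxE and symmetrize GxG", {
  fits <- data.frame(vqtl = c("rs1", "rs1", "rs2", "rs2"),
                     partner = c("AGE", "SEX", "AGE", "SEX"),
                     signed_log10p = c(1.5, -2, 0.3, 4))
  m <- interaction_matrix(fits)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["rs1", "SEX"], -2)

  gxg <- data.frame(vqtl = c("rs1", "rs1", "rs2"),
                    partner = c("rs2", "rs3", "rs3"),
                    signed_log10p = c(5, 1, 2))
  mg <- interaction_matrix(gxg)
  expect_equal(mg, t(mg))
  expect_equal(diag(mg), setNames(rep(0, 3), c("rs1", "rs2", "rs3")))

  path <- withr::local_tempfile(fileext = ".tsv")
  interaction_matrix(fits, file = path)
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$SEX, c(-2, 4))
})
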