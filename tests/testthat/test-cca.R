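test_that("covariance blocks reproduce textbook arithmetic", {
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- cbind(c(2, 1, 4, 3, 5), c(5, 4, 3, 2, 1))
  b <- covariance_blocks(x, y)
  expect_equal(b$s_xx[1, 1], var(x[, 1]))
  expect_equal(b$s_xy[1, 1], sum((x - 3) * (y[, 1] - 3)) / 4)  # = 1.75
  expect_equal(b$s_xy[1, 2], -2.5)
  expect_equal(b$n, 5)
  # y = x gives s_xy = s_xx; orthogonal blocks give zero cross-covariance
  x2 <- matrix(rnorm(40), 20, 2)
  expect_equal(covariance_blocks(x2, x2)$s_xy, cov(x2))
  xo <- matrix(rep(c(1, -1), 4), ncol = 1)
  yo <- matrix(rep(c(1, 1, -1, -1), 2), ncol = 1)
  expect_equal(covariance_blocks(xo, yo)$s_xy[1, 1], 0)
  expect_error(covariance_blocks(matrix(1, 10, 1), matrix(rnorm(10))),
               "constant")
})

test_that("canonical correlations have their closed forms", {
  b <- structure(list(s_xx = matrix(1), s_xy = matrix(c(0.3, 0.4), 1),
                      s_yy = diag(2), n = 100), class = "covariance_blocks")
  cc <- canonical_correlations(b)
  expect_equal(cc$r[1], 0.5)              # r^2 = |s_xy|^2 with identity blocks
  b0 <- b; b0$s_xy <- matrix(0, 1, 2)
  expect_equal(canonical_correlations(b0)$r[1], 0, tolerance = 1e-12)
})

test_that("canonical correlations match the eigen-solver oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 50
    x <- matrix(rnorm(n * 3), n, 3)
    y <- x %*% matrix(rnorm(9), 3) * 0.5 + matrix(rnorm(n * 3), n, 3)
    b <- covariance_blocks(x, y)
    r <- canonical_correlations(b)$r
    # independent formula: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx
    ev <- eigen(solve(b$s_xx) %*% b$s_xy %*% solve(b$s_yy) %*% t(b$s_xy),
                only.values = TRUE)$values
    expect_equal(r, sqrt(sort(Re(ev), decreasing = TRUE)), tolerance = 1e-8)
    # r maximises the correlation objective: no random direction beats r1
    cc <- canonical_correlations(b)
    for (k in 1:5) {
      a_try <- rnorm(3); b_try <- rnorm(3)
      expect_lte(abs(cor(x %*% a_try, y %*% b_try)), r[1] + 1e-10)
    }
  }
})

test_that("canonical correlations are invariant to affine maps of Y", {
  set.seed(33)
  n <- 80
  x <- matrix(rnorm(n * 2), n, 2)
  y <- 0.4 * x[, 1] + matrix(rnorm(n * 2), n, 2)
  r0 <- canonical_correlations(covariance_blocks(x, y))$r
  A <- matrix(c(2, 0.5, -1, 3), 2)   # invertible
  y2 <- y %*% A + matrix(rep(c(5, -7), each = n), n, 2)
  r1 <- canonical_correlations(covariance_blocks(x, y2))$r
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("Wilks' Lambda test matches the regression-F oracle", {
  # null: r = 0 -> Lambda 1, F 0, p 1
  w0 <- wilks_lambda_test(0, 100, 1, 2)
  expect_equal(w0$wilks_lambda, 1)
  expect_equal(w0$f_stat, 0)
  expect_equal(w0$p, 1)
  # g=1, p=2, n=100, r=0.3: F = (0.09/0.91) * (97/2)
  w <- wilks_lambda_test(0.3, 100, 1, 2)
  expect_equal(w$f_stat, (0.09 / 0.91) * (97 / 2), tolerance = 1e-12)
  expect_equal(w$df1, 2); expect_equal(w$df2, 97)
  # oracle: overall F of regressing x on the two y columns
  set.seed(9)
  n <- 100
  y <- matrix(rnorm(2 * n), n, 2)
  x <- 0.3 * y[, 1] + rnorm(n)
  r1 <- canonical_correlations(covariance_blocks(matrix(x), y))$r[1]
  fit <- summary(lm(x ~ y))
  f <- unname(fit$fstatistic)
  ww <- wilks_lambda_test(r1, n, 1, 2)
  expect_equal(ww$f_stat, f[1], tolerance = 1e-9)
  expect_equal(ww$p, pf(f[1], f[2], f[3], lower.tail = FALSE),
               tolerance = 1e-9)
  # g=1, p=1 equals the Pearson correlation t-test
  y1 <- rnorm(n); x1 <- 0.2 * y1 + rnorm(n)
  rr <- abs(cor(x1, y1))
  wp <- wilks_lambda_test(rr, n, 1, 1)
  expect_equal(wp$p, cor.test(x1, y1)$p.value, tolerance = 1e-9)
  expect_error(wilks_lambda_test(0.5, 4, 1, 2), "small")
})

test_that("per-SNP scan detects a perfect monotone proxy", {
  spec <- cohort_spec(n_samples = 200, n_snps = 10, n_causal = 0, seed = 2)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, spec)
  # overwrite one SNP with a deterministic function of egfr_std
  d <- g$dosage
  d[, 1] <- as.integer(cut(y$egfr_std, breaks = 3)) - 1L
  g2 <- genotype_matrix(d, g$variants, g$samples)
  sc <- cca_scan(g2, y)
  # a three-level dosage proxy of a normal score tops out near r = 0.88
  expect_gt(sc$results$r1[1], 0.85)
  expect_lt(sc$results$p[1], 1e-50)
  expect_true(all(sc$results$p_adj >= sc$results$p))
  # bonferroni mode multiplies by the scan size
  expect_equal(sc$results$p_adj,
               pmin(1, sc$results$p * sc$m))
})

test_that("scan p-values equal the per-SNP least-squares oracle", {
  spec <- cohort_spec(n_samples = 150, n_snps = 30, seed = 4)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, spec)
  sc <- cca_scan(g, y)
  yb <- pheno_y_block(y)
  for (j in seq_len(30)) {
    fit <- summary(lm(g$dosage[, j] ~ yb))
    f <- unname(fit$fstatistic)
    p_oracle <- pf(f[1], f[2], f[3], lower.tail = FALSE)
    expect_equal(log10(sc$results$p[j]), log10(p_oracle), tolerance = 1e-8)
  }
  expect_error(cca_scan(g, yb[1:100, ]), "mismatch")
})

test_that("planted canonical correlation of 0.3 is recovered unbiasedly", {
  set.seed(77)
  n <- 2000
  est <- replicate(200, {
    x <- rbinom(n, 2, 0.3)
    xs <- as.vector(scale(x))
    y1 <- 0.3 * xs + sqrt(1 - 0.09) * rnorm(n)
    y2 <- rnorm(n)
    b <- covariance_blocks(matrix(x), cbind(y1, y2))
    canonical_correlations(b)$r[1]
  })
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("minimal detectable correlation behaves like Fisher-z power", {
  expect_lt(min_detectable_r(1e8), 0.001)
  ns <- c(500, 1000, 5000, 50000)
  rs <- min_detectable_r(ns)
  expect_true(all(diff(rs) < 0))
  # two-sided is strictly more demanding
  expect_gt(min_detectable_r(2494, sided = "two"), min_detectable_r(2494))
  expect_error(min_detectable_r(2), "exceed")
  expect_error(min_detectable_r(100, alpha = 0.9, power = 0.8), "alpha")
})
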