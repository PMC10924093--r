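test_that("beta standardisation follows the t-statistic formula", {
  expect_equal(standardize_betas(0, 0.1, 100), 0)
  expect_equal(standardize_betas(0.1, 0.02, 1000), 5 / sqrt(1023),
               tolerance = 1e-12)
  set.seed(1)
  b <- rnorm(50); s <- runif(50, 0.01, 0.2); n <- sample(100:1000, 50, TRUE)
  r <- standardize_betas(b, s, n)
  expect_equal(sign(r), sign(b))
  expect_true(all(abs(r) < 1))
  expect_error(standardize_betas(0.1, 0, 100), "positive")
  # cross-check against OLS on standardised simulated variables
  n <- 500; x <- scale(rbinom(n, 2, 0.3)); y <- scale(0.2 * x + rnorm(n))
  fit <- summary(lm(y ~ x))
  r_hat <- standardize_betas(fit$coefficients[2, 1], fit$coefficients[2, 2], n)
  expect_equal(r_hat, cor(x, y)[1, 1], tolerance = 1e-6)
})

test_that("phenotypic correlation is recovered from null-genetics summaries", {
  spec <- cohort_spec(n_samples = 2000, n_snps = 5000, n_causal = 0,
                      pheno_corr = 0.6, ld_rho = 0, seed = 19)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, spec)
  ss <- simulate_summary_stats(g, y)
  pc <- estimate_pheno_corr(ss)
  expect_lt(abs(pc$s_yy[1, 2] - 0.6), 0.05)
  expect_equal(diag(pc$s_yy), c(egfr = 1, bun = 1))
  # independent traits: the estimate tracks the cohort's realised
  # phenotype correlation within the effect-column sampling bound
  spec0 <- cohort_spec(n_samples = 1000, n_snps = 2000, n_causal = 0,
                       pheno_corr = 0, ld_rho = 0, seed = 23)
  g0 <- simulate_genotypes(spec0)
  y0 <- simulate_phenotypes(g0, spec0)
  pc0 <- estimate_pheno_corr(simulate_summary_stats(g0, y0))
  r_emp <- cor(y0$egfr_std, y0$bun_std)
  expect_lt(abs(pc0$s_yy[1, 2] - r_emp), 3 / sqrt(2000))
  expect_lt(abs(pc0$s_yy[1, 2]), 0.1)
  # degenerate duplicated trait
  ss_dup <- ss
  for (cl in c("beta", "se", "n", "p"))
    ss_dup[[paste0(cl, "_bun")]] <- ss_dup[[paste0(cl, "_egfr")]]
  pc_dup <- estimate_pheno_corr(ss_dup)
  expect_gt(pc_dup$s_yy[1, 2], 1 - 1e-9)
  expect_error(estimate_pheno_corr(ss[1:2, ]), "3 SNPs")
  expect_warning(estimate_pheno_corr(ss[1:100, ]), "recommended")
})

test_that("PSD shrinkage follows the declared schedule", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  out <- shrink_to_psd(s)
  expect_equal(unclass(out), s, ignore_attr = TRUE)
  expect_equal(attr(out, "iterations"), 0L)
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  shr <- shrink_to_psd(bad, min_eig = 1e-12)
  expect_equal(attr(shr, "iterations"), 183L)   # first k with 1.2*0.999^k <= 1
  expect_equal(shr[1, 2], 1.2 * 0.999^183, tolerance = 1e-12)
  expect_gte(min(eigen(shr)$values), 1e-12)
  expect_equal(diag(shr), c(1, 1))
  # never increases |off-diagonal|, terminates on random symmetric input
  set.seed(3)
  for (rep in 1:10) {
    a <- matrix(runif(9, -1.5, 1.5), 3); a <- (a + t(a)) / 2; diag(a) <- 1
    sh <- shrink_to_psd(a)
    expect_true(all(abs(sh) <= abs(a) + 1e-12))
    expect_equal(diag(sh), diag(a))
  }
  expect_error(shrink_to_psd(matrix(c(1, 2, 3, 1), 2)), "symmetric")
  expect_error(shrink_to_psd(bad, max_iter = 5), "converge")
})

test_that("summary-statistics validation applies the stated filters", {
  df <- generic_stats_df()
  df <- rbind(df, df[1, ])              # duplicate key (both copies drop)
  df$se[2] <- 0                          # zero SE
  df$ref[3] <- "I"                       # non-ACGT
  extra <- df[1, ]; extra$chr <- "9"; extra$pos <- 99L; extra$af <- 0.005
  df <- rbind(df, extra)                 # AF below 0.01
  tab <- read_summary_stats(write_tsv(df))
  expect_warning(out <- validate_summary_input(tab), "no rows")
  expect_equal(unname(out$report["se_zero"]), 1L)
  expect_equal(unname(out$report["non_acgt"]), 1L)
  expect_equal(unname(out$report["duplicate"]), 2L)
  expect_equal(unname(out$report["af"]), 1L)
  expect_equal(nrow(out$stats), 0L)
  expect_equal(unname(out$report["input"]), 5L)
})

test_that("single-SNP metaCCA has its closed form", {
  s_yy <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("egfr", "bun"),
                                                       c("egfr", "bun")))
  stats <- data.frame(chr = "1", pos = 100L, rsid = "rs1", ref = "A",
                      ea = "G", af = 0.3,
                      beta_egfr = 0.1, se_egfr = 1, n_egfr = 1000, p_egfr = NA,
                      beta_bun = -0.1, se_bun = 1, n_bun = 1000, p_bun = NA)
  attr(stats, "traits") <- c("egfr", "bun")
  # pick se so that r_xy is exactly (0.1, -0.1): t/sqrt(t^2+n-2) = 0.1
  t_needed <- 0.1 * sqrt(998 / (1 - 0.01))
  stats$se_egfr <- stats$beta_egfr / t_needed
  stats$se_bun <- abs(stats$beta_bun / t_needed)
  sc <- metacca_scan(stats, s_yy)
  expect_equal(sc$results$rxy_egfr, 0.1, tolerance = 1e-12)
  expect_equal(sc$results$r1, 0.2, tolerance = 1e-10)  # (3*0.01)/0.75 = 0.04
  # null SNP: r1 = 0, p = 1
  stats0 <- stats
  stats0$beta_egfr <- stats0$beta_bun <- 0
  stats0$se_egfr <- stats0$se_bun <- 1
  sc0 <- metacca_scan(stats0, s_yy)
  expect_equal(sc0$results$r1, 0)
  expect_equal(sc0$results$p, 1)
})

test_that("opposite-sign effects are synergistic when traits correlate", {
  rho <- 0.5
  s_yy <- matrix(c(1, rho, rho, 1), 2)
  r1_of <- function(s) sqrt(sum(s * solve(s_yy, s)))
  for (c_eff in seq(0.05, 0.45, by = 0.05))
    expect_gt(r1_of(c(c_eff, -c_eff)), r1_of(c(c_eff, c_eff)))
})

test_that("metaCCA agrees with individual-level CCA on the same cohort", {
  # ~1% causal fraction, the polygenic sparsity the estimator assumes
  spec <- cohort_spec(n_samples = 2000, n_snps = 400, n_causal = 4,
                      seed = 41)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, spec)
  sc <- cca_scan(g, y)
  ss <- simulate_summary_stats(g, y)
  pc <- suppressWarnings(estimate_pheno_corr(ss))
  mt <- metacca_scan(ss, pc)
  idx <- match(variant_id(mt$results), variant_id(sc$results))
  dr <- abs(mt$results$r1 - sc$results$r1[idx])
  expect_lt(median(dr), 0.01)
  expect_gt(cor(-log10(mt$results$p), -log10(sc$results$p[idx]),
                method = "spearman"), 0.99)
})
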