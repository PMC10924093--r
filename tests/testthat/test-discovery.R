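test_that("significance filter applies both threshold modes", {
  df <- data.frame(chr = "1", pos = 1:10, ref = "A", ea = "G",
                   p = c(1e-3, 6e-3, 4e-3, 0.2, 4.9e-8, 5.1e-8,
                         1e-9, 0.5, 4.99e-3, 5.01e-3))
  kept <- significance_filter(df, "bonferroni_by_count", alpha = 0.05)
  expect_equal(kept$p, df$p[df$p < 0.005])      # 0.05 / 10
  fixed <- significance_filter(df, "fixed_genomewide")
  expect_true(4.9e-8 %in% fixed$p)
  expect_false(5.1e-8 %in% fixed$p)
  # monotone in alpha
  k1 <- nrow(significance_filter(df, "bonferroni_by_count", alpha = 0.01))
  k2 <- nrow(significance_filter(df, "bonferroni_by_count", alpha = 0.10))
  expect_lte(k1, k2)
  # empty survivors allowed, empty input is not
  expect_equal(nrow(significance_filter(df[df$p > 0.4, , drop = FALSE],
                                        "fixed_genomewide")), 0)
  expect_error(significance_filter(df[0, ], "fixed_genomewide"), "empty")
})

test_that("direction filter keeps only strictly opposite effect pairs", {
  df <- data.frame(beta_egfr = c(0.02, 0.02, 0.0, -0.01),
                   beta_bun = c(-0.03, 0.03, -0.03, 0.05))
  out <- opposite_direction_filter(df)
  expect_equal(out$beta_egfr, c(0.02, -0.01))
  expect_error(opposite_direction_filter(data.frame(x = 1)), "not found")
})

test_that("harmonisation joins direct and allele-swapped records", {
  a <- data.frame(chr = c("1", "1", "2", "3"), pos = c(10L, 20L, 30L, 40L),
                  rsid = paste0("rs", 1:4),
                  ref = c("A", "G", "C", "A"), ea = c("G", "A", "T", "T"),
                  af = c(0.2, 0.3, 0.4, 0.25),
                  beta = c(0.1, 0.2, 0.3, 0.4), stringsAsFactors = FALSE)
  b <- a
  # swap alleles at the second site; rs4 is A/T strand-ambiguous
  b$ref[2] <- "A"; b$ea[2] <- "G"; b$beta[2] <- -0.2; b$af[2] <- 0.7
  b$ref[4] <- "T"; b$ea[4] <- "A"
  h <- harmonize_across_datasets(a, b)
  expect_equal(nrow(h$matched), 3)       # rs4 excluded from swap matching
  expect_equal(h$n_swapped, 1)
  m2 <- h$matched[h$matched$rsid == "rs2", ]
  expect_equal(m2$beta_b, 0.2)           # sign flipped back
  expect_equal(m2$af_b, 0.3)             # frequency complemented
  expect_true(4 %in% h$unmatched_a)
  # involution: harmonising in either order pairs the same variants
  h_rev <- harmonize_across_datasets(b, a)
  expect_equal(sort(h$matched$rsid), sort(h_rev$matched$rsid))
  expect_equal(h_rev$matched$beta_b[h_rev$matched$rsid == "rs2"], -0.2)
  # without swapping the flipped site is unmatched
  expect_equal(nrow(harmonize_across_datasets(a, b, allow_swap = FALSE)$matched), 2)
})

test_that("nominal replication requires p < alpha in every cohort", {
  cand <- data.frame(chr = "1", pos = c(10L, 20L, 30L),
                     ref = "A", ea = "G", stringsAsFactors = FALSE)
  mk <- function(p, pos = c(10L, 20L, 30L)) {
    data.frame(chr = "1", pos = pos, ref = "A", ea = "G", p = p,
               stringsAsFactors = FALSE)
  }
  res <- replicate_nominal(cand, list(mk(c(0.01, 0.01, 0.04)),
                                      mk(c(0.04, 0.06, 0.049))))
  expect_equal(res$replicated$pos, c(10L, 30L))
  # a candidate missing from one cohort is untestable
  res2 <- replicate_nominal(cand, list(mk(c(0.01, 0.01, 0.01)),
                                       mk(c(0.01, 0.01), pos = c(10L, 20L))))
  expect_equal(res2$untestable$pos, 30L)
  expect_false(30L %in% res2$replicated$pos)
})

test_that("clumping walks the greedy two-threshold algorithm", {
  sig <- data.frame(chr = "1",
                    pos = c(10000L, 20000L, 30000L, 600000L, 610000L),
                    ref = "A", ea = "G",
                    p = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6),
                    stringsAsFactors = FALSE)
  ids <- variant_id(sig)
  r2 <- diag(5); dimnames(r2) <- list(ids, ids)
  r2[1, 2] <- r2[2, 1] <- 0.7    # block {1,2}
  r2[4, 5] <- r2[5, 4] <- 0.7    # block {4,5}
  r2[1, 3] <- r2[3, 1] <- 0.2    # SNP3 independent of 1 but in LD above r2_lead
  r2[c(1, 2, 3), c(4, 5)] <- 0.05; r2[c(4, 5), c(1, 2, 3)] <- 0.05
  r2[2, 3] <- r2[3, 2] <- 0.2
  ls <- clump_lead_snps(sig, r2)
  expect_equal(ls$independent, ids[c(1, 3, 4)])
  expect_equal(ls$leads, ids[c(1, 4)])
  expect_equal(nrow(ls$loci), 2)
  # partition: every significant SNP in exactly one locus
  expect_false(any(is.na(ls$assignments$locus)))
  expect_equal(sum(ls$loci$n_members), 5)
  expect_equal(ls$assignments$locus, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(ls$loci$lead_id, ids[c(1, 4)])
  expect_equal(ls$loci$lead_p, c(1e-10, 1e-7))
  # two fully correlated SNPs yield one lead, the smaller p
  sig2 <- sig[1:2, ]
  r2b <- matrix(1, 2, 2, dimnames = list(ids[1:2], ids[1:2]))
  ls2 <- clump_lead_snps(sig2, r2b)
  expect_equal(ls2$leads, ids[1])
  expect_equal(nrow(ls2$loci), 1)
  # single SNP is its own lead
  ls1 <- clump_lead_snps(sig[1, ], diag(1))
  expect_equal(ls1$loci$lead_id, ids[1])
  # missing r2 for a needed pair is a named error
  r2c <- r2[1:4, 1:4]
  expect_error(clump_lead_snps(sig, r2c), "unavailable")
})

test_that("clumping accepts a genotype panel as the LD source", {
  spec <- cohort_spec(n_samples = 400, n_snps = 60, ld_rho = 0.9,
                      ld_block_size = 6, seed = 13)
  g <- simulate_genotypes(spec)
  y <- simulate_phenotypes(g, spec)
  sc <- cca_scan(g, y)
  sig <- sc$results
  sig <- sig[order(sig$p)[1:12], ]
  ls <- clump_lead_snps(sig, g)
  expect_lte(length(ls$leads), length(ls$independent))
  expect_lte(length(ls$independent), nrow(sig))
  expect_false(any(is.na(ls$assignments$locus)))
})

test_that("nearest-gene annotation uses distance then size then name", {
  genes <- data.frame(chr = "1",
                      start = c(1000L, 50000L, 120000L),
                      end = c(5000L, 60000L, 125000L),
                      symbol = c("A", "B", "C"), stringsAsFactors = FALSE)
  leads <- data.frame(chr = c("1", "1", "1", "2"),
                      pos = c(2000L, 70000L, 90000L, 5L))
  ann <- nearest_gene(leads, genes)
  expect_equal(ann$gene, c("A", "B", "C", "none"))
  expect_equal(ann$gene_distance[1], 0)
  expect_equal(ann$gene_distance[2], 10000)   # 10 kb right of B's end
  # equidistant tie: smaller interval wins
  g2 <- data.frame(chr = "1", start = c(100L, 300L), end = c(150L, 320L),
                   symbol = c("BIG", "SMALL"))
  mid <- data.frame(chr = "1", pos = 225L)    # 75 from both intervals
  expect_equal(nearest_gene(mid, g2)$gene, "SMALL")
})
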