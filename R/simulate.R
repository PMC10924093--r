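# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic CKD cohort
#'
#' Bundles the generator parameters with their study-condition defaults:
#' a cohort of 2,000 samples and 2,000 SNPs in 10-SNP LD blocks
#' (within-block latent correlation 0.5), MAF drawn uniformly on
#' [0.05, 0.5], 20 causal SNPs with opposite-direction effects on the two
#' kidney-function markers, residual eGFR-BUN correlation 0.6 in
#' magnitude, and a 99% CKD case fraction (matching a mostly-case renal
#' cohort).
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param maf_range interval for effect-allele frequencies.
#' @param ld_block_size,ld_rho LD block length and within-block latent
#'   correlation.
#' @param n_causal number of causal SNPs.
#' @param effect_size per-causal-SNP effect on the latent phenotype scale.
#' @param direction_mode \code{"opposite"} (effects on eGFR and BUN have
#'   opposite signs), \code{"same"}, or \code{"mixed"}.
#' @param pheno_corr residual correlation between the two latent
#'   phenotypes.
#' @param case_fraction fraction of samples labelled CKD cases (assigned
#'   to the lowest-eGFR tail).
#' @param seed integer seed; every generator is a pure function of the
#'   spec and this seed.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples = 2000, n_snps = 2000,
                        maf_range = c(0.05, 0.5),
                        ld_block_size = 10, ld_rho = 0.5,
                        n_causal = 20, effect_size = 0.15,
                        direction_mode = c("opposite", "same", "mixed"),
                        pheno_corr = 0.6, case_fraction = 0.99,
                        seed = 1L) {
  direction_mode <- match.arg(direction_mode)
  stopifnot(n_samples >= 10, n_snps >= 1, n_causal <= n_snps,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            abs(pheno_corr) < 1, case_fraction >= 0, case_fraction <= 1)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_rho = ld_rho, n_causal = n_causal,
                 effect_size = effect_size, direction_mode = direction_mode,
                 pheno_corr = pheno_corr, case_fraction = case_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate genotypes with block LD under Hardy-Weinberg equilibrium
#'
#' Within each block of \code{ld_block_size} adjacent SNPs, latent
#' Gaussian vectors share an exchangeable correlation \code{ld_rho}
#' (Gaussian copula); each SNP's latent values are thresholded at the
#' Hardy-Weinberg genotype quantiles for its allele frequency, so
#' realised genotype counts are HWE-consistent by construction. Variants
#' are laid out on chromosome 1 at 10 kb spacing.
#'
#' @param spec a [cohort_spec()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples; m <- spec$n_snps
    af <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    rho <- spec$ld_rho
    d <- matrix(0L, n, m)
    block <- (seq_len(m) - 1L) %/% spec$ld_block_size
    for (b in unique(block)) {
      idx <- which(block == b)
      common <- stats::rnorm(n)
      z <- sqrt(rho) * common +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(idx)), n)
      for (j in seq_along(idx)) {
        f <- af[idx[j]]
        # P(dosage = 0) = (1-f)^2, P(<= 1) = (1-f)^2 + 2f(1-f)
        q0 <- stats::qnorm((1 - f)^2)
        q1 <- stats::qnorm((1 - f)^2 + 2 * f * (1 - f))
        d[, idx[j]] <- (z[, j] > q0) + (z[, j] > q1)
      }
    }
    variants <- data.frame(
      chr = "1", pos = 10000L * seq_len(m),
      rsid = paste0("rs", seq_len(m)),
      ref = "A", ea = "G", stringsAsFactors = FALSE
    )
    genotype_matrix(d, variants, samples = sprintf("S%04d", seq_len(n)))
  })
}

#' Simulate kidney-function phenotypes driven by sparse causal SNPs
#'
#' Causal SNPs (evenly spread over the panel) add \code{effect_size} per
#' effect allele to the latent eGFR score; under the default
#' \code{"opposite"} direction mode the same SNPs subtract from the
#' latent BUN score, so their effects on the two markers point in
#' opposite directions. Residual noise is bivariate normal with
#' correlation \code{pheno_corr} between the latents (the standardised
#' markers are oriented so that their shared non-genetic physiology
#' correlates positively). The latents are
#' back-transformed to plausible raw scales (eGFR in ml/min/1.73 m^2,
#' urea in mmol/L) so the standardisation code paths run on realistic
#' magnitudes, and case labels are assigned to the lowest-eGFR
#' \code{case_fraction}.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param spec the matching [cohort_spec()].
#' @return a \code{phenotype_matrix} (see [build_phenotype_matrix()]) with
#'   attributes \code{raw} (data.frame egfr, urea) and \code{truth}
#'   (causal indices and per-trait latent effects).
#' @export
simulate_phenotypes <- function(g, spec) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1L, {
    n <- length(g$samples); m <- ncol(g$dosage)
    causal <- if (spec$n_causal > 0)
      unique(round(seq(1, m, length.out = spec$n_causal))) else integer(0)
    beta_e <- rep(spec$effect_size, length(causal))
    beta_b <- switch(spec$direction_mode,
      opposite = -beta_e,
      same = beta_e,
      mixed = beta_e * rep_len(c(-1, 1), length(causal)))
    xs <- scale(g$dosage[, causal, drop = FALSE])
    rho <- spec$pheno_corr
    e1 <- stats::rnorm(n)
    e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
    lat_e <- as.vector(xs %*% beta_e) + e1
    lat_b <- as.vector(xs %*% beta_b) + e2
    lat_e <- as.vector(scale(lat_e)); lat_b <- as.vector(scale(lat_b))
    egfr <- 71 + 22 * lat_e                   # spans roughly 5-137
    urea <- 10^(0.9 + 0.25 * lat_b)           # roughly 1.4-45 mmol/L
    n_case <- round(spec$case_fraction * n)
    case <- as.integer(rank(egfr, ties.method = "first") <= n_case)
    y <- build_phenotype_matrix(egfr, urea, case, samples = g$samples)
    attr(y, "raw") <- data.frame(egfr = egfr, urea = urea)
    attr(y, "truth") <- list(causal = causal, beta_egfr = beta_e,
                             beta_bun = beta_b)
    y
  })
}

#' Per-SNP univariate summary statistics from an individual-level cohort
#'
#' Simple least-squares regression of each standardised phenotype on each
#' SNP dosage: slope, standard error, two-sided t p-value, sample size
#' and effect-allele frequency. Monomorphic SNPs are dropped with a
#' warning. The output emulates the shape of a public GWAS download.
#'
#' @param g a post-QC [genotype_matrix()].
#' @param y a \code{phenotype_matrix} aligned with \code{g}.
#' @return a multi-trait summary table (traits \code{egfr}, \code{bun})
#'   as produced by [combine_trait_stats()].
#' @export
simulate_summary_stats <- function(g, y) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(y, "phenotype_matrix"))
  d <- g$dosage
  n <- nrow(d)
  sx2 <- apply(d, 2, stats::var)
  mono <- sx2 == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped from summary statistics")
    d <- d[, !mono, drop = FALSE]
    sx2 <- sx2[!mono]
  }
  vars <- g$variants[!mono, , drop = FALSE]
  dc <- scale(d, center = TRUE, scale = FALSE)
  out <- vars
  out$af <- colMeans(d) / 2
  for (tr in c("egfr", "bun")) {
    yv <- as.vector(scale(y[[paste0(tr, "_std")]]))
    beta <- as.vector(crossprod(dc, yv)) / ((n - 1) * sx2)
    resid_ss <- sum(yv^2) - beta^2 * (n - 1) * sx2
    se <- sqrt(pmax(resid_ss, 0) / ((n - 2) * (n - 1) * sx2))
    tstat <- beta / se
    out[[paste0("beta_", tr)]] <- beta
    out[[paste0("se_", tr)]] <- se
    out[[paste0("n_", tr)]] <- n
    out[[paste0("p_", tr)]] <- 2 * stats::pt(abs(tstat), n - 2,
                                             lower.tail = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "traits") <- c("egfr", "bun")
  out
}

#' Simulate a paired GWAS/eQTL region for colocalisation testing
#'
#' Builds two summary-statistic regions over the same variant panel with
#' one causal SNP each: the same index in both when \code{shared}, two
#' distinct indices otherwise. Null SNPs carry z-scores ~ N(0,1); the
#' causal SNP's expected |z| is \code{causal_z}. Effects are on the
#' standardised scale with se = 1/sqrt(n).
#'
#' @param shared logical: one shared causal variant (H4-like truth) or
#'   distinct variants (H3-like truth).
#' @param n_snps region size (>= 10).
#' @param causal_z expected causal |z| (e.g. 12 for an unambiguous
#'   signal).
#' @param seed integer seed.
#' @param n nominal per-study sample size (default 10000).
#' @return list of two \code{region_stats} data.frames
#'   (\code{gwas}, \code{eqtl}) with attribute \code{truth}.
#' @export
simulate_eqtl_pair <- function(shared, n_snps, causal_z, seed, n = 10000) {
  if (n_snps < 10) stop("need at least 10 SNPs in the region")
  with_seed(seed, {
    af <- 0.3
    se <- 1 / sqrt(2 * af * (1 - af) * n)  # trait-standardised OLS scale
    vars <- data.frame(
      chr = "1", pos = 1000L * seq_len(n_snps),
      rsid = paste0("rs", seq_len(n_snps)),
      ref = "A", ea = "G", stringsAsFactors = FALSE
    )
    idx1 <- floor(n_snps / 2)
    idx2 <- if (shared) idx1 else max(1, floor(n_snps / 4))
    mk <- function(causal_idx) {
      z <- stats::rnorm(n_snps)
      z[causal_idx] <- z[causal_idx] + causal_z * sign(stats::runif(1) - 0.5)
      out <- vars
      out$beta <- z * se
      out$se <- se
      out$varbeta <- se^2
      out$n <- n
      out$af <- af
      class(out) <- c("region_stats", "data.frame")
      out
    }
    res <- list(gwas = mk(idx1), eqtl = mk(idx2))
    attr(res, "truth") <- list(shared = shared, idx_gwas = idx1,
                               idx_eqtl = idx2)
    res
  })
}

#' Simulate a log2 expression matrix with a planted DE fraction
#'
#' Gaussian log2-scale expression; a \code{de_fraction} of genes is
#' shifted by \code{true_lfc} in cases (alternating sign).
#'
#' @param n_genes,n_case,n_control matrix dimensions.
#' @param de_fraction fraction of genes differentially expressed.
#' @param true_lfc absolute log2 fold change of DE genes.
#' @param sigma per-gene expression SD.
#' @param seed integer seed.
#' @return list: \code{expr} (genes x samples), \code{groups} (1 = case),
#'   \code{truth} (logical DE indicator per gene).
#' @export
simulate_expression <- function(n_genes, n_case, n_control,
                                de_fraction = 0.1, true_lfc = 1.2,
                                sigma = 0.2, seed = 1L) {
  stopifnot(n_genes >= 2, n_case >= 2, n_control >= 2)
  with_seed(seed, {
    n <- n_case + n_control
    base <- stats::runif(n_genes, 4, 12)
    expr <- matrix(stats::rnorm(n_genes * n, mean = base, sd = sigma),
                   n_genes, n)
    n_de <- round(de_fraction * n_genes)
    de <- seq_len(n_genes) <= n_de
    if (n_de > 0) {
      shift <- true_lfc * rep_len(c(1, -1), n_de)
      expr[de, seq_len(n_case)] <- expr[de, seq_len(n_case)] + shift
    }
    rownames(expr) <- paste0("gene", seq_len(n_genes))
    colnames(expr) <- c(paste0("case", seq_len(n_case)),
                        paste0("ctrl", seq_len(n_control)))
    list(expr = expr, groups = rep(c(1L, 0L), c(n_case, n_control)),
         truth = de)
  })
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' GT-only records, one biallelic SNP per row; missing dosages become
#' \code{./.}. Heterozygotes are written \code{0/1} and homozygotes
#' \code{0/0} / \code{1/1}, so dosages round-trip exactly through
#' [read_genotypes_vcf()].
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  v <- g$variants
  body <- vapply(seq_len(nrow(v)), function(i) {
    d <- g$dosage[, i]
    gts <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chr[i], v$pos[i],
            ifelse(is.na(v$rsid[i]), ".", v$rsid[i]),
            v$ref[i], v$ea[i], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
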