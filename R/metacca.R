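#' Standardise a GWAS beta to a genotype-phenotype correlation
#'
#' Converts a univariate regression coefficient and its standard error to
#' the correlation between the (standardised) genotype and phenotype via
#' the t statistic: \eqn{t = \beta/se}, \eqn{r = t / \sqrt{t^2 + n - 2}}.
#' The sign of beta is preserved and no allele frequency is needed.
#'
#' @param beta effect size(s).
#' @param se standard error(s), strictly positive.
#' @param n per-SNP sample size(s), > 2.
#' @return correlation(s) in (-1, 1).
#' @export
standardize_betas <- function(beta, se, n) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(n <= 2)) stop("sample sizes must exceed 2")
  t <- beta / se
  t / sqrt(t^2 + n - 2)
}

#' Estimate the phenotypic correlation matrix from summary statistics
#'
#' The correlation of standardised effect columns across null SNPs
#' estimates the phenotypic correlation, because under the null the
#' per-SNP standardised effects of two traits are correlated exactly as
#' the traits themselves are. SNPs showing nominal association evidence
#' on any trait (p below \code{null_p_max}) are excluded first: effect
#' columns at genuinely associated SNPs (and their LD partners) reflect
#' the causal effect-direction structure rather than the phenotypic
#' correlation and otherwise bias the estimate.
#'
#' @param stats multi-trait table from [combine_trait_stats()] (columns
#'   \code{beta_<trait>}, \code{se_<trait>}, \code{n_<trait>}; p columns
#'   are recomputed from the t statistic when absent).
#' @param traits trait labels; default taken from the table's attribute.
#' @param null_p_max per-trait p-value below which a SNP is considered
#'   associated and excluded from the estimate (default 0.01; set to 0 to
#'   use every SNP).
#' @return object of class \code{pheno_corr}: list with \code{s_yy}
#'   (P x P, unit diagonal) and \code{n_snps_used}.
#' @export
estimate_pheno_corr <- function(stats, traits = attr(stats, "traits"),
                                null_p_max = 0.01) {
  if (is.null(traits)) stop("trait labels not found")
  if (nrow(stats) < 3)
    stop("need at least 3 SNPs to estimate phenotypic correlation")
  keep <- rep(TRUE, nrow(stats))
  if (null_p_max > 0) {
    for (tr in traits) {
      p <- stats[[paste0("p_", tr)]]
      if (is.null(p) || all(is.na(p))) {
        t <- stats[[paste0("beta_", tr)]] / stats[[paste0("se_", tr)]]
        p <- 2 * stats::pt(abs(t), stats[[paste0("n_", tr)]] - 2,
                           lower.tail = FALSE)
      }
      keep <- keep & !is.na(p) & p > null_p_max
    }
    if (sum(keep) < 3) keep <- rep(TRUE, nrow(stats))
  }
  m <- sum(keep)
  if (m < 1000)
    warning("phenotypic correlation estimated from only ", m,
            " SNPs; >= 1000 recommended")
  rxy <- sapply(traits, function(tr)
    standardize_betas(stats[[paste0("beta_", tr)]][keep],
                      stats[[paste0("se_", tr)]][keep],
                      stats[[paste0("n_", tr)]][keep]))
  s_yy <- stats::cor(rxy)
  diag(s_yy) <- 1
  dimnames(s_yy) <- list(traits, traits)
  structure(list(s_yy = s_yy, n_snps_used = m), class = "pheno_corr")
}

#' @export
#' @method print pheno_corr
print.pheno_corr <- function(x, ...) {
  cat("phenotypic correlation matrix (", x$n_snps_used, " SNPs):\n", sep = "")
  print(round(x$s_yy, 4))
  invisible(x)
}

#' Shrink a symmetric matrix to positive semidefiniteness
#'
#' Repeatedly multiplies all off-diagonal entries by \code{factor} until
#' the minimum eigenvalue reaches \code{min_eig}. The diagonal is never
#' touched, so a correlation matrix stays a correlation matrix.
#'
#' @param sigma symmetric matrix.
#' @param factor per-iteration off-diagonal multiplier in (0,1)
#'   (default 0.999).
#' @param min_eig target minimum eigenvalue (default 1e-12).
#' @param max_iter iteration cap (default 10000).
#' @return the shrunk matrix with attribute \code{iterations}.
#' @export
shrink_to_psd <- function(sigma, factor = 0.999, min_eig = 1e-12,
                          max_iter = 10000) {
  sigma <- as.matrix(sigma)
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("matrix is not symmetric")
  if (factor <= 0 || factor >= 1) stop("factor must be in (0,1)")
  it <- 0L
  while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < min_eig) {
    if (it >= max_iter)
      stop("shrink_to_psd did not converge in ", max_iter, " iterations")
    off <- sigma; diag(off) <- 0
    sigma <- sigma - off * (1 - factor)
    it <- it + 1L
  }
  attr(sigma, "iterations") <- it
  sigma
}

#' Validate and filter a summary-statistics table for metaCCA
#'
#' Drops rows with: a zero standard error on any trait; alleles outside
#' A/C/G/T; duplicated variant keys (all copies removed, since provenance
#' cannot be arbitrated); allele frequency below \code{af_min} or above
#' \code{1 - af_min} (rows with missing AF are kept, counted in the
#' report, and noted with a warning).
#'
#' @param stats single- or multi-trait summary table.
#' @param af_min allele-frequency bound (default 0.01).
#' @return list: \code{stats} (filtered), \code{report} (named counts of
#'   removed rows per cause plus retained).
#' @export
validate_summary_input <- function(stats, af_min = 0.01) {
  traits <- attr(stats, "traits")
  se_cols <- if (is.null(traits)) "se" else paste0("se_", traits)
  n0 <- nrow(stats)
  report <- c(se_zero = 0L, non_acgt = 0L, duplicate = 0L, af = 0L,
              af_missing = 0L)

  se_bad <- rowSums(sapply(se_cols, function(cl) stats[[cl]] == 0)) > 0
  se_bad[is.na(se_bad)] <- FALSE
  report["se_zero"] <- sum(se_bad)
  stats <- stats[!se_bad, , drop = FALSE]

  acgt <- c("A", "C", "G", "T")
  allele_bad <- !(stats$ref %in% acgt & stats$ea %in% acgt)
  report["non_acgt"] <- sum(allele_bad)
  stats <- stats[!allele_bad, , drop = FALSE]

  key <- variant_id(stats)
  dup <- key %in% key[duplicated(key)]
  report["duplicate"] <- sum(dup)
  stats <- stats[!dup, , drop = FALSE]

  af_na <- is.na(stats$af)
  report["af_missing"] <- sum(af_na)
  if (any(af_na))
    warning(sum(af_na), " row(s) with missing AF: frequency filter skipped for them")
  af_bad <- !af_na & (stats$af < af_min | stats$af > 1 - af_min)
  report["af"] <- sum(af_bad)
  stats <- stats[!af_bad, , drop = FALSE]

  rownames(stats) <- NULL
  attr(stats, "traits") <- traits
  if (nrow(stats) == 0) warning("no rows survived summary-statistics validation")
  list(stats = stats,
       report = c(report, retained = nrow(stats), input = n0))
}

#' Per-SNP canonical correlation from summary statistics (metaCCA)
#'
#' Reconstructs, for each SNP, the joint correlation matrix
#' \eqn{[[1, s^T], [s, S_{YY}]]} from the standardised per-trait effects
#' \eqn{s} and the phenotypic correlation matrix, shrinks it to positive
#' semidefiniteness if needed, and solves the single-SNP canonical
#' correlation \eqn{r_1^2 = s^T S_{YY}^{-1} s} with a Wilks' Lambda
#' p-value (g = 1). The per-SNP sample size is the minimum (or mean) of
#' the per-trait sizes.
#'
#' @param stats validated multi-trait table (see
#'   [validate_summary_input()]).
#' @param s_yy a \code{pheno_corr} object or P x P matrix.
#' @param n_mode \code{"min"} (default, conservative) or \code{"mean"}.
#' @param adjust multiplicity mode as in [cca_scan()].
#' @param shrink_factor,shrink_min_eig passed to [shrink_to_psd()].
#' @return a \code{cca_scan} object with \code{engine = "metacca"}; its
#'   results table carries the per-trait standardised effects as
#'   \code{rxy_<trait>} columns.
#' @export
metacca_scan <- function(stats, s_yy, n_mode = c("min", "mean"),
                         adjust = c("bonferroni_by_count", "fixed_genomewide"),
                         shrink_factor = 0.999, shrink_min_eig = 1e-12) {
  n_mode <- match.arg(n_mode)
  adjust <- match.arg(adjust)
  traits <- attr(stats, "traits")
  if (is.null(traits)) stop("stats must be a multi-trait table")
  syy <- if (inherits(s_yy, "pheno_corr")) s_yy$s_yy else as.matrix(s_yy)
  p_dim <- length(traits)
  stopifnot(nrow(syy) == p_dim)
  syy <- shrink_to_psd(syy, factor = shrink_factor, min_eig = shrink_min_eig)

  rxy <- sapply(traits, function(tr)
    standardize_betas(stats[[paste0("beta_", tr)]],
                      stats[[paste0("se_", tr)]],
                      stats[[paste0("n_", tr)]]))
  rxy <- matrix(rxy, ncol = p_dim)
  ns <- sapply(traits, function(tr) stats[[paste0("n_", tr)]])
  ns <- matrix(ns, ncol = p_dim)
  n_snp <- if (n_mode == "min") apply(ns, 1, min) else rowMeans(ns)

  syy_inv <- solve(syy)
  r2 <- rowSums((rxy %*% syy_inv) * rxy)
  # joint [[1, s'],[s, syy]] is PSD iff the Schur complement 1 - r2 >= 0;
  # only SNPs breaching that need the shrinkage loop
  fix <- which(r2 >= 1)
  for (i in fix) {
    joint <- rbind(c(1, rxy[i, ]), cbind(rxy[i, ], syy))
    joint <- shrink_to_psd(joint, factor = shrink_factor,
                           min_eig = shrink_min_eig)
    s <- joint[1, -1]
    r2[i] <- sum(s * solve(joint[-1, -1], s))
    if (r2[i] > 1 + 1e-8)
      stop("canonical correlation above 1 after shrinkage at SNP ",
           variant_id(stats[i, ]))
  }
  r1 <- sqrt(pmin(pmax(r2, 0), 1))

  m <- nrow(stats)
  lambda <- 1 - r1^2
  # g = 1 so Rao's t = 1; df2 varies per SNP through n
  df1 <- p_dim
  df2 <- n_snp - (1 + p_dim + 3) / 2 - p_dim / 2 + 1
  f_stat <- ifelse(lambda <= 0, Inf, (1 - lambda) / lambda * (df2 / df1))
  pval <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  p_adj <- if (adjust == "bonferroni_by_count") pmin(1, pval * m) else pval

  res <- data.frame(stats[c("chr", "pos", "rsid", "ref", "ea", "af")],
                    r1 = r1, lambda = lambda, F = f_stat,
                    df1 = df1, df2 = df2, p = pval, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  colnames(rxy) <- paste0("rxy_", traits)
  res <- cbind(res, as.data.frame(rxy))
  for (tr in traits) res[[paste0("beta_", tr)]] <- stats[[paste0("beta_", tr)]]
  rownames(res) <- NULL
  structure(list(results = res, n = stats::median(n_snp), p_dim = p_dim,
                 m = m, adjust = adjust, engine = "metacca",
                 s_yy = syy, traits = traits),
            class = "cca_scan")
}
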