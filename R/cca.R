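#' Sample covariance blocks for canonical correlation
#'
#' @param x numeric matrix n x G (genotype block).
#' @param y numeric matrix n x P (phenotype block).
#' @return list of class \code{covariance_blocks}: \code{s_xx}, \code{s_xy},
#'   \code{s_yy} (n-1 denominator) and \code{n}.
#' @export
covariance_blocks <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of rows")
  if (n <= max(ncol(x), ncol(y)) + 2)
    stop("too few samples for the requested dimensions")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  cx <- which(apply(x, 2, stats::sd) == 0)
  if (length(cx)) stop("constant column in x: ",
                       paste(colnames(x)[cx] %||% cx, collapse = ", "))
  cy <- which(apply(y, 2, stats::sd) == 0)
  if (length(cy)) stop("constant column in y: ",
                       paste(colnames(y)[cy] %||% cy, collapse = ", "))
  structure(list(s_xx = stats::cov(x), s_xy = stats::cov(x, y),
                 s_yy = stats::cov(y), n = n),
            class = "covariance_blocks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric inverse square root with an eigenvalue floor
inv_sqrt_sym <- function(s, floor = 1e-10) {
  s <- as.matrix(s)
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  if (any(e$values < floor))
    stop("covariance block is numerically singular (eigenvalue < ", floor,
         "); remove collinear columns or add a ridge")
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
}

#' Canonical correlations from covariance blocks
#'
#' Whitens the cross-covariance, \eqn{K = \Sigma_{XX}^{-1/2} \Sigma_{XY}
#' \Sigma_{YY}^{-1/2}}, and takes its singular value decomposition. The
#' singular values (clipped to [0,1]) are the canonical correlations; the
#' canonical weight vectors are the whitened singular vectors. The sign of
#' each weight pair is fixed by making the first non-zero entry of the X
#' weight positive.
#'
#' @param blocks a \code{covariance_blocks} object.
#' @return list with \code{r} (descending canonical correlations),
#'   \code{weights_a} (G x k), \code{weights_b} (P x k).
#' @export
canonical_correlations <- function(blocks) {
  sxx_i <- inv_sqrt_sym(blocks$s_xx)
  syy_i <- inv_sqrt_sym(blocks$s_yy)
  k <- sxx_i %*% blocks$s_xy %*% syy_i
  sv <- svd(k)
  r <- pmin(pmax(sv$d, 0), 1)
  a <- sxx_i %*% sv$u
  b <- syy_i %*% sv$v
  for (j in seq_along(r)) {
    nz <- which(abs(a[, j]) > 1e-12)[1]
    if (!is.na(nz) && a[nz, j] < 0) { a[, j] <- -a[, j]; b[, j] <- -b[, j] }
  }
  list(r = r, weights_a = a, weights_b = b)
}

#' Wilks' Lambda test of the joint null of zero canonical correlation
#'
#' \eqn{\Lambda = \prod_i (1 - r_i^2)} with Rao's F approximation:
#' \eqn{t = \sqrt{(g^2p^2-4)/(g^2+p^2-5)}} when \eqn{gp > 2}, else 1;
#' \eqn{w = n - (g+p+3)/2}; \eqn{df_1 = gp}; \eqn{df_2 = wt - gp/2 + 1};
#' \eqn{F = \frac{1-\Lambda^{1/t}}{\Lambda^{1/t}} \cdot \frac{df_2}{df_1}}.
#' For g = 1 the approximation is exact and equals the overall F test of
#' regressing the single X column on the Y block.
#'
#' @param r canonical correlations.
#' @param n sample size.
#' @param g,p dimensions of the X and Y blocks.
#' @return list: wilks_lambda, f_stat, df1, df2, p.
#' @export
wilks_lambda_test <- function(r, n, g, p) {
  if (n <= g + p + 1) stop("sample size too small for Wilks test")
  lambda <- prod(1 - r^2)
  t <- if (g * p > 2) sqrt((g^2 * p^2 - 4) / (g^2 + p^2 - 5)) else 1
  w <- n - (g + p + 3) / 2
  df1 <- g * p
  df2 <- w * t - g * p / 2 + 1
  l1t <- lambda^(1 / t)
  f_stat <- if (lambda >= 1) 0 else ((1 - l1t) / l1t) * (df2 / df1)
  pval <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(wilks_lambda = lambda, f_stat = f_stat, df1 = df1, df2 = df2, p = pval)
}

#' Per-SNP canonical correlation scan (individual-level data)
#'
#' For each variant, computes the canonical correlation between the single
#' dosage column (G = 1) and the phenotype block (eGFR and BUN; P = 2, or
#' 3 when the case indicator is included), with a Wilks' Lambda p-value.
#' With G = 1 the first canonical correlation equals the multiple
#' correlation of the SNP on the Y block, so the scan is computed in one
#' vectorised pass.
#'
#' @param g a post-QC [genotype_matrix()] (no missing dosages).
#' @param y a \code{phenotype_matrix} from [build_phenotype_matrix()], or a
#'   plain numeric matrix aligned with \code{g$samples}.
#' @param adjust multiplicity mode: \code{"bonferroni_by_count"}
#'   (p_adj = min(1, p*m), judged at alpha) or \code{"fixed_genomewide"}
#'   (p judged at 5e-8; p_adj = p).
#' @return object of class \code{cca_scan}: list with \code{results} (one
#'   row per SNP: chr, pos, rsid, ref, ea, r1, lambda, F, df1, df2, p,
#'   p_adj), \code{n}, \code{p_dim}, \code{m}, \code{adjust},
#'   \code{engine = "cca"}.
#' @export
cca_scan <- function(g, y, adjust = c("bonferroni_by_count", "fixed_genomewide")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(g, "genotype_matrix"))
  ymat <- if (inherits(y, "phenotype_matrix")) pheno_y_block(y) else as.matrix(y)
  if (nrow(ymat) != length(g$samples))
    stop("sample mismatch between genotype and phenotype matrices")
  if (anyNA(g$dosage))
    stop("genotype matrix contains missing dosages; run filter_variants_qc first")
  d <- g$dosage
  n <- nrow(d); m <- ncol(d); p_dim <- ncol(ymat)
  yc <- scale(ymat, center = TRUE, scale = FALSE)
  syy <- crossprod(yc) / (n - 1)
  syy_inv <- solve(syy)
  dc <- scale(d, center = TRUE, scale = FALSE)
  sx <- colSums(dc^2) / (n - 1)
  if (any(sx == 0)) stop("monomorphic variant in scan: ",
                         colnames(d)[which(sx == 0)[1]])
  sxy <- crossprod(dc, yc) / (n - 1)          # m x p
  r2 <- rowSums((sxy %*% syy_inv) * sxy) / sx
  r1 <- sqrt(pmin(pmax(r2, 0), 1))
  wt <- wilks_lambda_test(0, n, 1, p_dim)      # df are SNP-independent
  lambda <- 1 - r1^2
  f_stat <- ifelse(lambda <= 0, Inf, (1 - lambda) / lambda * (wt$df2 / wt$df1))
  pval <- stats::pf(f_stat, wt$df1, wt$df2, lower.tail = FALSE)
  p_adj <- if (adjust == "bonferroni_by_count") pmin(1, pval * m) else pval
  res <- data.frame(g$variants,
                    r1 = r1, lambda = lambda, F = f_stat,
                    df1 = wt$df1, df2 = wt$df2, p = pval, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(results = res, n = n, p_dim = p_dim, m = m,
                 adjust = adjust, engine = "cca"),
            class = "cca_scan")
}

#' @export
#' @method print cca_scan
print.cca_scan <- function(x, ...) {
  cat(sprintf("%s scan: %d SNPs, n = %d, %d phenotype(s), adjust = %s\n",
              x$engine, x$m, x$n, x$p_dim, x$adjust))
  cat("  min p:", format(min(x$results$p), digits = 4), "\n")
  invisible(x)
}

#' @export
#' @method summary cca_scan
summary.cca_scan <- function(object, alpha = 0.05, ...) {
  r <- object$results
  thr <- if (object$adjust == "fixed_genomewide") 5e-8 else alpha / object$m
  sig <- sum(r$p < thr)
  cat(sprintf("%s scan of %d SNPs (n = %d)\n", object$engine, object$m, object$n))
  cat(sprintf("  significance threshold: p < %.3g (%s)\n", thr, object$adjust))
  cat(sprintf("  significant SNPs: %d (%.2f%%)\n", sig, 100 * sig / object$m))
  cat(sprintf("  r1 range: %.4f - %.4f\n", min(r$r1), max(r$r1)))
  invisible(list(threshold = thr, n_significant = sig))
}

#' Manhattan-style plot of a scan
#' @param x a \code{cca_scan}.
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot cca_scan
plot.cca_scan <- function(x, ...) {
  r <- x$results
  ord <- order(match(r$chr, AUTOSOMES), r$pos)
  r <- r[ord, ]
  col <- c("grey30", "steelblue")[1 + (match(r$chr, AUTOSOMES) %% 2)]
  graphics::plot(seq_len(nrow(r)), -log10(r$p), pch = 20, col = col,
                 xlab = "SNP (genome order)", ylab = "-log10 p", ...)
  graphics::abline(h = -log10(5e-8), lty = 2)
  invisible(x)
}

#' Minimal detectable canonical correlation (power analysis)
#'
#' Fisher-z approximation to the smallest correlation detectable at the
#' given significance level and power:
#' \eqn{r = \tanh((z_{1-\alpha} + z_{power}) / \sqrt{n - 3})}
#' (one-sided by default; two-sided uses \eqn{z_{1-\alpha/2}}).
#'
#' @param n sample size (> 3).
#' @param alpha significance level (default the genome-wide 5e-8).
#' @param power target power (default 0.80).
#' @param sided \code{"one"} or \code{"two"}.
#' @return the minimal detectable correlation.
#' @export
min_detectable_r <- function(n, alpha = 5e-8, power = 0.80,
                             sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (any(n <= 3)) stop("n must exceed 3")
  if (alpha <= 0 || power <= alpha || power >= 1)
    stop("require 0 < alpha < power < 1")
  za <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  zb <- stats::qnorm(power)
  tanh((za + zb) / sqrt(n - 3))
}
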