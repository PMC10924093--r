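#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values are \eqn{p_{(i)} m / i} with a cumulative minimum
#' enforced from the largest rank down, capped at 1.
#'
#' @param pvalues p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  ord <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(pvalues[ord] * m / (m:1)))
  adj[order(ord)]
}

#' Differential gene expression between CKD cases and controls
#'
#' Per gene, a Welch two-sample t test on log2 expression; the fold
#' change is the case-minus-control mean difference on the log2 scale.
#' A gene passes when |log2FC| >= \code{lfc_min} and the BH-adjusted
#' p-value is below \code{fdr}.
#'
#' @param expr genes x samples matrix of log2 expression values.
#' @param groups per-sample labels, 1/"case" for CKD, 0/"control".
#' @param lfc_min absolute log2 fold-change gate (default 1, i.e. a
#'   two-fold change).
#' @param fdr BH-adjusted significance gate (default 0.05).
#' @return data.frame per gene: log2fc, p, p_adj, passes.
#' @export
differential_expression <- function(expr, groups, lfc_min = 1, fdr = 0.05) {
  expr <- as.matrix(expr)
  case <- groups %in% c(1, "1", "case")
  ctrl <- groups %in% c(0, "0", "control")
  if (!all(case | ctrl)) stop("groups must be case/control (1/0)")
  if (sum(case) < 2 || sum(ctrl) < 2)
    stop("need at least two samples per group")
  xc <- expr[, case, drop = FALSE]; xk <- expr[, ctrl, drop = FALSE]
  n1 <- ncol(xc); n2 <- ncol(xk)
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  v1 <- apply(xc, 1, stats::var); v2 <- apply(xk, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  log2fc <- m1 - m2
  data.frame(
    gene = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
    log2fc = log2fc, p = p, p_adj = p_adj,
    passes = abs(log2fc) >= lfc_min & p_adj < fdr,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Effect-allele frequency of a SNP in a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param snp variant key (chr:pos:ref:ea string, or a one-row data.frame
#'   with those columns).
#' @param subgroup optional sample identifiers restricting the cohort
#'   (e.g. a CKD diagnostic subgroup).
#' @return list: \code{af} (effect-allele frequency), \code{allele_number}
#'   (2 x samples used).
#' @export
allele_freq <- function(g, snp, subgroup = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  id <- if (is.character(snp)) snp else variant_id(snp)
  if (!id %in% colnames(g$dosage)) stop("SNP not in genotype matrix: ", id)
  d <- g$dosage[, id]
  if (!is.null(subgroup)) {
    idx <- match(subgroup, g$samples)
    if (anyNA(idx)) stop("unknown sample(s) in subgroup")
    d <- d[idx]
  }
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("empty subgroup")
  list(af = sum(d) / (2 * length(d)), allele_number = 2L * length(d))
}

#' Chi-square test with Yates' continuity correction (2 x 2)
#'
#' \eqn{\chi^2 = \sum (\max(|O - E| - 0.5, 0))^2 / E} on 1 degree of
#' freedom; cells with |O - E| < 0.5 contribute zero.
#'
#' @param table2x2 2 x 2 matrix of counts.
#' @return list: statistic, p.
#' @export
yates_chi_square <- function(table2x2) {
  tab <- as.matrix(table2x2)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Compare a cohort allele frequency against a reference population
#'
#' Builds the 2 x 2 allele-count table (effect/other allele x
#' cohort/reference), shortlists SNPs whose absolute frequency difference
#' is at least \code{shortlist_diff} (the test is only run for
#' shortlisted SNPs), and flags as significant those with a difference
#' above \code{report_diff} and a Yates-corrected chi-square p < 0.05.
#'
#' @param cohort list or vector with \code{af} and \code{allele_number}
#'   (as returned by [allele_freq()]).
#' @param reference same shape, from the reference population (e.g.
#'   gnomAD non-Finnish European af/an fields).
#' @param shortlist_diff frequency-difference gate for testing
#'   (default 0.10).
#' @param report_diff frequency-difference gate for reporting
#'   significance (default 0.15).
#' @return object of class \code{af_comparison}: af_diff, shortlisted,
#'   chi2_yates, p, significant.
#' @export
af_comparison <- function(cohort, reference, shortlist_diff = 0.10,
                          report_diff = 0.15) {
  caf <- cohort[["af"]]; can <- cohort[["allele_number"]]
  raf <- reference[["af"]]; ran <- reference[["allele_number"]]
  if (can <= 0 || ran <= 0) stop("allele numbers must be positive")
  af_diff <- caf - raf
  # comparisons against the gates tolerate float representation noise
  eps <- 1e-12
  shortlisted <- abs(af_diff) >= shortlist_diff - eps
  chi2 <- NA_real_; p <- NA_real_
  if (shortlisted) {
    tab <- rbind(
      cohort = c(effect = round(caf * can), other = round((1 - caf) * can)),
      reference = c(effect = round(raf * ran), other = round((1 - raf) * ran))
    )
    yt <- yates_chi_square(tab)
    chi2 <- yt$statistic; p <- yt$p
  }
  structure(list(af_diff = af_diff, shortlisted = shortlisted,
                 chi2_yates = chi2, p = p,
                 significant = isTRUE(shortlisted && !is.na(p) &&
                                      abs(af_diff) > report_diff + eps &&
                                      p < 0.05)),
            class = "af_comparison")
}

#' @export
#' @method print af_comparison
print.af_comparison <- function(x, ...) {
  cat(sprintf("allele-frequency difference: %+.3f (shortlisted: %s)\n",
              x$af_diff, x$shortlisted))
  if (x$shortlisted)
    cat(sprintf("  Yates chi-square = %.3f, p = %.3g, significant: %s\n",
                x$chi2_yates, x$p, x$significant))
  invisible(x)
}
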