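#' Extract the summary statistics of a region around a lead SNP
#'
#' Keeps SNPs on the lead's chromosome with position within
#' \code{window_bp} of the lead (boundary inclusive).
#'
#' @param lead a one-row data.frame or list with chr and pos (and
#'   optionally ref/ea); must be present in \code{stats}.
#' @param stats single-trait summary table with beta and se columns.
#' @param window_bp half-window in base pairs (default 200000).
#' @return a \code{region_stats} data.frame: chr, pos, rsid, ref, ea,
#'   beta, varbeta (= se^2), n, af.
#' @export
extract_region <- function(lead, stats, window_bp = 200000) {
  hit <- stats$chr == lead$chr & stats$pos == lead$pos
  if (!any(hit)) stop("lead SNP ", lead$chr, ":", lead$pos,
                      " not found in the summary table")
  keep <- stats$chr == lead$chr & abs(stats$pos - lead$pos) <= window_bp
  out <- stats[keep, , drop = FALSE]
  out$varbeta <- out$se^2
  if (any(out$varbeta <= 0)) stop("non-positive variance in region")
  rownames(out) <- NULL
  if (nrow(out) == 1)
    warning("region contains only the lead SNP; colocalisation is under-powered")
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Wakefield approximate log Bayes factor
#'
#' For effect \eqn{\beta} with variance \eqn{V} and prior effect SD
#' \eqn{W^{1/2}}: with \eqn{z = \beta/\sqrt{V}} and \eqn{r = W/(W+V)},
#' \eqn{\log ABF = \tfrac12 \log(1-r) + \tfrac12 z^2 r}.
#'
#' @param beta effect estimate(s).
#' @param varbeta variance(s) of the estimate, > 0.
#' @param prior_sd prior standard deviation of the true effect
#'   (default 0.15, the quantitative-trait convention).
#' @return log Bayes factor(s) in favour of a non-zero effect.
#' @export
wakefield_log_abf <- function(beta, varbeta, prior_sd = 0.15) {
  if (any(varbeta <= 0)) stop("varbeta must be positive")
  w <- prior_sd^2
  z2 <- beta^2 / varbeta
  r <- w / (w + varbeta)
  0.5 * log(1 - r) + 0.5 * z2 * r
}

# Trait standard deviation from summary statistics: for a quantitative
# trait, var(beta_hat) ~ sdY^2 / (2 f (1-f) n), so sdY^2 is recovered as
# the mean of varbeta * 2 f (1-f) n over the region. Falls back to 1
# (betas treated as trait-standardised) when AF or n is unavailable.
# Scaling all betas and sqrt(varbeta) of a region by a constant scales
# the estimate by the same constant, which keeps the posterior
# probabilities scale-free.
estimate_sdy <- function(region) {
  if (is.null(region$af) || is.null(region$n) ||
      anyNA(region$af) || anyNA(region$n)) return(1)
  sd2 <- mean(region$varbeta * 2 * region$af * (1 - region$af) * region$n)
  if (!is.finite(sd2) || sd2 <= 0) return(1)
  sqrt(sd2)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Colocalisation of two association signals by approximate Bayes factors
#'
#' Enumerates the five single-causal-variant hypotheses (H0: no
#' association; H1/H2: association with one trait only; H3: both traits,
#' distinct variants; H4: both traits, one shared variant) with per-SNP
#' Wakefield Bayes factors and the stated prior probabilities, and
#' returns normalised posterior probabilities. The two regions are
#' intersected on variant keys first; allele-swapped matches are accepted
#' (betas are sign-irrelevant here since only z^2 enters the ABF) except
#' at strand-ambiguous A/T and C/G sites. All accumulation is in log
#' space.
#'
#' @param region1,region2 \code{region_stats} tables (e.g. the CCA-driving
#'   trait's univariate statistics and an eQTL region).
#' @param p1,p2 prior probability that a random SNP is associated with
#'   trait 1 / trait 2 only (defaults 1e-4).
#' @param p12 prior probability that a random SNP is associated with both
#'   (default 1e-6).
#' @param pp4_threshold posterior probability above which the region is
#'   flagged colocalised (default 0.8).
#' @param prior_sd prior effect SD on the trait-standardised scale
#'   (default 0.15); each region's trait SD is estimated from its
#'   varbeta, AF and n columns (treated as 1 when those are absent), so
#'   the posteriors depend on the per-SNP z-scores and not on the unit in
#'   which effects are expressed.
#' @return object of class \code{coloc_result}: \code{pp} (named pp0..pp4,
#'   summing to 1), \code{n_snps_tested}, \code{colocalised}, priors.
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-6,
                      pp4_threshold = 0.8, prior_sd = 0.15) {
  k1 <- variant_id(region1)
  k2 <- variant_id(region2)
  swap2 <- paste(region2$chr, region2$pos, region2$ea, region2$ref, sep = ":")
  direct <- match(k1, k2)
  swapped <- match(k1, swap2)
  swapped[is_strand_ambiguous(region1$ref, region1$ea)] <- NA
  idx2 <- ifelse(!is.na(direct), direct, swapped)
  keep <- !is.na(idx2)
  if (!any(keep)) stop("no shared SNPs between the two regions")
  r1 <- region1[keep, , drop = FALSE]
  r2 <- region2[idx2[keep], , drop = FALSE]

  l1 <- wakefield_log_abf(r1$beta, r1$varbeta, prior_sd * estimate_sdy(r1))
  l2 <- wakefield_log_abf(r2$beta, r2$varbeta, prior_sd * estimate_sdy(r2))

  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse_both <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + lse1,
    h2 = log(p2) + lse2,
    h3 = log(p1) + log(p2) + logdiffexp(lse1 + lse2, lse_both),
    h4 = log(p12) + lse_both
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, n_snps_tested = sum(keep),
                 colocalised = unname(pp["pp4"] > pp4_threshold),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = prior_sd),
            class = "coloc_result")
}

#' @export
#' @method print coloc_result
print.coloc_result <- function(x, ...) {
  cat("colocalisation over", x$n_snps_tested, "shared SNPs\n")
  print(round(x$pp, 4))
  cat(if (x$colocalised) "  -> colocalised (PP4 above threshold)\n"
      else "  -> not colocalised\n")
  invisible(x)
}
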