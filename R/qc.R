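#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on the genotype counts of one
#' biallelic variant: given the total sample size and the minor-allele
#' count, the p-value is the sum of the conditional probabilities of all
#' heterozygote counts (same parity, same allele totals) whose probability
#' does not exceed that of the observed count.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("all genotype counts are zero")
  n_alt <- 2 * n_hom_alt + n_het   # rarer-allele bookkeeping is symmetric
  n_ref <- 2 * n_hom_ref + n_het
  n_minor <- min(n_ref, n_alt)
  if (n_minor == 0) return(1)      # monomorphic: single attainable table
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, n_minor) up to a shared constant
  logp <- lgamma(n + 1) -
    lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) -
    lgamma((2 * n - n_minor - hets) / 2 + 1) +
    hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Genotype-level variant quality control
#'
#' Applies, in order: non-autosome removal, minor-allele-frequency filter,
#' missingness filter (threshold is inclusive: call-rate gaps at or above
#' \code{max_missing} are removed), exact Hardy-Weinberg filter, and
#' finally removal of any variant still carrying a missing cell (CCA
#' cannot tolerate missing data). Allele frequencies and genotype counts
#' are computed over non-missing cells.
#'
#' @param g a [genotype_matrix()] possibly containing NA dosages.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param max_missing missingness fraction at or above which a variant is
#'   removed (default 0.015).
#' @param hwe_alpha exact-test p-value below which a variant is removed
#'   (default 1e-5).
#' @param drop_any_missing drop variants with any residual missing cell
#'   (default TRUE).
#' @return list with elements \code{genotypes} (filtered matrix) and
#'   \code{report} (a \code{qc_report}).
#' @export
filter_variants_qc <- function(g, maf_min = 0.01, max_missing = 0.015,
                               hwe_alpha = 1e-5, drop_any_missing = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  m0 <- ncol(d)
  removed <- c(non_autosome = 0L, maf = 0L, missingness = 0L, hwe = 0L,
               any_missing = 0L)
  keep <- g$variants$chr %in% AUTOSOMES
  removed["non_autosome"] <- sum(!keep)
  d <- d[, keep, drop = FALSE]; vars <- g$variants[keep, , drop = FALSE]

  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= maf_min
  removed["maf"] <- sum(!keep)
  d <- d[, keep, drop = FALSE]; vars <- vars[keep, , drop = FALSE]

  miss <- colMeans(is.na(d))
  keep <- miss < max_missing
  removed["missingness"] <- sum(!keep)
  d <- d[, keep, drop = FALSE]; vars <- vars[keep, , drop = FALSE]

  if (ncol(d) > 0) {
    hwe_p <- apply(d, 2, function(x) {
      x <- x[!is.na(x)]
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    keep <- hwe_p >= hwe_alpha
  } else keep <- logical(0)
  removed["hwe"] <- sum(!keep)
  d <- d[, keep, drop = FALSE]; vars <- vars[keep, , drop = FALSE]

  if (drop_any_missing) {
    keep <- colSums(is.na(d)) == 0
    removed["any_missing"] <- sum(!keep)
    d <- d[, keep, drop = FALSE]; vars <- vars[keep, , drop = FALSE]
  }

  report <- structure(list(variants_in = m0, variants_removed = removed,
                           variants_retained = ncol(d),
                           empty = ncol(d) == 0L),
                      class = "qc_report")
  if (ncol(d) == 0L)
    warning("no variants survived quality control")
  rownames(vars) <- NULL
  list(genotypes = genotype_matrix(d, vars, samples = g$samples),
       report = report)
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("variant QC:", x$variants_in, "in ->", x$variants_retained, "retained\n")
  for (nm in names(x$variants_removed))
    cat(sprintf("  removed by %-12s %d\n", paste0(nm, ":"),
                x$variants_removed[[nm]]))
  invisible(x)
}

#' Radius-based ancestry filter in principal-component space
#'
#' Retains samples whose Euclidean distance in PC1-PC2 from the centre of
#' a reference panel is at most \code{scale} times the maximum reference
#' distance from that centre.
#'
#' @param sample_pcs numeric matrix (samples x 2) with rownames as ids.
#' @param reference_pcs numeric matrix (reference samples x 2).
#' @param scale radius multiplier (> 0); 2 reproduces the choice that
#'   keeps all European-ancestry reference samples inside the radius.
#' @return identifiers (rownames, else indices) of retained samples.
#' @export
ancestry_filter <- function(sample_pcs, reference_pcs, scale = 2) {
  if (scale <= 0) stop("scale must be positive")
  sample_pcs <- as.matrix(sample_pcs); reference_pcs <- as.matrix(reference_pcs)
  if (ncol(sample_pcs) != 2 || ncol(reference_pcs) != 2)
    stop("coordinates must be two-dimensional (PC1, PC2)")
  if (nrow(reference_pcs) < 1) stop("need at least one reference sample")
  centre <- colMeans(reference_pcs)
  ref_d <- sqrt(rowSums(sweep(reference_pcs, 2, centre)^2))
  radius <- scale * max(ref_d)
  d <- sqrt(rowSums(sweep(sample_pcs, 2, centre)^2))
  ids <- rownames(sample_pcs)
  if (is.null(ids)) ids <- seq_len(nrow(sample_pcs))
  ids[d <= radius]
}

#' Standardise serum urea as log-Z BUN
#'
#' Urea (mmol/L) is converted to blood urea nitrogen by dividing by a
#' fixed factor, log10-transformed, then z-scored (mean 0, SD 1 with the
#' n-1 denominator).
#'
#' @param urea positive serum urea values (mmol/L).
#' @param urea_to_bun_divisor conversion factor (default 2.14, the
#'   molar-mass ratio of urea to its two nitrogen atoms).
#' @return standardised BUN values.
#' @export
transform_bun <- function(urea, urea_to_bun_divisor = 2.14) {
  if (any(urea <= 0)) stop("urea values must be positive")
  if (length(unique(urea)) < 2) stop("urea values are constant (zero variance)")
  x <- log10(urea / urea_to_bun_divisor)
  (x - mean(x)) / stats::sd(x)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their (average-tied) ranks
#' using the Blom offset: \eqn{\Phi^{-1}((r - c)/(n + 1 - 2c))}.
#'
#' @param values numeric vector, length >= 2.
#' @param offset rank offset c (default 0.375, Blom).
#' @return transformed values, strictly monotone in the input except for
#'   ties, which share the quantile of their average rank.
#' @export
rank_inverse_normal <- function(values, offset = 0.375) {
  n <- length(values)
  if (n < 2) stop("need at least two values")
  if (length(unique(values)) < 2) stop("values are constant (zero variance)")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n + 1 - 2 * offset))
}

#' Assemble the phenotype block for canonical correlation
#'
#' eGFR is standardised by [rank_inverse_normal()], urea by
#' [transform_bun()]; the CKD case/control status is carried as a binary
#' indicator and optionally appended to the Y block as a third column.
#' The caller is responsible for supplying eGFR and urea measured on the
#' same date per sample.
#'
#' @param egfr eGFR values (ml/min/1.73 m^2).
#' @param urea serum urea values (mmol/L).
#' @param case_flags binary case indicator (1 = CKD case).
#' @param include_status_in_y append the indicator to Y (default FALSE,
#'   i.e. Y is the two kidney-function markers only).
#' @param samples optional sample identifiers.
#' @param urea_to_bun_divisor passed to [transform_bun()].
#' @return object of class \code{phenotype_matrix}: data.frame with
#'   columns sample, egfr_std, bun_std, case; attribute
#'   \code{include_status_in_y} controls the Y block returned by
#'   [pheno_y_block()].
#' @export
build_phenotype_matrix <- function(egfr, urea, case_flags,
                                   include_status_in_y = FALSE,
                                   samples = NULL,
                                   urea_to_bun_divisor = 2.14) {
  n <- length(egfr)
  if (length(urea) != n || length(case_flags) != n)
    stop("egfr, urea and case_flags must have equal length")
  if (!all(case_flags %in% c(0, 1))) stop("case_flags must be 0/1")
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  out <- data.frame(
    sample = samples,
    egfr_std = rank_inverse_normal(egfr),
    bun_std = transform_bun(urea, urea_to_bun_divisor),
    case = as.integer(case_flags),
    stringsAsFactors = FALSE
  )
  attr(out, "include_status_in_y") <- include_status_in_y
  class(out) <- c("phenotype_matrix", "data.frame")
  out
}

#' Extract the numeric Y block from a phenotype matrix
#' @param y a \code{phenotype_matrix}.
#' @return numeric matrix with 2 columns (eGFR, BUN) or 3 when the case
#'   indicator is included.
#' @export
pheno_y_block <- function(y) {
  stopifnot(inherits(y, "phenotype_matrix"))
  cols <- c("egfr_std", "bun_std")
  if (isTRUE(attr(y, "include_status_in_y"))) cols <- c(cols, "case")
  as.matrix(as.data.frame(y)[cols])
}
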