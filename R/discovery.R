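# accept either a cca_scan object or its results data.frame
scan_results <- function(x) {
  if (inherits(x, "cca_scan")) list(df = x$results, m = x$m)
  else list(df = as.data.frame(x), m = nrow(x))
}

#' Filter scan results for significance
#'
#' \code{bonferroni_by_count} keeps SNPs with p < alpha/m (m = number of
#' SNPs scanned); \code{fixed_genomewide} keeps p < 5e-8 regardless of m.
#'
#' @param results a \code{cca_scan} or results data.frame with a
#'   \code{p} column.
#' @param mode \code{"bonferroni_by_count"} or \code{"fixed_genomewide"}.
#' @param alpha family-wise level for the Bonferroni mode (default 0.05).
#' @return the significant subset of the results data.frame.
#' @export
significance_filter <- function(results,
                                mode = c("bonferroni_by_count", "fixed_genomewide"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  sr <- scan_results(results)
  if (nrow(sr$df) == 0) stop("empty results table")
  thr <- if (mode == "bonferroni_by_count") alpha / sr$m else 5e-8
  out <- sr$df[sr$df$p < thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Keep SNPs whose eGFR and BUN effects point in opposite directions
#'
#' A SNP is biologically compatible with kidney function when its effect
#' raises one marker and lowers the other (higher BUN and lower eGFR both
#' indicate worse function). Rows are retained when
#' \code{beta_egfr * beta_bun < 0}; a zero effect on either trait fails
#' the strict opposite-direction requirement and is excluded.
#'
#' @param stats data.frame containing the two effect columns.
#' @param beta_cols names of the two effect columns
#'   (default \code{c("beta_egfr", "beta_bun")}).
#' @return the retained subset.
#' @export
opposite_direction_filter <- function(stats,
                                      beta_cols = c("beta_egfr", "beta_bun")) {
  if (!all(beta_cols %in% names(stats)))
    stop("effect columns not found: ", paste(beta_cols, collapse = ", "))
  b1 <- stats[[beta_cols[1]]]; b2 <- stats[[beta_cols[2]]]
  keep <- !is.na(b1) & !is.na(b2) & (b1 * b2 < 0)
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_strand_ambiguous <- function(ref, ea) {
  (ref == "A" & ea == "T") | (ref == "T" & ea == "A") |
  (ref == "C" & ea == "G") | (ref == "G" & ea == "C")
}

#' Harmonise two summary-statistics tables on variant keys
#'
#' Joins rows with matching (chr, pos, ref, ea). When \code{allow_swap},
#' rows whose alleles are recorded in the opposite orientation
#' (ref/ea swapped) are also joined, with the second table's betas
#' sign-flipped and its allele frequency complemented; A/T and C/G
#' strand-ambiguous sites are never matched via swap because the flip
#' cannot be distinguished from a strand error.
#'
#' @param a,b summary tables (single- or multi-trait); columns of \code{b}
#'   get suffix \code{_b} in the output.
#' @param allow_swap permit allele-swapped matches (default TRUE).
#' @return list: \code{matched} (joined rows), \code{n_swapped},
#'   \code{unmatched_a}, \code{unmatched_b} (row indices).
#' @export
harmonize_across_datasets <- function(a, b, allow_swap = TRUE) {
  key_a <- variant_id(a)
  key_b <- variant_id(b)
  swap_b <- paste(b$chr, b$pos, b$ea, b$ref, sep = ":")
  beta_cols <- grep("^beta(_|$)", names(b), value = TRUE)
  af_cols <- grep("^af(_|$)", names(b), value = TRUE)

  direct <- match(key_a, key_b)
  swapped <- match(key_a, swap_b)
  swapped[is_strand_ambiguous(a$ref, a$ea)] <- NA
  use_swap <- allow_swap & is.na(direct) & !is.na(swapped)
  idx_b <- ifelse(!is.na(direct), direct, ifelse(use_swap, swapped, NA))

  keep <- !is.na(idx_b)
  bb <- b[idx_b[keep], , drop = FALSE]
  flip <- use_swap[keep]
  for (cl in beta_cols) bb[[cl]][flip] <- -bb[[cl]][flip]
  for (cl in af_cols) bb[[cl]][flip] <- 1 - bb[[cl]][flip]
  bb$ref[flip] <- a$ref[keep][flip]
  bb$ea[flip] <- a$ea[keep][flip]
  names(bb) <- paste0(names(bb), "_b")
  matched <- cbind(a[keep, , drop = FALSE], bb)
  rownames(matched) <- NULL
  list(matched = matched,
       n_swapped = sum(flip),
       unmatched_a = which(!keep),
       unmatched_b = setdiff(seq_len(nrow(b)), idx_b[keep]))
}

#' Nominal replication across cohorts
#'
#' A candidate SNP replicates when its scan p-value is below \code{alpha}
#' in every cohort. Candidates absent from any cohort are untestable and
#' reported separately.
#'
#' @param candidates data.frame of candidate SNPs (chr, pos, ref, ea).
#' @param cohort_results named list of \code{cca_scan} objects or results
#'   data.frames.
#' @param alpha nominal level (default 0.05).
#' @return list: \code{replicated} (subset of candidates),
#'   \code{untestable} (subset absent from >= 1 cohort).
#' @export
replicate_nominal <- function(candidates, cohort_results, alpha = 0.05) {
  key_c <- variant_id(candidates)
  status <- rep(TRUE, length(key_c))
  testable <- rep(TRUE, length(key_c))
  for (res in cohort_results) {
    df <- scan_results(res)$df
    idx <- match(key_c, variant_id(df))
    testable <- testable & !is.na(idx)
    pv <- df$p[idx]
    status <- status & !is.na(pv) & pv < alpha
  }
  list(replicated = candidates[status & testable, , drop = FALSE],
       untestable = candidates[!testable, , drop = FALSE])
}

# pairwise dosage r^2 between two variant columns of a panel
panel_r2 <- function(panel, id1, id2) {
  stats::cor(panel$dosage[, id1], panel$dosage[, id2])^2
}

#' Greedy lead-SNP clumping into loci
#'
#' Reproduces the two-threshold locus definition: significant SNPs are
#' first thinned greedily by ascending p into *independent significant
#' SNPs* (pairwise r^2 < \code{r2_indep}), then independent SNPs are
#' thinned into *lead SNPs* (pairwise r^2 < \code{r2_lead}); each
#' dependent SNP is attached to its best-correlated survivor, loci span
#' each lead's members and loci on the same chromosome closer than
#' \code{merge_kb} are merged. Pairs further apart than 1 Mb are treated
#' as unlinked (r^2 = 0). Ties in p are broken by genomic order.
#'
#' @param sig data.frame of significant SNPs (chr, pos, ref, ea, p).
#' @param ld either a symmetric r^2 matrix whose dimnames are variant ids
#'   (\code{chr:pos:ref:ea}), or a [genotype_matrix()] reference panel
#'   from which r^2 is computed.
#' @param r2_indep independence threshold (default 0.6).
#' @param r2_lead lead threshold (default 0.1).
#' @param merge_kb locus merge distance in kb (default 250).
#' @return object of class \code{locus_set}: list with \code{loci}
#'   (chr, start, end, lead id/p, member counts), \code{assignments}
#'   (per-SNP locus and role), and the thresholds used.
#' @export
clump_lead_snps <- function(sig, ld, r2_indep = 0.6, r2_lead = 0.1,
                            merge_kb = 250) {
  if (nrow(sig) == 0) stop("no significant SNPs to clump")
  ids <- variant_id(sig)
  if (anyDuplicated(ids)) stop("duplicate variant keys in significant set")
  get_r2 <- function(i, j) {
    if (sig$chr[i] != sig$chr[j] || abs(sig$pos[i] - sig$pos[j]) > 1e6)
      return(0)
    if (inherits(ld, "genotype_matrix")) {
      if (!all(c(ids[i], ids[j]) %in% colnames(ld$dosage)))
        stop("r^2 unavailable for pair ", ids[i], " / ", ids[j])
      return(panel_r2(ld, ids[i], ids[j]))
    }
    if (!all(c(ids[i], ids[j]) %in% rownames(ld)))
      stop("r^2 unavailable for pair ", ids[i], " / ", ids[j])
    ld[ids[i], ids[j]]
  }
  ord <- order(sig$p, match(sig$chr, AUTOSOMES), sig$pos)

  indep <- integer(0)          # indices into sig
  parent_indep <- integer(nrow(sig))
  for (i in ord) {
    r2s <- vapply(indep, function(j) get_r2(i, j), numeric(1))
    if (all(r2s < r2_indep)) {
      indep <- c(indep, i); parent_indep[i] <- i
    } else {
      parent_indep[i] <- indep[which.max(r2s)]
    }
  }

  leads <- integer(0)
  parent_lead <- integer(nrow(sig))
  for (i in indep) {           # indep is already in p order
    r2s <- vapply(leads, function(j) get_r2(i, j), numeric(1))
    if (all(r2s < r2_lead)) {
      leads <- c(leads, i); parent_lead[i] <- i
    } else {
      parent_lead[i] <- leads[which.max(r2s)]
    }
  }
  lead_of <- parent_lead[parent_indep]   # every significant SNP -> its lead

  loci <- lapply(leads, function(l) {
    mem <- which(lead_of == l)
    list(chr = sig$chr[l], start = min(sig$pos[mem]), end = max(sig$pos[mem]),
         lead = l, members = mem)
  })
  # merge loci on the same chromosome closer than merge_kb
  loci <- loci[order(sapply(loci, function(x) match(x$chr, AUTOSOMES)),
                     sapply(loci, `[[`, "start"))]
  merged <- list()
  for (lc in loci) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chr == lc$chr &&
        lc$start - last$end < merge_kb * 1000) {
      last$end <- max(last$end, lc$end)
      last$start <- min(last$start, lc$start)
      last$members <- c(last$members, lc$members)
      if (sig$p[lc$lead] < sig$p[last$lead]) last$lead <- lc$lead
      merged[[length(merged)]] <- last
    } else merged <- c(merged, list(lc))
  }
  loci_df <- do.call(rbind, lapply(merged, function(x)
    data.frame(chr = x$chr, start = x$start, end = x$end,
               lead_id = ids[x$lead], lead_p = sig$p[x$lead],
               n_members = length(x$members), stringsAsFactors = FALSE)))
  assignments <- data.frame(
    id = ids,
    locus = vapply(seq_along(ids), function(i) {
      which(vapply(merged, function(x) i %in% x$members, logical(1)))[1]
    }, integer(1)),
    role = ifelse(seq_along(ids) %in% leads, "lead",
                  ifelse(seq_along(ids) %in% indep, "independent", "member")),
    stringsAsFactors = FALSE
  )
  structure(list(loci = loci_df, assignments = assignments,
                 independent = ids[sort(indep)], leads = ids[sort(leads)],
                 r2_indep = r2_indep, r2_lead = r2_lead, merge_kb = merge_kb),
            class = "locus_set")
}

#' @export
#' @method print locus_set
print.locus_set <- function(x, ...) {
  cat("locus_set:", nrow(x$loci), "loci,", length(x$leads), "lead SNPs,",
      length(x$independent), "independent significant SNPs\n")
  print(utils::head(x$loci, 10))
  invisible(x)
}

#' Annotate lead SNPs with the nearest gene
#'
#' Distance is 0 for a SNP inside a gene body; ties at equal distance are
#' broken by the smaller interval, then by lexicographic symbol. A
#' chromosome with no genes yields the annotation \code{"none"}.
#'
#' @param leads data.frame with chr, pos (one row per lead SNP).
#' @param genes gene interval table from [read_gene_bed()] (1-based
#'   inclusive: chr, start, end, symbol).
#' @return \code{leads} with added columns \code{gene} and
#'   \code{gene_distance}.
#' @export
nearest_gene <- function(leads, genes) {
  leads$gene <- NA_character_
  leads$gene_distance <- NA_real_
  for (i in seq_len(nrow(leads))) {
    g <- genes[genes$chr == leads$chr[i], , drop = FALSE]
    if (nrow(g) == 0) { leads$gene[i] <- "none"; next }
    pos <- leads$pos[i]
    d <- pmax(0, pmax(g$start - pos, pos - g$end))
    width <- g$end - g$start + 1L
    ord <- order(d, width, g$symbol)
    leads$gene[i] <- g$symbol[ord[1]]
    leads$gene_distance[i] <- d[ord[1]]
  }
  leads
}
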