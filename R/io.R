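AUTOSOMES <- as.character(1:22)

# column maps from each supported GWAS dialect to the internal schema
.DIALECTS <- list(
  generic  = c(chr = "chr", pos = "pos", rsid = "rsid", ref = "ref",
               ea = "alt", beta = "beta", se = "se", n = "n", af = "af"),
  ckdgen   = c(chr = "Chr", pos = "Pos_b37", rsid = "RSID", ref = "Allele2",
               ea = "Allele1", beta = "Effect", se = "StdErr", n = "n",
               af = "Freq1", p = "P-value"),
  opengwas = c(chr = "chr", pos = "pos", rsid = "rsid", ref = "nea",
               ea = "ea", beta = "beta", se = "se", n = "n", af = "eaf",
               p = "p")
)

#' Read per-SNP GWAS summary statistics
#'
#' Reads a delimited per-SNP association table in one of three column
#' dialects and maps it onto the internal single-trait schema
#' (\code{chr, pos, rsid, ref, ea, af, beta, se, n, p}). Chromosome labels
#' are normalised (a leading \code{"chr"} is stripped) and rows on
#' non-autosomal chromosomes are dropped with a message, since the analysis
#' is restricted to chromosomes 1--22.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect one of \code{"generic"}, \code{"ckdgen"},
#'   \code{"opengwas"}. The generic dialect expects columns
#'   \code{chr, pos, rsid, ref, alt, beta, se, n, af} (and optionally
#'   \code{p}); ckdgen uses \code{Chr, Pos_b37, RSID, Allele1} (effect
#'   allele), \code{Allele2, Freq1, Effect, StdErr, P-value, n}; opengwas
#'   uses \code{chr, pos, rsid, ea, nea, eaf, beta, se, p, n}.
#' @return a data.frame in the internal schema, with attributes
#'   \code{n_dropped_nonautosome} and \code{dialect}.
#' @export
read_summary_stats <- function(path, dialect = c("generic", "ckdgen", "opengwas")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- .DIALECTS[[dialect]]
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  mandatory <- map[c("chr", "pos", "ref", "ea", "beta", "se")]
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("dialect '", dialect, "': mandatory column missing: ",
         paste(missing_cols, collapse = ", "))
  present <- map[map %in% names(raw)]
  cols <- lapply(c(chr = "chr", pos = "pos", rsid = "rsid", ref = "ref",
                   ea = "ea", af = "af", beta = "beta", se = "se",
                   n = "n", p = "p"),
                 function(internal) {
                   if (internal %in% names(present)) raw[[present[internal]]]
                   else rep(NA_character_, nrow(raw))
                 })
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  # numeric coercion with row-level diagnostics (line = data row + header)
  for (col in c("pos", "af", "beta", "se", "n", "p")) {
    vals <- out[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num) | (col %in% c("beta", "se") & is.na(num)))
    if (col %in% c("beta", "se")) bad <- which(is.na(num))
    if (length(bad) && !all(is.na(vals)))
      stop("unparseable numeric value in column '", col, "' at data row ",
           bad[1], " (file line ", bad[1] + 1L, ")")
    out[[col]] <- num
  }
  out$pos <- as.integer(out$pos)
  out$chr <- sub("^chr", "", out$chr, ignore.case = TRUE)
  keep <- out$chr %in% AUTOSOMES
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " row(s) on non-autosomal chromosomes dropped")
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nonautosome") <- n_drop
  attr(out, "dialect") <- dialect
  out
}

#' Combine single-trait summary tables into a multi-trait table
#'
#' Joins per-trait summary statistics on the variant key
#' (chr, pos, ref, ea). Only variants present in every trait table are
#' retained, mirroring the selection of SNPs with both eGFR and BUN
#' statistics available.
#'
#' @param ... named single-trait tables from [read_summary_stats()];
#'   names become trait labels (e.g. \code{egfr = ..., bun = ...}).
#' @return multi-trait data.frame with columns \code{beta_<trait>},
#'   \code{se_<trait>}, \code{n_<trait>}, \code{p_<trait>} and a
#'   \code{"traits"} attribute.
#' @export
combine_trait_stats <- function(...) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    stop("all trait tables must be named")
  traits <- names(tabs)
  key_cols <- c("chr", "pos", "ref", "ea")
  out <- tabs[[1]][c(key_cols, "rsid", "af")]
  for (tr in traits) {
    tab <- tabs[[tr]]
    sub <- tab[c(key_cols, "beta", "se", "n", "p")]
    names(sub)[5:8] <- paste(c("beta", "se", "n", "p"), tr, sep = "_")
    out <- merge(out, sub, by = key_cols, sort = FALSE)
  }
  out <- out[order(match(out$chr, AUTOSOMES), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "traits") <- traits
  out
}

#' Read genotype dosages from a VCF file
#'
#' Parses a VCF 4.x file (GT field) into a [genotype_matrix()]. Dosage is
#' the per-sample count of the ALT allele (0/1/2); missing genotypes are
#' recorded as \code{NA}. Multi-allelic or non-SNP records are skipped with
#' a warning and counted in the returned object's \code{skipped} attribute.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ok <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!ok)
  if (n_skip > 0)
    warning(n_skip, " multi-allelic or non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  # count ALT alleles in the GT string; "./." and ".|." -> NA
  alt_count <- function(s) {
    miss <- is.na(s) | grepl("\\.", s)
    d <- vapply(strsplit(s, "[/|]"), function(a) sum(a == "1"), integer(1))
    d[miss] <- NA_integer_
    d
  }
  dosage <- t(apply(gt, 1, alt_count))
  if (ncol(gt) == 1) dosage <- matrix(dosage, ncol = 1)
  dosage <- t(dosage)  # samples x variants
  variants <- data.frame(
    chr = sub("^chr", "", fix$CHROM),
    pos = as.integer(fix$POS),
    rsid = ifelse(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID),
    ref = fix$REF, ea = fix$ALT,
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dosage, variants, samples = colnames(gt))
  attr(g, "skipped") <- n_skip
  g
}

#' Construct a genotype matrix
#'
#' @param dosage samples x variants matrix of ALT-allele counts in
#'   \{0,1,2\} (NA allowed pre-QC).
#' @param variants data.frame with columns chr, pos, rsid, ref, ea.
#' @param samples sample identifiers (defaults to rownames of dosage).
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  stopifnot(nrow(variants) == ncol(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- samples
  colnames(dosage) <- variant_id(variants)
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  n_miss <- sum(is.na(x$dosage))
  if (n_miss > 0) cat("  missing dosage cells:", n_miss, "\n")
  invisible(x)
}

#' @export
#' @method dim genotype_matrix
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Canonical variant identifier chr:pos:ref:ea
#' @param v data.frame with chr, pos, ref, ea columns.
#' @return character vector of keys.
#' @export
variant_id <- function(v) paste(v$chr, v$pos, v$ref, v$ea, sep = ":")

#' Write a results table as TSV
#'
#' Numeric columns are written with 15 significant digits so the table
#' round-trips through [read_results_table()] to at least 12 significant
#' digits.
#'
#' @param results a data.frame.
#' @param path output path; the directory must exist.
#' @export
write_results_table <- function(results, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write to '", path, "': directory does not exist")
  df <- as.data.frame(results)
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read. Columns used: chrom, start, end
#' and (if present) name.
#'
#' @param path BED file path.
#' @return data.frame with chr, start, end, symbol (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(
    chr = sub("^chr", "", bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    symbol = if (ncol(bed) >= 4) as.character(bed[[4]])
             else paste0("gene", seq_len(nrow(bed))),
    stringsAsFactors = FALSE
  )
  out
}
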