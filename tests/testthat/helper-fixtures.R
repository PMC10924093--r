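# shared fixture builders for the test suite

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# three clean variants in the generic dialect
generic_stats_df <- function() {
  data.frame(
    chr = c("1", "2", "22"), pos = c(1000L, 2000L, 3000L),
    rsid = c("rs1", "rs2", "rs3"),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.03, 0.01),
    n = c(1000L, 1000L, 1000L), af = c(0.2, 0.3, 0.4),
    stringsAsFactors = FALSE
  )
}

# small genotype matrix with explicit dosages (variants in columns)
toy_genotypes <- function(dosage, chr = NULL, pos = NULL) {
  m <- ncol(dosage)
  variants <- data.frame(
    chr = chr %||% rep("1", m),
    pos = pos %||% (1000L * seq_len(m)),
    rsid = paste0("rs", seq_len(m)),
    ref = "A", ea = "G", stringsAsFactors = FALSE
  )
  kidneycca::genotype_matrix(dosage, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent enumeration oracle for the conditional HWE distribution:
# choose()-based, coded separately from the package's lgamma route
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het
  nm <- min(na, 2 * n - na)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  w <- vapply(hets, function(h) {
    choose(n, h) * choose(n - h, (nm - h) / 2) * 2^h
  }, numeric(1))
  p <- w / sum(w)
  min(1, sum(p[p <= p[match(n_het, hets)] * (1 + 1e-7)]))
}

# brute-force hypergeometric upper tail by enumerating placements of set B
hyper_oracle <- function(observed, n1, n2, N) {
  universe <- seq_len(N)
  a <- seq_len(n1)
  hits <- utils::combn(N, n2, function(b) length(intersect(a, b)) >= observed)
  mean(hits)
}
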