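.PIPELINE_DEFAULTS <- list(
  seed = 1L,
  out_dir = NULL,
  # synthetic cohort conditions (two individual-level cohorts are drawn)
  cohort = list(n_samples = 1000, n_snps = 5000, n_causal = 20,
                effect_size = 0.15, ld_block_size = 10, ld_rho = 0.5,
                pheno_corr = 0.6, case_fraction = 0.99),
  qc = list(maf_min = 0.01, max_missing = 0.015, hwe_alpha = 1e-5,
            scale_ancestry = 2),
  pheno = list(urea_divisor = 2.14, include_status_in_y = FALSE),
  scan = list(adjust = "bonferroni_by_count", alpha = 0.05),
  discovery = list(nominal_alpha = 0.05, r2_indep = 0.6, r2_lead = 0.1,
                   merge_kb = 250, direction_filter = TRUE),
  coloc = list(window_bp = 200000, p1 = 1e-4, p2 = 1e-4, p12 = 1e-6,
               pp4_threshold = 0.8),
  de = list(lfc_min = 1, fdr = 0.05),
  af = list(shortlist_diff = 0.10, report_diff = 0.15),
  stages = list(qc = TRUE, metacca = TRUE, cca = TRUE, direction = TRUE,
                significance = TRUE, replication = TRUE, clump = TRUE,
                coloc = TRUE, overlap = TRUE, de = TRUE, af = TRUE)
)

merge_config <- function(defaults, user, path = character(0)) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ",
           paste(c(path, nm), collapse = "."))
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build a pipeline configuration
#'
#' Starts from the analysis defaults (MAF 0.01, missingness 0.015, HWE
#' 1e-5, Bonferroni at 0.05 / genome-wide 5e-8, nominal 0.05, clumping
#' r^2 0.6/0.1, 200 kb colocalisation window with priors
#' 1e-4/1e-4/1e-6 and PP4 > 0.8, |log2FC| >= 1 with BH < 0.05, allele
#' frequency gates 0.10/0.15) and overrides them with user values, which
#' may come from a YAML file. Unknown keys raise an error naming the key.
#'
#' @param config named list of overrides, or NULL.
#' @param yaml_path optional YAML file of overrides.
#' @return validated configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config = NULL, yaml_path = NULL) {
  cfg <- .PIPELINE_DEFAULTS
  if (!is.null(yaml_path)) cfg <- merge_config(cfg, yaml::read_yaml(yaml_path))
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_write <- function(out_dir, name, df) {
  if (!is.null(out_dir))
    write_results_table(df, file.path(out_dir, paste0(name, ".tsv")))
}

#' Run the discovery pipeline end-to-end on synthetic cohorts
#'
#' Executes the stage sequence QC, per-SNP CCA on two individual-level
#' cohorts, summary-statistic metaCCA on cohort A, direction filter,
#' significance filter, cross-cohort replication, lead-SNP clumping,
#' colocalisation of the top locus against a simulated eQTL region,
#' overlap enrichment between the cohorts' significant sets, and the
#' differential-expression and allele-frequency follow-ups. Each enabled
#' stage appends its row counts to the run manifest; with an
#' \code{out_dir} set, per-stage TSVs and a YAML manifest are written.
#'
#' @param config a [pipeline_config()] (or a list of overrides).
#' @return the manifest: a list of per-stage counts, the resolved
#'   configuration, and the seed.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  st <- cfg$stages
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = cfg$seed, counts = list(),
                   parameters = unclass(cfg))
  note <- function(stage, ...) {
    manifest$counts[[stage]] <<- c(...)
  }

  spec_a <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
  spec_b <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed + 1000L)))
  g_a <- simulate_genotypes(spec_a); y_a <- simulate_phenotypes(g_a, spec_a)
  g_b <- simulate_genotypes(spec_b); y_b <- simulate_phenotypes(g_b, spec_b)
  note("simulate", n_samples = spec_a$n_samples, n_snps = spec_a$n_snps)

  if (isTRUE(st$qc)) {
    qa <- filter_variants_qc(g_a, cfg$qc$maf_min, cfg$qc$max_missing,
                             cfg$qc$hwe_alpha)
    qb <- filter_variants_qc(g_b, cfg$qc$maf_min, cfg$qc$max_missing,
                             cfg$qc$hwe_alpha)
    g_a <- qa$genotypes; g_b <- qb$genotypes
    note("qc", retained_a = qa$report$variants_retained,
         retained_b = qb$report$variants_retained)
  }

  scan_a <- cca_scan(g_a, y_a, adjust = cfg$scan$adjust)
  scan_b <- cca_scan(g_b, y_b, adjust = cfg$scan$adjust)
  stage_write(out_dir, "cca_a", scan_a$results)
  stage_write(out_dir, "cca_b", scan_b$results)
  note("cca", m_a = scan_a$m, m_b = scan_b$m)

  if (isTRUE(st$metacca)) {
    ss <- simulate_summary_stats(g_a, y_a)
    val <- validate_summary_input(ss)
    pc <- suppressWarnings(estimate_pheno_corr(val$stats))
    meta <- metacca_scan(val$stats, pc, adjust = cfg$scan$adjust)
    stage_write(out_dir, "metacca", meta$results)
    note("metacca", m = meta$m, validated = nrow(val$stats))
    working <- meta$results
  } else {
    working <- scan_a$results
  }

  if (isTRUE(st$significance)) {
    sig <- significance_filter(working, mode = cfg$scan$adjust,
                               alpha = cfg$scan$alpha)
    note("significance", n = nrow(sig))
  } else sig <- working

  if (isTRUE(st$direction) && isTRUE(cfg$discovery$direction_filter) &&
      all(c("beta_egfr", "beta_bun") %in% names(sig))) {
    sig <- opposite_direction_filter(sig)
    note("direction", n = nrow(sig))
  }
  stage_write(out_dir, "significant", sig)

  if (isTRUE(st$replication) && nrow(sig) > 0) {
    rep_res <- replicate_nominal(sig, list(a = scan_a, b = scan_b),
                                 alpha = cfg$discovery$nominal_alpha)
    replicated <- rep_res$replicated
    note("replication", n = nrow(replicated),
         untestable = nrow(rep_res$untestable))
    stage_write(out_dir, "replicated", replicated)
  } else replicated <- sig

  loci <- NULL
  if (isTRUE(st$clump) && nrow(sig) > 0) {
    loci <- clump_lead_snps(sig, g_a, r2_indep = cfg$discovery$r2_indep,
                            r2_lead = cfg$discovery$r2_lead,
                            merge_kb = cfg$discovery$merge_kb)
    note("clump", loci = nrow(loci$loci), leads = length(loci$leads),
         independent = length(loci$independent))
    stage_write(out_dir, "loci", loci$loci)
  }

  if (isTRUE(st$coloc)) {
    pair <- simulate_eqtl_pair(shared = TRUE, n_snps = 100, causal_z = 12,
                               seed = cfg$seed + 2000L)
    cl <- coloc_abf(pair$gwas, pair$eqtl, p1 = cfg$coloc$p1,
                    p2 = cfg$coloc$p2, p12 = cfg$coloc$p12,
                    pp4_threshold = cfg$coloc$pp4_threshold)
    note("coloc", pp4 = unname(cl$pp["pp4"]),
         colocalised = as.integer(cl$colocalised))
  }

  if (isTRUE(st$overlap)) {
    sig_a <- significance_filter(scan_a, mode = cfg$scan$adjust,
                                 alpha = cfg$scan$alpha)
    sig_b <- significance_filter(scan_b, mode = cfg$scan$adjust,
                                 alpha = cfg$scan$alpha)
    if (nrow(sig_a) > 0 && nrow(sig_b) > 0) {
      ov <- overlap_test_sets(list(variant_id(sig_a), variant_id(sig_b)),
                              universe_n = scan_a$m)
      note("overlap", observed = ov$observed, expected = ov$expected,
           p = ov$p)
    }
  }

  if (isTRUE(st$de)) {
    sim_expr <- simulate_expression(500, 10, 10, de_fraction = 0.1,
                                    seed = cfg$seed + 3000L)
    de <- differential_expression(sim_expr$expr, sim_expr$groups,
                                  lfc_min = cfg$de$lfc_min, fdr = cfg$de$fdr)
    note("de", genes = nrow(de), passing = sum(de$passes))
    stage_write(out_dir, "de", de)
  }

  if (isTRUE(st$af) && !is.null(loci) && nrow(loci$loci) > 0) {
    lead <- loci$loci$lead_id[1]
    cases <- g_a$samples[y_a$case == 1]
    cohort <- allele_freq(g_a, lead, subgroup = cases)
    reference <- list(af = 0.3, allele_number = 10000L)
    cmp <- af_comparison(cohort, reference,
                         shortlist_diff = cfg$af$shortlist_diff,
                         report_diff = cfg$af$report_diff)
    note("af", af_diff = cmp$af_diff,
         shortlisted = as.integer(cmp$shortlisted))
  }

  if (!is.null(out_dir))
    yaml::write_yaml(manifest["counts"], file.path(out_dir, "manifest.yaml"))
  class(manifest) <- "pipeline_manifest"
  manifest
}

#' @export
#' @method print pipeline_manifest
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline run (seed", x$seed, ")\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-13s %s\n", paste0(nm, ":"),
                paste(names(v), signif(unlist(v), 6), sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}
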