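---
title: "Multivariate kidney-function SNP discovery with kidneycca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate kidney-function SNP discovery with kidneycca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneycca)
```

## The model

Kidney function is monitored through two complementary serum markers:
estimated glomerular filtration rate (eGFR, ml/min/1.73 m²) and blood
urea nitrogen (BUN, the nitrogen component of serum urea, mmol/L after
conversion). A variant that genuinely alters filtration should move both
markers, and in opposite directions — impaired filtration lowers eGFR
and raises urea. `kidneycca` tests each SNP against the two markers
jointly by canonical correlation analysis (CCA).

For a dosage vector $x$ and phenotype block $Y$, CCA finds weight
vectors $a, b$ maximising $\mathrm{corr}(Xa, Yb)$; the maximum $r_1$ is
the first canonical correlation, computed as the leading singular value
of the whitened cross-covariance
$K = \Sigma_{XX}^{-1/2}\,\Sigma_{XY}\,\Sigma_{YY}^{-1/2}$. Significance
uses Wilks' Lambda $\Lambda = \prod_i (1 - r_i^2)$ with Rao's F
approximation. For the per-SNP scan ($G = 1$, $P = 2$) the approximation
is exact: $r_1^2$ is the coefficient of determination of regressing the
dosage on the phenotype block and the Wilks F equals that regression's
overall F. The test suite checks this identity against an independent
least-squares fit at every scanned SNP, to $|\Delta\log_{10} p| <
10^{-8}$.

The summary-statistic engine (`metacca_scan`) reconstructs the same scan
from per-trait GWAS results alone. Each trait's $(\beta, se, n)$ becomes
a genotype–phenotype correlation through the $t$ statistic,
$r = t/\sqrt{t^2 + n - 2}$ — for ordinary least squares this equals the
sample Pearson correlation exactly, which is why the two engines agree
to numerical precision when given the same cohort and the same
phenotypic correlation matrix. The single-SNP canonical correlation is
then $r_1^2 = s^\top S_{YY}^{-1} s$, after the joint matrix
$[[1, s^\top], [s, S_{YY}]]$ is shrunk to positive semidefiniteness if
needed (off-diagonal multiplier 0.999 per iteration, eigenvalue floor
$10^{-12}$).

## Phenotype standardisation

* eGFR: rank-based inverse normal transform with the Blom offset 0.375
  and average ranks for ties. The transform is monotone, so it preserves
  the ordering of kidney function while making the marginal exactly
  normal scores.
* Urea: divided by 2.14 (the molar-mass ratio of urea to its two
  nitrogen atoms — the conventional urea-to-BUN conversion; the divisor
  is configurable since laboratories differ), then $\log_{10}$, then
  z-scored with the $n-1$ standard deviation.
* CKD case status is carried as a 0/1 indicator. By default it does
  **not** enter the CCA Y block — the scan tests the two quantitative
  markers jointly — but `include_status_in_y = TRUE` appends it as a
  third column for sensitivity analyses. Both behaviours are supported
  because either reading of "an additional binary indicator variable" is
  defensible; excluding it keeps the test interpretable as a
  kidney-function test and is the default.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.01 | minor allele frequency floor |
| `max_missing` | 0.015 | variant removed when missingness ≥ 1.5% |
| `hwe_alpha` | 1e-5 | exact Hardy–Weinberg p-value floor ("0.001%") |
| ancestry `scale` | 2 | PC-radius multiplier over the reference panel |
| significance | 0.05/m or 5e-8 | Bonferroni-by-count or fixed genome-wide |
| clumping r² | 0.6 / 0.1 | independent-SNP and lead-SNP thresholds |
| `merge_kb` | 250 | locus merge distance |
| coloc priors | 1e-4, 1e-4, 1e-6 | single-trait and shared-causal priors |
| `pp4_threshold` | 0.8 | colocalisation call |
| DE gates | \|log2FC\| ≥ 1, BH < 0.05 | differential-expression call |
| AF gates | 0.10 / 0.15 | shortlist and report frequency differences |

The QC filters apply in a fixed order (non-autosome, MAF, missingness,
HWE, any-missing) and the report's removed-plus-retained counts always
equal the input count, which the suite property-tests under random
missingness.

The power helper `min_detectable_r` is the one-sided Fisher-z solution
$r = \tanh((z_{1-\alpha} + z_{power})/\sqrt{n-3})$. One-sided is the
declared convention: at $n = 2494$ and $\alpha = 5\times10^{-8}$ it
gives 0.12 (two-sided would give 0.13), and at $n = 1917$ it gives 0.14.

## Estimating the phenotypic correlation from summary statistics

Under the null, the standardised effects of two traits at one SNP are
correlated exactly as the traits themselves, so the correlation of
effect columns across SNPs estimates $S_{YY}$. That argument fails at
associated SNPs: there the effect pair reflects the causal
effect-direction structure (for kidney function, systematically
opposite signs), and with a non-negligible associated fraction the naive
genome-wide Pearson estimate is badly biased — in our simulations with
1% causal SNPs plus their LD partners it lands at $-0.36$ when the
cohort's realised phenotype correlation is $+0.08$.
`estimate_pheno_corr` therefore excludes SNPs with per-trait $p < 0.01$
(`null_p_max`, set 0 to disable) before correlating. Under a fully null
genome this drops about 2% of SNPs and changes nothing material (a 0.6
correlation is still recovered within 0.05); with causal structure it
restores the engine agreement that motivates the method. Note also that
with many more SNPs than samples the estimator's target is the cohort's
*realised* phenotype correlation, not the population value: all effect
columns share one draw of $n$ individuals.

## Colocalisation

`coloc_abf` enumerates the five single-causal-variant hypotheses with
per-SNP Wakefield approximate Bayes factors,
$\log ABF = \tfrac12\log(1-r) + \tfrac12 z^2 r$, $r = W/(W+V)$, and the
stated priors. All accumulation is in log space with log-sum-exp, since
regions with $|z| > 30$ overflow the natural scale. The prior effect SD
is 0.15 on the trait-standardised scale; each region's trait SD is
estimated from $\mathrm{var}(\hat\beta)\cdot 2f(1-f)n$ (the identity
that links the OLS standard error to the trait variance) and multiplies
the prior, so posteriors depend on the per-SNP z-scores and not on the
unit in which effects are expressed. When AF or n is missing the trait
SD falls back to 1, i.e. betas are treated as already standardised.
Region intersection excludes strand-ambiguous A/T and C/G
allele-swapped sites, the same rule the harmonisation step uses. For
CCA-identified lead regions the signed per-SNP statistics fed to coloc
are the driving trait's univariate effects (eGFR by default,
configurable), since a canonical correlation has no sign of its own.

## The synthetic cohorts

Every pipeline input can be generated in code (`cohort_spec`,
`simulate_genotypes`, `simulate_phenotypes`, `simulate_summary_stats`,
`simulate_eqtl_pair`, `simulate_expression`). The generator's defaults
are the package's study conditions:

* 2,000 samples × 2,000 SNPs; MAF uniform on [0.05, 0.5]; LD as a
  Gaussian copula with exchangeable correlation 0.5 in blocks of 10
  adjacent SNPs, thresholded at the Hardy–Weinberg genotype quantiles so
  realised counts are HWE-consistent by construction.
* 20 causal SNPs (1% of the panel) of latent effect 0.15 each, with
  opposite signs on the two markers (`direction_mode = "opposite"`);
  residual marker correlation 0.6; 99% CKD case fraction assigned to the
  low-eGFR tail, matching a mostly-case renal cohort.
* Raw scales: eGFR mapped affinely to roughly 5–137 ml/min/1.73 m² and
  urea log-mapped to roughly 1.4–45 mmol/L, so the standardisation code
  paths run on realistic magnitudes.

What the generator does **not** emulate: realistic recombination and
demographic LD structure (blocks are exchangeable, not decaying),
imputation uncertainty, ancestry admixture, genotyping batch effects,
and case ascertainment beyond the eGFR-tail rule. Passing tests
therefore demonstrate the statistics are computed correctly and are
well calibrated under the stated generative model — not that real
cohort artefacts are handled.

Each generator is a pure function of its spec and seed (per-stage
streams are derived at fixed offsets from one global seed) and restores
the caller's RNG state.

## Numerical choices

* Whitening uses symmetric eigendecomposition with an eigenvalue floor
  of $10^{-10}$; blocks below the floor raise an error advising removal
  of collinear columns rather than silently regularising.
* Canonical correlations are clipped to [0, 1]; weight signs are fixed
  by making the first non-zero X weight positive.
* The HWE exact test is the two-sided conditional test (probabilities
  summed over heterozygote counts no more probable than observed, with a
  $1+10^{-7}$ slack factor against ties), computed through log-gamma.
* Clumping treats pairs more than 1 Mb apart as unlinked, breaks p-value
  ties by genomic order, and assigns each dependent SNP to its
  best-correlated survivor, so loci always partition the significant
  set.
* Zero effect sizes fail the opposite-direction filter: the requirement
  is strictly opposite signs.
* Duplicate variant keys in summary input drop *all* copies, since
  provenance cannot be arbitrated.
* The allele-frequency gates compare against 0.10/0.15 with a $10^{-12}$
  tolerance so decimal thresholds behave as written.
* Triple-set overlap enrichment has no standard exact null, so its
  p-value is a Poisson upper tail at the independence mean
  $n_1 n_2 n_3 / N^2$, flagged as an approximation in the result.
* Differential expression uses a plain Welch two-sample test per gene.
  Moderated (empirical-Bayes) statistics are deliberately out of scope;
  the acceptance behaviour tested is the threshold logic and power under
  the generative model, not a microarray re-analysis.

## Problem sizes used by the test suite

The suite simulates cohorts up to 2,000 samples × 2,000 SNPs for the
engine-agreement check, 10,000 SNPs for null calibration, 100-SNP
regions × 200 seeds for colocalisation, and exhaustive enumeration for
the exact-test oracles (hypergeometric universes to $N = 12$, HWE tables
to total 50). These sizes were chosen so each property is measured with
useful Monte-Carlo precision while the whole suite stays quick to run on
a laptop.

## Known limitations

* Only single-SNP ($G = 1$) scans are vectorised; multi-SNP blocks run
  through the generic engine but without LD-aware reference panels
  (gene-level metaCCA with reference $S_{XX}$ is out of scope).
* Colocalisation assumes at most one causal variant per region per
  trait; multi-causal fine-mapping (SuSiE-style) is not implemented.
* The ancestry filter consumes PC coordinates; it does not compute the
  PCA or kinship itself (relatedness exclusions are accepted as sample
  lists).
* Binary-trait liability-scale conversions for summary statistics are
  not implemented; case/control inputs are treated as quantitative 0/1.
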