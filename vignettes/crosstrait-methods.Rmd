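---
title: "Methods: cross-trait genetic overlap from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait genetic overlap from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrait)
```

`crosstrait` implements a complete cross-trait genetic-overlap workflow for a
target trait (the motivating use case is Alzheimer's disease) against panels
of correlated traits such as blood lipids and coronary-artery-disease
phenotypes, working entirely from GWAS summary statistics. This vignette
explains each statistical component, its assumptions, the tunable parameters,
and the design decisions taken where the methodology leaves room for choice.

## Global genetic correlation by LD-score regression

For SNP $j$ with LD score $\ell_j$ (the sum of squared correlations with its
neighbours), the LD-score model for a polygenic trait with heritability
$h^2$, sample size $N$ and $M$ causal-SNP slots gives

$$\mathrm{E}[\chi^2_j] = 1 + \frac{N h^2 \ell_j}{M},$$

and for two traits A and B with genetic covariance $\rho_g$ and $N_s$ shared
samples of phenotypic correlation $r_p$,

$$\mathrm{E}[z_{Aj} z_{Bj}] = \frac{\sqrt{N_A N_B}\,\rho_g\,\ell_j}{M}
 + \frac{N_s r_p}{\sqrt{N_A N_B}}.$$

`estimate_h2()` and `estimate_rg()` fit these as weighted regressions of the
chi-square (or z-product) on $N\ell_j/M$. Heteroskedasticity weights
$1/\big(\ell_j (v_{Aj} v_{Bj} + c_j^2)\big)$ — with $v$ the expected per-SNP
z-variance and $c_j$ the expected z-product — are refined over two
reweighting passes, which is standard practice for this estimator family.
The univariate fit is the self-pair special case of the covariance
regression; `estimate_rg()` first runs preliminary univariate fits to fix
the variance parameters and then refits all three regressions under one
weighting rule, which guarantees the algebraic identity
`estimate_rg(a, a)$rg == 1`.

The genetic correlation is $r_g = \rho_g / \sqrt{h^2_A h^2_B}$. Standard
errors come from a delete-a-block jackknife over `n_blocks` (default 200)
contiguous SNP blocks, computed jointly for the three regressions from
block-wise weighted cross-products so the ratio's sampling covariance is
respected. $r_g$ is deliberately *not* clipped to $[-1, 1]$: clipping would
bias the jackknife; a warning is raised instead.

Key parameter choices:

* `m_ref` (the $M$ in the slope term) defaults to the number of regression
  SNPs; a reference-panel value can be supplied.
* SNPs with $\chi^2 > \max(80,\, 0.001\,N)$ are excluded before the fit, a
  conventional guard against single-locus leverage (`chisq_max = Inf`
  disables it).
* The cross-trait intercept absorbs sample overlap. With
  `constrain_intercepts = TRUE` it is fixed at 0 — appropriate once an
  unconstrained fit has shown no evidence of overlap — while the univariate
  intercepts always remain free, since the methodology we follow reports
  constrained-covariance results without stating fixed univariate
  intercepts.
* Pairwise scans (`pairwise_rg_scan()`) flag significance at
  $p < 0.025$, strict, reflecting a correction for testing each pair in two
  panels.

## Gene-level overlap and the exact binomial test

Given gene-based association tables for a discovery trait and the target
(`gene_table` objects, matching the `.genes.out` layout of common gene-based
analysis tools), `overlap_assessment()` counts genes with $P_{gene} < 0.05$
(strict) in each table and in both. The expected overlap proportion is
(discovery-significant / discovery-total); the observed proportion is
(overlap / target-significant). A one-sided exact binomial test
(`exact_binomial_upper()`, the upper tail $P(X \ge k)$ computed in log
space) asks whether the observed exceeds the expected proportion. The null
proportion is rounded to 3 decimals by default, matching how such tests are
conventionally invoked on published proportions; `null_rounding = NULL`
uses the exact fraction.

Under trait independence this test is *conservative*: conditional on both
margins the overlap count is hypergeometric, whose variance is below the
binomial's, and the null proportion is itself estimated from the same table.
Our calibration simulations show a type-I rate of roughly 0.01 at nominal
0.05, so rejections are trustworthy but the test is not exactly uniform
under the null.

Shared-gene discovery proceeds at two levels. `find_sentinel_shared()`
returns genes already genome-wide significant ($P_{gene} < 2.6\times10^{-6}$,
strict) in the target and at least one other trait. `classify_fcp_genes()`
combines two gene p-values by Fisher's method,
$X = -2(\ln p_A + \ln p_B) \sim \chi^2_4$, and flags genes that are *not*
genome-wide significant in either input ($2.6\times10^{-6} \le p < 0.05$ in
both — the only coherent reading of "nominally associated but not yet
genome-wide significant") whose combined p-value crosses the genome-wide
threshold. Genes already significant in one input whose combined p improves
on both are annotated separately as `improved`. Input p-values are clamped
at $10^{-300}$ before log-space combination, since real tables contain
underflowed values.

## Two-sample Mendelian randomisation

Instruments are exposure SNPs with $p < 5\times10^{-8}$ (strict), greedily
clumped by ascending p-value: a candidate within `clump_kb` (default
10,000 kb — deliberately wide, since the clumping window is rarely reported
and a wide window errs toward independence) of a retained SNP on the same
chromosome, and in the same LD block when block information is available, is
dropped. `extract_and_harmonise()` aligns outcome alleles to the exposure
(sign-flipping swapped alleles, resolving strand complements, dropping
frequency-ambiguous palindromic variants within ±0.08 of frequency 0.5) and
orients every instrument so the exposure effect is positive.

Estimators, with their minimum instrument counts chosen to reproduce the
dash/absence conventions of published MR tables:

* **IVW** (min 2): weighted regression through the origin, weights
  $1/se_{out}^2$; default multiplicative random effects inflates the SE by
  $\max(1, \sqrt{Q/(n-1)})$.
* **Weighted median** (min 3): interpolated weighted 50th percentile of the
  Wald ratios, first-order weights; SE by seeded parametric bootstrap
  (default 1000 replicates). Consistent when up to half the weight lies on
  invalid instruments.
* **MR-Egger** (min 3): free-intercept weighted regression; the intercept
  estimates directional pleiotropy and its t-test (df $n-2$) is the
  pleiotropy test. The residual variance is floored at 1 (the SE is never
  deflated below its fixed-effect value), the convention of the standard MR
  tooling; this makes the intercept test mildly conservative (we measure
  ~0.036 at nominal 0.05).
* **Cochran's Q** (min 2): heterogeneity of Wald ratios about the
  fixed-effect IVW estimate, $\chi^2_{n-1}$.
* **MR-PRESSO** (min 4): the observed leave-one-out residual sum of squares
  is compared against `n_sim` (default 1000) parametric simulations of the
  no-pleiotropy model; per-instrument exceedance p-values are
  Bonferroni-thresholded at $0.05/n$. An outlier-corrected IVW estimate and
  a resampling distortion test are reported only when outliers are found —
  with clean data the corrected slot is deliberately absent, mirroring the
  "no pleiotropy detected" reporting convention. Note the outlier test's
  resolution is bounded by `n_sim`: with 1000 simulations the smallest
  attainable adjusted p-value sits just at the 0.05 boundary, so flagging
  requires the observed residual to exceed every simulation.

Steiger filtering is not applied. Odds ratios and 95% intervals are
$e^\beta$, $e^{\beta \pm 1.96\,se}$; for continuous exposures the betas are
reported alongside, since the per-unit scale of published ORs is often
unstated.

## Local genetic correlation

`partition_by_locus()` assigns SNPs to semi-independent loci (1-based,
inclusive coordinates at both ends). Within a locus with $K$ SNPs and
per-effect sampling variance $1/n$, `local_univariate()` estimates the local
heritability by method of moments on decorrelated effects,
$\hat h^2_{loc} = \sum_j \eta_j^2 - K/n$, and tests the local signal by
referring $n \sum_j \eta_j^2$ to $\chi^2_K$. With identity LD (the bundled
synthetic setting) decorrelation is a pass-through; with a supplied LD
matrix, effects are projected onto the leading eigenvectors retaining 99% of
the LD variance and whitened.

`local_bivariate()` requires a nominally significant univariate signal in
*both* traits ($p < 0.05$, applied per locus per trait) — a bivariate test
without marginal signal is uninterpretable. The local correlation is
$\hat\rho = \widehat{cov}/\sqrt{\hat h^2_A \hat h^2_B}$, truncated to
$[-1, 1]$; $r^2 = \hat\rho^2$ exactly (pre-rounding) for every emitted row.
The p-value comes from a seeded simulation of the null (default 10,000
draws of independent effects with the estimated per-trait variances),
two-sided on the cross-product statistic. We chose a simulation null over
an analytic approximation because it is assumption-light and directly
testable; the cost is p-value granularity of $1/(n_{sims}+1)$.

Two degenerate cases are worth noting. A trait analysed against itself
yields $\hat\rho$ slightly above 1 before truncation — the cross-product of
identical vectors includes the shared sampling noise — and is reported as
exactly 1 after truncation. Non-positive local heritability yields an
undefined-rho flag rather than a number.

`scan_and_summarise()` flags loci at $p < $ the Bonferroni family threshold
(`bonferroni_threshold(n_tests)`, e.g. $0.05/35 = 1.4\times10^{-3}$,
strict), averages $\hat\rho$ over significant loci, and tallies them per
chromosome. The mean is reported at full precision together with a
2-decimal round-half-away-from-zero display value; published tables are not
always consistent at the half-way boundary, so the full-precision value is
authoritative.

## The synthetic-data generators

All inputs are generated with known ground truth so every downstream claim
is testable without external downloads:

* `simulate_sumstats_pair()` draws per-SNP z-scores from the exact bivariate
  moment model above. LD scores are drawn per block as
  $1 + \Gamma(\text{shape }2)$ with block-specific means (long-tailed, and
  bounded below by 1 as true LD scores are); sample overlap enters only
  through the cross-trait intercept, exactly as the regression model
  assumes. Default block mean 4 keeps the mean chi-square near 4 at the
  reference conditions ($h^2 = 0.3$, $N = 50{,}000$, $M = 20{,}000$), so
  the chi-square guard essentially never binds.
* `simulate_gene_tables()` draws gene z-statistics
  $\mathcal{N}(\mu_{assoc}, 1)$ for associated genes with a configurable
  shared fraction; one-sided upper-tail p-values.
* `simulate_mr_dataset()` builds harmonised instrument tables with a true
  causal effect, InSIDE-respecting pleiotropy (independent of instrument
  strength; a correlated-pleiotropy switch exists for stress tests), and a
  configurable fraction of high-pleiotropy outliers. Defaults
  ($se_{exp} = 0.01$, $se_{out} = 0.02$, instrument effects
  $U(0.05, 0.15)$, outlier pleiotropy SD 0.2) give strong instruments and
  outliers large enough for the PRESSO tests to have power at realistic
  instrument counts.
* `simulate_local_blocks()` plants per-locus correlations with independent
  LD.

What the generators emulate — the moment structure, sample overlap, shared
association fractions, pleiotropy and planted local correlations — is what
the estimators consume. What they do not emulate: realistic human LD (block
structure is exchangeable, not map-based), allele-frequency-dependent
architecture, in/dels, the X chromosome, or genomic inflation from
stratification. Passing tests therefore demonstrate statistical correctness
of the estimators under their stated models, not robustness to every
artefact of real GWAS data.

All generators are deterministic given `seed`; every stochastic analysis
component (bootstrap, PRESSO simulations, local null draws) takes an
explicit seed and restores the caller's RNG state.

## Orchestration

`run_workflow()` executes the stages in order — simulate, global
correlation, gene overlap, shared genes, MR (restricted to traits passing
the global-correlation or gene-overlap gate, plus an explicit allow-list,
since published analyses sometimes include a trait on external evidence),
local correlation, concordance — writing per-stage tables, a manifest and
the resolved configuration to a run directory. `classify_concordance()`
compares global and local conclusions per pair: both significant and
same-signed (`both_concordant`), opposite-signed (`both_discordant`), one
only (`ldsc_only` / `lava_only`), or `neither`; the mapping is total over
the flag/sign combinations.

The bundled example table `inst/extdata/local_rg_example.tsv` contains
bivariate local-correlation results for an Alzheimer's-disease analysis
against lipid and CAD traits (18 significant locus-pair rows across 8 loci
on chromosomes 6, 8, 17 and 19); the README shows the aggregation it
supports.

## Numerical and testing choices

Problem sizes in the test suite were chosen to make Monte-Carlo error small
relative to the tested tolerances while keeping the default run fast:
20,000 SNPs and 100 seeds for correlation recovery, 500 replicates for IVW
coverage and Egger calibration, 100 replicates for PRESSO recovery, 100–200
seeds for local-correlation recovery and null calibration. Closed-form
components (binomial tail, Fisher combination, weighted median) are checked
against independent oracles: direct log-space tail summation, chi-square
quadrature, and an interpolated weighted-quantile construction.

Known limitations: heritability and correlation estimates at small SNP
counts with dense per-SNP signal can trip the chi-square guard and bias the
slope (disable the guard or scale $M$ up if simulating such regimes); the
jackknife assumes exchangeable contiguous blocks; the local-correlation
p-value inherits simulation granularity; and MR-Egger's power is limited at
few instruments, as its not-run contracts make explicit.
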