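---
title: "Heritability and genetic regulation of DNA methylation in pedigrees: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability and genetic regulation of DNA methylation in pedigrees: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methkin)
```

# The problem

Array-based DNA methylation studies in extended families ask three related
questions about every CpG site: is methylation heritable, is it regulated
by nearby genetic variants (cis-mQTL), and is it associated with covariates
(age, sex) or disease-relevant traits (obesity measures)? methkin
implements this analysis for beta-value panels (GoldenGate-class arrays,
hundreds to a few thousand probes) on pedigreed cohorts, together with the
quality-control chain such studies use and a synthetic-study generator so
that every stage can be validated without access to protected family data.

# Pedigrees and the additive relationship matrix

`read_pedigree()` parses PED-style files (FAM, IID, FATHER, MOTHER, SEX,
`0` = missing parent; an optional sixth column labels monozygotic-twin
groups). Individuals must have zero or two known parents and the parentage
graph must be acyclic.

`additive_relationship()` computes the numerator relationship matrix A by
the tabular recursion, processing parents before offspring:

* `A[i,i] = 1 + A[f,m]/2` (founders: 1, assumed non-inbred, mutually
  unrelated),
* `A[i,j] = (A[f,j] + A[m,j])/2` for previously placed `j`.

A is twice the kinship matrix; parent-offspring and full-sib pairs have
coefficient 0.5, grandparent-grandchild, avuncular, half-sib and
double-first-cousin pairs 0.25. MZ twins are forced to coefficient 1 and
inherit identical relationships to everyone else. The recursion is checked
in the test suite against a gene-dropping Monte-Carlo estimate (10^5
drops, agreement within 0.02 per entry) and A is verified positive
semi-definite and order-equivariant.

The field also reports relationship *degrees* with conventional
coefficients. `relationship_degree_table()` stores the reporting
convention used by the study this package was built around, including its
3rd–6th-degree values (0.0078, 0.0020, 0.0005, 0.0001). Those do not
follow the exact halving series, and their derivation is not documented;
they are kept verbatim for reporting only and never enter any computation.
`pair_degree_census()` bins exact coefficients with the standard halving
series (`degree_bins()`); anything unmatched is reported as `other`, never
silently dropped.

# Methylation QC

The QC chain runs in a fixed order, and the `qc_report` keeps per-stage
books (`n_before - n_excluded = n_after`):

1. **Sample call rate** (default ≥ 0.90 of probes with detection p < 0.05).
2. **Sample CV outliers**: coefficient of variation of beta values per
   sample; samples strictly above the 97.5th percentile
   (linear-interpolation quantile, type 7) are removed. With ties at the
   cut nobody is removed — a deliberate reading, since "beyond the
   percentile" implies strict exceedance.
3. **Probe call rate** (default ≥ 0.97).
4. **Beta variation**: probes whose max−min beta across samples is below
   0.17 are removed; 0.17 is the platform's stated discrimination limit
   for beta differences, and "variation" is read as the observed range on
   non-missing values.
5. **Normality screen**: a Lilliefors test per probe, retaining probes
   with Benjamini–Hochberg-adjusted q ≥ 0.1. The downstream model is a
   Gaussian likelihood on untransformed beta values, so probes where that
   is indefensible are excluded rather than transformed.
6. **Autosomes only**: X/Y-linked probes are removed.

## Lilliefors with a Monte-Carlo null

Because the normal parameters are estimated from the data, the classical
Kolmogorov–Smirnov null does not apply. `lilliefors_test()` simulates the
null distribution of D from standard-normal samples of the same size
(default `n_mc` = 10,000, fixed seed; `p = (1 + #{D0 ≥ D})/(n_mc + 1)`),
which is exact at any sample size up to Monte-Carlo error, unlike the
Dallal–Wilkinson approximation. The null depends only on the sample size,
so it is computed once per distinct n and shared across probes. The test
suite checks the D statistic against `nortest::lillie.test` and the null
rejection rate at level 0.1 over 1,000 simulated normal probes. One
consequence of the shared null worth knowing: p-values of same-sized
probes are computed against the same realized null sample, so their
Monte-Carlo errors are correlated; at `n_mc` = 10,000 this is negligible.

`simulate_qc_panel()` generates a 1,505-probe demonstration panel whose
strata trip the four probe filters at exactly 103/355/641/11, leaving 395
survivors. The strata are engineered with wide margins (bimodal
"non-normal" probes with Monte-Carlo p ≈ 10⁻⁴; retained probes regenerated
until their Lilliefors p exceeds 0.25 and their range exceeds 0.2), so the
counts are reproduced for any seed.

# The polygenic model

For a trait vector t over n pedigree members with covariates x:

    t = m + Σ_k b_k x_k + g + e,
    g ~ MVN(0, σ²g · A),   e ~ MVN(0, σ²e · I),
    h² = σ²g / (σ²g + σ²e).

`fit_polygenic()` maximizes the full (not restricted) likelihood: LRT-based
inference requires comparable ML likelihoods between nested models, which
REML does not give when fixed effects differ. One eigendecomposition
A = U Λ Uᵀ rotates the problem so the covariance is diagonal in
h²: after `y* = Uᵀy`, `X* = UᵀX`, the weights are `w_i = h²λ_i + (1−h²)`,
and β and the total variance profile out in closed form by weighted least
squares. The 1-D profile likelihood in h² is maximized over a 64-point
grid on [0, 1−10⁻⁶] and refined with Brent search to 10⁻⁸; the grid guards
against flat ridges. When the likelihood is flat in h² (A = I: g and e are
indistinguishable), the boundary fit h² = 0 is returned with an
identifiability warning. Samples with missing trait or covariates are
dropped listwise, subsetting A.

Correctness anchors in the test suite: the rotated likelihood equals a
dense Cholesky-based multivariate-normal log-density at the fitted
parameters to 10⁻⁸, and the whole fit matches a dense-covariance ML oracle
(loglik to 10⁻⁶, ĥ² to 10⁻⁴) on small pedigrees; ĥ² is invariant to trait
rescaling and respects [0, 1).

## Inference

* **Heritability**: `lrt_h2()` compares the full fit to the σ²g = 0 null.
  σ²g sits on the parameter boundary, so λ = 2Δlogℓ is referred to the
  mixture ½χ²₀ + ½χ²₁: `p = ½·Pr(χ²₁ > λ)`, with p = 0.5 at λ = 0.
* **Covariates**: `covariate_lrt()` drops one term (polygenic background
  re-estimated) and uses plain χ²₁. The reported standardized coefficient
  is `b·sd(x)/sd(t)`, positive meaning higher methylation with the
  covariate (age in years; sex coded female = 1).
* **Measured genotype**: `measured_genotype_test()` adds a SNP dosage as a
  fixed effect and tests it by χ²₁ LRT; the standardized effect
  `b/sd(t residualized on covariates)` is per minor-allele copy in
  trait-SD units, positive when the minor allele increases methylation.
* **Obesity traits**: `obesity_covariate_test()` reverses the roles — a
  polygenic model for waist circumference or BMI with the CpG's beta value
  as a fixed covariate; positive means higher methylation with a larger
  obesity measure.

## Finite-sample behavior of the boundary mixture

The ½χ²₀ + ½χ²₁ null is asymptotic. On family data of realistic size it is
*conservative*: under h² = 0 the probability that ĥ² = 0 exceeds ½ (we
measure 0.62–0.71 at n ≈ 200, with null rejection at p < 0.05 around
0.034, approaching but not reaching 0.05 even at n ≈ 2,000). The test
never over-rejects; heritability p-values are, if anything, slightly
pessimistic. The same convention is used by the standard
variance-components engines for this analysis, so results are comparable.

Default covariates are sex, age, age², sex×age, sex×age²
(`default_covariates()`). Age is mean-centered before the quadratic and
interaction terms are formed: with raw adult ages these four columns are
nearly collinear (r > 0.98) and single-term LRTs lose almost all their
power; centering is a pure reparameterization that changes neither the
fitted model nor joint tests. Beta values are analyzed untransformed — the
QC chain already removed probes incompatible with a Gaussian likelihood.

# SNP QC and the cis window

`genotype_qc()` filters on hard calls: call rate ≥ 0.95, non-monomorphic,
≥ 10 minor-allele carriers, and a founders-only chi-square Hardy–Weinberg
test at p ≤ 10⁻⁴ (a deliberate simplification of pedigree-aware HWE; the
threshold is preserved). Missing dosages are then replaced by the SNP's
observed mean dosage (expected dosage, 2 × allele frequency), which
preserves the SNP mean exactly; pedigree-aware genotype imputation is out
of scope. Reported MAF comes from founders.

`select_proximal_snps()` defines the cis window as a closed ±100 kb
interval around the CpG position — a SNP exactly 100,000 bp away is
included — and keeps the signed distance (SNP − CpG; negative = upstream).
Probes without coordinates are skipped and logged.

# Multiple testing

* `bonferroni_threshold(α, m) = α/m`; for the probe scans m is the number
  of analyzed probes (0.05/395 = 1.27×10⁻⁴ at this study's panel size).
* `li_ji_meff()` computes the effective number of independent tests from
  the eigenvalues of the SNP×SNP correlation matrix:
  `Meff = Σ f(|λ|)`, `f(x) = I(x ≥ 1) + (x − ⌊x⌋)`.
  `li_ji_correction()` applies it per chromosome on the post-QC dosage
  correlations (pairwise-complete) and sums the effective counts.
* The combined per-test threshold defaults to α/Meff (division). The
  method is usually described with a Sidak step, but the division
  threshold is what reproduces the printed values this pipeline is
  anchored to (α/4209 = 1.19×10⁻⁵, whereas exact Sidak gives 1.22×10⁻⁵);
  `combine_meff(mode = "sidak")` provides the exact form.
* `tail_area_fdr()` returns Benjamini–Hochberg step-up q-values scaled by
  Storey's null-proportion estimate at λ = 0.5, clamped to (0, 1]. The
  estimator counts `p ≥ λ` rather than `p > λ`: heritability p-values from
  the boundary mixture have an atom at exactly 0.5 and no mass above, and
  Pr(p ≥ 0.5) = 0.5 under both the uniform and the mixture null, so the
  estimator stays calibrated for both scan types. This is a simpler
  estimator than the Grenander-density tail-area implementation used by
  some packages; it targets the same quantity and is exactly testable.

# The synthetic study generator

The generator's defaults are the study conditions the pipeline is
validated under, not tuning knobs:

* **Pedigree** (`simulate_pedigree()`): 18 three-generation families — a
  founder couple, 4 children married to unrelated spouses, 2 children per
  couple (18 members each, 324 total) — with a phenotyped cohort of 183
  individuals sampled from the pedigree. Cohort subsampling is what makes
  the printed pair census attainable: 183 people with only 196
  first-degree pairs cannot all sit in complete nuclear families (any
  2-parents-k-children family carries ≥ 1.5 first-degree pairs per
  member). Expected cohort census ≈ 195 first-degree and 229 second-degree
  pairs against the printed 196 and 221; the calibration test accepts
  ±30%.
* **Ages** truncated normal (mean 42.15, sd 13.74, range 19–75), 55%
  female; **BMI** sex-specific means 31.21/33.38 (cohort 32.40, sd 7.40);
  **waist** 104.08/105.50 cm (cohort 104.86, sd 16.14). BMI and waist get
  an additive familial component (`pheno_h2` = 0.4 of residual variance —
  a typical anthropometric-trait value, chosen once) plus noise calibrated
  so the cohort sd matches; the between-sex mean difference is removed
  from the residual budget first.
* **Genotypes** (`simulate_genotypes()`): founder haplotypes from a
  Gaussian-copula AR(1) model (adjacent-locus correlation `ld_rho`,
  default 0.5 — enough linkage disequilibrium to exercise the Li–Ji
  correction), gene-dropped through the pedigree by whole-haplotype
  transmission, so offspring genotypes are Mendelian-consistent by
  construction. Default 3 SNPs inside every probe's cis window, MAF
  uniform on (0.05, 0.5).
* **Methylation** (`simulate_methylation()`): per probe a latent trait
  `y = g + a·dosage + b_age·age_std + b_sex·sex + e` with
  `g ~ MVN(0, h²·A)`, the cis coefficient set so the SNP explains q² of
  the unit genetic-plus-residual variance. `"bounded"` mode maps
  `logit(baseline) + 0.35·y` through the inverse logit, guaranteeing
  betas in (0, 1); `"latent"` mode returns the linear scale so
  variance-component recovery tests are exact. The default labeled panel
  (`probe_panel_default()`) has 10 heritable probes (h² = 0.6), 10
  cis-regulated (q² = 0.3), 10 age-affected and 20 pure-noise nulls.
* **Detection p-values** are drawn near zero with a 0.5% failure rate.

What the generator does *not* emulate: realistic genome-wide LD structure
(first-order only), probe cross-reactivity, batch or cell-composition
effects, non-Gaussian beta distributions beyond the logit squash, and
assortative mating or founder inbreeding. Green tests on synthetic data
therefore certify the statistical machinery — not robustness to those
real-data pathologies.

# Pipeline

`run_study()` executes sample QC → probe QC → heritability scan → cis
mQTL scan (with per-chromosome Li–Ji correction) → age and sex scans →
obesity scans → corrections and a tiered summary
(`summarize_proportions()`: nominal / FDR 5% / Bonferroni, with
percentages rounded to one decimal and mean ĥ² per tier). Identical
config + seed gives identical outputs. Thresholds all live in one named
list and every applied threshold is recorded in the report, so outputs are
self-documenting. `inst/scripts/run_study.R` wraps this as a command-line
entry point with a YAML config.

# Numerical and design notes

* h² is optimized on [0, 1−10⁻⁶]; σ²e > 0 is structural. Negative LRT
  statistics beyond −10⁻⁶ raise an optimization-failure error; smaller
  negatives clamp to 0.
* `eigen_relationship()` tolerates eigenvalues down to −10⁻⁸ and clips
  them at zero; anything lower is a PSD error.
* The CV-percentile uses R's default type-7 quantile; the exclusion rule
  is strict exceedance. Whether the original analysis computed the CV
  before or after other filters is not documented; the chain here fixes
  the order stated above and records it.
* Covariate screening is not performed: all default covariates stay in
  every model. The alternative reading (prune non-significant covariates)
  would change per-probe degrees of freedom; keeping the full set is the
  reproducible choice.
* Simulation problem sizes in the tests (e.g. 11-family/198-member
  pedigrees for recovery, 500-replicate power runs, 3,000-trio Mendelian
  checks) were chosen to give Monte-Carlo error comfortably inside each
  test's tolerance.

# Known limitations

* Single-trait models only: no bivariate genetic models, dominance or
  household components, and no linkage analysis.
* HWE on founders ignores pedigree information for the founders'
  descendants; with very few founders the filter loses power (it is
  skipped, with a warning, when no founders are genotyped).
* The boundary-mixture heritability test is conservative at realistic
  sample sizes (see above).
* Tail-area FDR uses BH × η̂₀ rather than a density-estimated local FDR;
  q-values can differ in the tails from density-based implementations.
* Trans-mQTL scans, LD pruning and conditional multi-SNP models are out of
  scope.
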