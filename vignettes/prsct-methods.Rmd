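---
title: "Methods: clumping + thresholding polygenic scores and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clumping + thresholding polygenic scores and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsct)
```

This vignette is the package's own account of the statistics it implements:
the model behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## The C+T model

A polygenic risk score summarizes an individual's load of trait-associated
alleles. Given discovery GWAS summary statistics (per SNP: effect allele A1,
odds ratio or beta, p-value) and a target genotype panel, the score at
inclusion threshold $p_T$ is

$$\mathrm{PRS}_i(p_T) \;=\; \sum_{j:\,p_j \le p_T} \beta_j\, x_{ij},$$

with $\beta_j$ the log odds ratio after harmonization and $x_{ij}$ the
A1-allele dosage. Two preprocessing steps make this sum well-defined:

* **Harmonization** aligns each summary-statistic record with the target
  panel's allele pair: direct match, swap (effect negated), strand complement
  (effect kept), or complement-and-swap (negated). Palindromic A/T and C/G
  SNPs are dropped unconditionally — without allele-frequency comparison the
  strand cannot be resolved, and frequency-based rescue is deliberately out
  of scope as the less conservative convention.
* **LD clumping** removes SNPs whose association signal is redundant with a
  stronger neighbour: processing SNPs by ascending p-value (ties by
  chromosome, position, id), each surviving SNP becomes an index and removes
  all later SNPs on the same chromosome within the physical window whose
  squared dosage correlation with it reaches the threshold. Defaults
  $r^2 \ge 0.1$ within 250 kb are the standard C+T settings. LD is measured
  in the target panel itself (genotype, not haplotype, correlation): no
  external reference panel or phasing is assumed.

Scoring is evaluated on a dense threshold grid — by default $p_T = 0$ to
$0.5$ in steps of $0.001$ (501 points, "high-resolution scoring"). Grid
arithmetic is done in integer multiples of the step so 501 accumulations
cannot drift; $p_T = 0$ is kept in the grid for completeness but flagged
unusable, since p-values are strictly positive and the empty score is not a
model. Scores accumulate incrementally (each SNP enters once, at its first
qualifying threshold), which both guarantees nestedness of the included SNP
sets and makes the full grid one pass over the data. Missing dosages are mean
imputed ($2\hat f_j$) rather than renormalized per sample, keeping the score
linear in the data.

## Association, incremental $R^2$, and the scan

For each phenotype the baseline model regresses the phenotype on the
covariate set (age, sex, two birthplace coordinates, genotyping batch one-hot
encoded with the first level as reference, and principal components); the
full model adds the PRS standardized to unit variance on the analysis subset.
Reported effect sizes are therefore per SD of score, and standardization is
affine so p-values and $\Delta R^2$ are unchanged by it (property-tested).
Rows with any missing value are dropped listwise before both fits, so each
phenotype carries its own n.

"Variance explained by the score" is the **incremental** $R^2$: full minus
baseline. For binary phenotypes both models are logistic and the Nagelkerke
pseudo-$R^2$

$$R^2_N = \frac{1 - \exp\{2(\ell_0 - \ell_1)/n\}}{1 - \exp\{2\ell_0/n\}}$$

is differenced instead; this matches the convention of the standard C+T
scoring tools. (The alternative reading of "adjusted from a baseline model" —
small-sample-adjusted $R^2$ — was rejected: it does not produce the reported
near-zero-but-positive percentages for weak scores, and incremental variance
explained is what the field's tools print.)

The high-resolution scan fits the incremental model at every usable
threshold and reports the maximizer of $\Delta R^2$, breaking ties toward the
smaller threshold (fewer SNPs, same fit). For linear models the scan is
computed by residualizing the phenotype and every score column against the
baseline design once (a single QR decomposition); per threshold the PRS
coefficient, its t-test and $\Delta R^2$ then follow in closed form. This is
algebraically identical to refitting the full model per threshold — an
equality the test suite asserts at $10^{-10}$ — and turns a 501-fit scan into
one matrix operation. Logistic scans refit per threshold.

Best-threshold selection is optimistic: under the global null the minimum
p-value over a scanned grid is stochastically smaller than uniform. The
package follows the convention of reporting the raw best-fit p-value and
leaves permutation correction to the user (a deliberate non-feature, matching
how such results are normally reported, with the study-wide significance
thresholds doing the multiplicity control instead). The default thresholds —
$2.1\times10^{-4}$ for main effects and $4.5\times10^{-4}$ for interactions,
both strict inequalities — correspond to Bonferroni-style control for testing
the most predictive score across ~19 phenotypes and are configurable in
`apply_significance()`.

**Interactions.** The sex-interaction model adds PRS, sex and PRS×sex to the
covariates and reads the Wald p of the product term; sex-stratified PRS
coefficients come from separate fits within each sex so they are estimates on
disjoint subsets, not reparameterizations of the pooled model.

**Quantile-effect curves.** Samples are ranked into K quantiles (default
K = 20, i.e. 5% bins); sizes differ by at most one, remainders go to the
lowest-index quantiles, and ties are broken by stable original order so the
assignment depends only on ranks (equivariance under monotone transformations
is property-tested). Each non-reference quantile is compared to the reference
by an indicator regression restricted to the two quantiles' samples, with the
full covariate set; binary phenotypes report odds ratios with
normal-approximation intervals on the link scale. "Central quantile" is
ambiguous for even K: the package defaults to quantile K/2 (the lower-middle
bin) and makes the reference configurable. A single-class binary subset
yields a flagged missing point rather than an error.

**Power.** The 1-df Wald chi-square of the PRS term under a true incremental
$R^2$ at sample size n is approximately non-central chi-square with
$\lambda = nR^2/(1-R^2)$; power is the tail probability beyond the central
critical value. This is documented as a non-centrality approximation built
for this package — not a port of any published power calculator — and is
cross-checked against Monte-Carlo simulation in the acceptance suite (±0.03
at three settings).

## Quality control

Defaults reproduce standard target-panel practice: SNPs fail on minor allele
frequency < 0.01, Hardy–Weinberg exact p < 10⁻⁸, or missingness > 0.02;
samples fail on missingness > 0.01 or pairwise relatedness > 0.088. The
filters are applied in a fixed, logged order (MAF → HWE → missingness for
SNPs; missingness → relatedness → external exclusions for samples) so the
per-filter removal counts are reproducible; the order itself was an open
choice and is fixed by convention here.

The HWE test is the exact conditional test: given the allele counts, the
heterozygote count has a known distribution, and the two-sided p sums the
probabilities of all configurations no more probable than the observed one.
The mid-p variant is *not* used — the plain sum is what mainstream QC tools
compute. Monomorphic SNPs return p = 1. The test is slightly conservative for
small n because the support is discrete; the calibration suite measures a
rejection rate of ≈0.045 at nominal 0.05 with n = 1,000, inside the ±0.01
acceptance band.

Relatedness uses the standardized method-of-moments estimator
$\hat K_{ik} = m^{-1}\sum_j (x_{ij}-2\hat f_j)(x_{kj}-2\hat f_j)/(2\hat
f_j(1-\hat f_j))$ with pairwise-complete missing handling. On this r-scale a
duplicate pair sits near 1 and a parent–offspring pair near 0.5, so the 0.088
default cuts around third-degree relatedness. Two practical caveats are
documented rather than hidden: in-sample allele frequencies shrink the
estimate by O(1/n) (visible in very small panels), and the estimator's
sampling noise is $\approx 1/\sqrt{m}$, so pruning at 0.088 needs a few
thousand SNPs before unrelated pairs stop triggering it by chance. Pruning is
greedy — repeatedly remove the individual in the most violating pairs, ties
broken by lower call rate then larger index — which is deterministic and
leaves no violating pair, though not always the minimum number of removals
(for small cliques it coincides with the brute-force optimum, as tested).
Reported-sex mismatch and ancestry filters require data the package does not
model (X chromosome, reference panels) and are supported as an external
exclusion-list hook instead.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. It
emulates the statistical structure of a large population-cohort PRS study —
a discovery GWAS of configurable size (default 55,374, with SNP-heritability
0.22, the scale reported for ADHD-like psychiatric traits) and a target
cohort with covariates (age 40–73, 53% female, birthplace coordinates,
genotyping batch, 15 PCs) — at desk scale: thousands of SNPs and samples
rather than the hundreds of thousands of a real biobank.

* **Genotypes.** Each individual is two haplotypes; each haplotype of an LD
  block is a latent AR1($\rho$) Gaussian vector thresholded at each SNP's
  allele-frequency quantile. This was chosen over a coalescent simulator
  because the implied LD is analytically controlled: adjacent-SNP $r^2$ can
  be checked against direct simulation of the two-variable latent model, and
  inter-block LD is exactly zero. Blocks are placed 1 Mb apart with ≤25 kb
  internal span, so a 250-kb clumping window never crosses blocks. Default
  block size 20 and $\rho = 0.7$ give realistic-looking within-block decay.
* **Effects.** Point-normal architecture: a configurable fraction of SNPs
  (default 0.2) is causal with i.i.d. normal effects on the standardized
  scale, normalized so $\sum\beta_j^2$ equals the target heritability. Each
  target trait's effects are $r_g\beta + \sqrt{1-r_g^2}\,\epsilon$ rescaled
  to the trait's own $h^2$, so the genetic correlation to the discovery trait
  is $r_g$ by construction. The real per-SNP architecture of psychiatric
  traits is unknown; point-normal is this package's choice.
* **Summary statistics.** Marginal estimates are truth plus
  $N(0, 1/n_{\rm disc})$ noise with Wald p-values, emitted as odds ratios on
  the allelic scale. By default allele pairs are non-palindromic so the
  pipeline is lossless; `palindromic_frac` injects strand-ambiguous SNPs to
  exercise the harmonization path.
* **Phenotypes.** Continuous traits are
  $\sqrt{h^2}\,g_{\rm std} + \text{covariate effects} + e$ with unit total
  variance; binary traits threshold the same liability at
  $\Phi^{-1}(1-\text{prevalence})$ (default 0.0214, an anxiety-disorder-like
  rate). Seven covariates carry fixed effects of 0.5% variance each —
  baseline adjustment matters but does not dominate.
* **Injections.** Uniform missingness, duplicate samples, and Mendelian
  parent–child resampling support the QC tests. Neither missingness nor
  relatedness is present by default.

What the generator does **not** emulate: realistic human LD maps and allele
frequency spectra, imputation uncertainty, the X chromosome, population
structure and admixture, ascertainment. Passing tests therefore demonstrate
the correctness and calibration of the algorithms, not that real-data effect
sizes would be reproduced; headline percentages from biobank-scale studies
depend on restricted data and are out of reach by design.

## Calibration findings worth knowing

Two behaviors surfaced during validation that are properties of the method,
not bugs:

* **Polygenic "null" traits are overdispersed.** If the target trait is
  heritable ($h^2 > 0$) but genetically uncorrelated with the discovery trait
  ($r_g = 0$), the PRS test at a fixed threshold still rejects above the
  nominal rate (we measured ≈0.15 at n = 5,000 with a 5,000-SNP panel). The
  reason: per dataset the realized inner product between score weights and
  causal effects is $O(1/\sqrt{m})$, not zero, inflating the z-variance by
  roughly $1 + nh^2/m_{\rm eff}$. Exact uniformity holds only when the target
  trait has no genetic component at all, which is what the package's
  null-calibration suite simulates ($h^2_{\rm target} = 0$; measured
  rejection ≈0.046–0.052 at nominal 0.05).
* **Scan optimism.** The best-threshold p-value is the minimum over a
  dependent family; it is anticonservative relative to a single pre-chosen
  threshold. The calibration suite therefore fixes a single threshold; the
  scan's optimism is a documented reporting convention.

## Problem sizes used in the validation suites

Chosen as the smallest sizes at which each property is sharply testable: the
clumping and scoring oracles run on hundreds of random instances of ≤10 SNPs
and ≤150 samples (where exhaustive re-derivation is exact); HWE calibration
uses 10,000 SNPs × 1,000 individuals; null and interaction calibrations use
2,000 replicate phenotypes over a fixed 5,000 × 5,000 panel and n = 1,000
respectively; the incremental-$R^2$ recovery uses the study-scale n = 50,000
with a 100-SNP panel (the estimator's accuracy is governed by n and the true
$\Delta R^2$, not panel size) over 20 seeds; quantile monotonicity uses
n = 50,000 with a true $\Delta R^2$ of 0.5%. Replicate phenotypes in the
calibration suites are drawn over a fixed genotype panel: under the null the
test statistic's distribution is the same whether or not genotypes are
redrawn, and fixing them keeps the suites fast.

## Known limitations

* Clumping LD comes from the target panel; using an external reference panel
  is not supported.
* No INDELs, no genome-build liftover, no frequency-based rescue of
  palindromic SNPs.
* Logistic scans refit per threshold and are correspondingly slower than the
  linear fast path; dense logistic scans on large cohorts should coarsen the
  grid.
* The greedy relatedness pruner does not minimize removals in general.
* `analytic_power()` is an NCP approximation; it agrees with Monte-Carlo
  power to ±0.03 in the tested range but is not an exact finite-sample
  calculation.
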