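---
title: "Covariate-selection metabolite GWAS across unequal cohorts: models and methods"
author: "MetaboGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-selection metabolite GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metabolite GWAS regresses each of a panel of continuous biomarkers —
typically NMR-resolved lipoprotein subclass lipids, fatty acids and
low-molecular-weight metabolites — on each genotyped variant. Two features
dominate the statistics of such screens. First, the panel is heavily
redundant: lipoprotein subclasses share most of their variance, including
near-duplicate pairs with r > 0.9. Second, the interesting comparisons are
often between a small patient cohort (hundreds of individuals) and a
biobank-scale reference (tens of thousands), which makes the small cohort
both underpowered and prone to winner's-curse inflation among the hits it
does produce.

This package implements the full chain: preprocessing and QC, a
covariate-selection regression that converts panel redundancy from a
multiple-testing nuisance into a power gain, LD-block summarization with
an effective-test threshold, cross-cohort effect comparison, and a
truncated-SVD decomposition of the resulting summary statistics.

# Association model

For outcome biomarker $Y_m$, variant dosage $G$ (minor-allele count
0/1/2), fixed confounders $C$ and proxy covariates $Y_l$ (a subset of the
other biomarkers):

$$Y_m \sim \beta_G G + \beta_C C + \beta_l Y_l$$

Ordinary least squares over complete cases, with $\beta_G$ inference from
the two-sided $t$ reference at residual degrees of freedom (not the
normal: at the sample sizes used for testing the difference matters). The
STD method sets $Y_l = \emptyset$; CMS selects $Y_l$ per (variant,
biomarker) pair:

1. **Admissibility mask.** Only biomarkers with pairwise-complete
   $|r| \le 0.9$ against the outcome are candidates (strict $>$ excludes;
   the boundary stays admissible, with a $10^{-9}$ numerical guard so the
   decision is stable under floating-point rounding). This removes
   same-subclass near-duplicates whose inclusion would soak up genuine
   signal. We apply the rule on transformed values; the raw-versus-
   transformed choice is immaterial for a rank-preserving transform at
   these correlation levels, but transformed is what enters the model.
2. **Variance rule.** Candidates with univariate $R^2 > 0.70$ against
   $Y_m$ are dropped.
3. **AIC ranking.** The rest are ranked by ascending AIC of the univariate
   model $Y_m \sim Y_l$ (on each candidate's complete cases) and at most
   30 retained. The univariate model is the only one computable before
   selection, and its AIC order coincides with descending explanatory
   power.
4. **Genotype-association screen.** A one-way MANOVA (Pillai) of the
   candidate set across genotype classes; while significant at
   $\alpha = 0.05$, the candidate with the smallest univariate $p$ against
   dosage is removed and the joint test repeated (a univariate $F$ test
   when a single candidate remains). Covariates correlated with the
   variant would bias $\hat\beta_G$ toward zero; this screen is what keeps
   CMS unbiased, and its type-I cost is only the occasional loss of a
   useful covariate. Results are insensitive to $\alpha$ in
   $[0.01, 0.1]$; $\alpha$ is exposed as `genotypeAssocAlpha`.

Confounders $C$ are always included and never screened. With no surviving
covariates CMS reduces exactly to STD — this identity is tested.

Under the null, $\mathrm{corr}(\hat\beta_\mathrm{STD},
\hat\beta_\mathrm{CMS}) = \sqrt{1 - R^2_\mathrm{cov}}$, so across *all*
pairs the two methods' estimates decorrelate exactly to the degree the
covariates absorb variance. Method agreement is therefore summarized over
significant pairs (where true signal dominates), which is also the
quantity such screens conventionally report; on the demo cohort it
exceeds 0.99.

# Preprocessing and QC

* **Inverse normal rank transform**:
  $\Phi^{-1}\big((r_i - 3/8)/(n + 1/4)\big)$ with average ranks for ties.
  The Blom offset 3/8 is the convention of the surrounding ecosystem; ties
  matter because NMR values are quantized by rounding. Missing values pass
  through; constant vectors are an error ("degenerate biomarker").
* **Variant QC**: remove MAF < 5%, missing rate ≥ 10%, or HWE $p <
  10^{-9}$. The HWE test is the 1-df chi-square against $p^2, 2pq, q^2$ at
  the sample allele frequency, with $p = 1$ for monomorphic SNPs. A
  chi-square rather than an exact test: the $10^{-9}$ screen only targets
  gross genotyping failures, where the asymptotic and exact tests agree on
  the decision. (The test suite quantifies the agreement against an exact
  multinomial enumeration oracle: within the regime where the asymptotic
  approximation claims validity — all expected genotype counts ≥ 5 and
  moderate $p$ — at least 90% of tables agree within 10% relative and all
  within 20% at totals ≤ 50; in the discrete tail the asymptotic $p$ can
  differ by orders of magnitude, which is inherent to the chi-square
  choice, not an implementation artifact.)
* MAF is recomputed per cohort after sample selection; QC is per-cohort.

# Region summary and multiple testing

LD blocks enter as half-open 0-based BED intervals; the package keeps
0-based half-open coordinates everywhere on disk and converts to 1-based
only at the PLINK `.bim` boundary. The most significant SNP per (block,
biomarker) represents the block; exact $p$ ties break by smaller position,
then lexicographic id; SNPs outside every block form singleton blocks.

The effective number of tests is the smallest $k$ such that the top-$k$
eigenvalues of the biomarker *correlation* matrix reach 99% of total
variance ("reach" read as cumulative proportion ≥ 0.99). Correlation
rather than covariance: transformed traits are unit-variance by
construction, so the two coincide, and correlation is robust if a caller
skips the transform. The genome-wide threshold is $5\times10^{-8}/k$, and
significance calls use strict $<$.

# Cross-cohort comparison

**Winner's curse.** Selected effect estimates are biased away from zero.
The correction is a summary-statistic parametric bootstrap, applied per
biomarker: draw $\beta^*_j \sim N(\hat\beta_j, se_j^2)$ for all records;
for each record selected in the original data (at the selection $p$
threshold), estimate its selection-conditional bias as the mean of
$\beta^*_j - \hat\beta_j$ over replicates where the record is again
selected in the same direction, and subtract it. Unselected records pass
through; `se` and `p` are never altered. The scheme shrinks
near-threshold hits strongly and leaves well-powered hits essentially
untouched (a $\beta = 1$, $se = 0.01$ hit moves by $< 0.005$). Default
100 replicates; deterministic given the seed.

**Heterogeneity.** Fixed-effect inverse-variance Cochran's Q with df = 1
for two cohorts (equal to $(\beta_1-\beta_2)^2/(se_1^2+se_2^2)$, an
identity tested to $10^{-12}$), $p$ from the chi-square survival function,
and $I^2 = \max(0, (Q - df)/Q) \times 100$, floored at zero. By
convention the small cohort enters with its winner's-curse-adjusted betas
(configurable), and the comparison set is the union of associations
significant in either cohort.

**Frequency tests.** The MAF comparison is a pooled two-proportion z-test
using *individual counts* as denominators. Allele-count denominators
($2n$) would be the textbook choice for allele frequencies, but the
individuals convention is what reproduces the reference analyses this
package mirrors (printed $p = 0.03$ and $0.04$ for the worked MAF pairs);
the discrepancy is documented here deliberately. Genotype-class
distributions compare by Pearson chi-square without continuity correction,
dropping classes absent in both cohorts; expected cells below 1 flag a
warning rather than aborting.

# Decomposition of genetic associations

From an association table, $z = \beta/se$ per (biomarker, variant) cell.
Cells with $p > 0.001$ or $se > 0.08$ are censored as unreliable, variants
censored everywhere are dropped, one lead variant is kept per LD block
(smallest $p$ across biomarkers), remaining missing cells become 0, and
each biomarker row is centered and scaled to unit variance. Zero-filling
*before* standardization is the framework convention this follows —
censoring then shrinks a biomarker's dense signal instead of deleting
rows; `standardizeBeforeFill` switches to the alternative order for
sensitivity analysis. The $se$ cutoff presumes biobank-scale standard
errors ($se \approx 0.03$–$0.07$ at $n \approx 2000$–$36000$); a
200-individual cohort has $se > 0.1$ everywhere and yields an empty
matrix, so the pipeline exposes both cutoffs and which cohort to
decompose.

The truncated SVD $W = U S V^\top$ is computed by dense LAPACK and
truncated to $k$ components (default $k = 24$, chosen in the reference
analyses as the smallest $k$ past 50% cumulative variance; the variance
report supports the same criterion here). Dense SVD is exact and
deterministic at the matrix sizes this package targets; implicitly
restarted Lanczos methods approximate the same leading factors for much
larger matrices. Sign convention: the largest-magnitude entry of each $U$
column is positive, $V$ flipped in step, so outputs are reproducible
across LAPACK backends.

Scores: factor scores $F = US$; contribution scores $u_{ik}^2$ (or
$v_{jk}^2$), summing to 1 per component by orthonormality; squared cosines
$f_{ik}^2 / \sum_{k'} f_{ik'}^2$, summing to 1 per entity, with all-zero
rows reported as missing. Top contributors per component are ranked by
$v_{jk}^2$ (ties by variant id) and exported as single-base 0-based BED
with the score in column 5, full precision, ready for region-enrichment
tools.

A caution established while testing: two planted biomarker clusters of
*equal* size produce two nearly equal singular values, and the
corresponding singular vectors are then an arbitrary rotation of the
cluster subspace — the decomposition is only identifiable up to rotation
within degenerate blocks. The planted-structure tests use clusters of
unequal size (8 vs 4 biomarkers) so the spectrum is well separated.

# The synthetic generator

`SimulationConfig()` defines the study conditions; `demoConfig()` is the
desk-scale preset used throughout the tests.

* **Genotypes.** Each allele copy derives from a latent Gaussian with
  equicorrelation `blockLdRho` (default 0.5) inside each LD block and
  independence across blocks; the allele is minor when the latent value is
  below the MAF quantile. Marginally each SNP is Binomial(2, maf) — i.e.
  Hardy-Weinberg — while block-mates are in LD. MAFs draw once from
  `mafRange` (default 0.05–0.45, the post-QC regime) and are shared by
  both cohorts; a per-SNP case-cohort override exists to create true
  frequency differences. Missingness is i.i.d. (default 2%, typical of
  array data after sample QC).
* **Biomarkers.** $Y = G B + C \Gamma + F \Lambda^\top + E$ with standard
  normal latent factors (default 2 factors, loading 0.7 in contiguous
  groups — the lipoprotein-subclass style of shared variance), unit
  residual noise, modest confounder effects, and planted genetic effects
  $B$ that may differ between cohorts. Duplicate pairs are realized as a
  copy plus 10% noise (r ≈ 0.995), giving the r > 0.9 exclusion rule
  something real to catch.
* **Cohort asymmetry.** Defaults are 875 cases vs 36,033 controls — the
  asymmetry that makes winner's-curse behavior reproducible. The demo
  preset scales to 200/2000 individuals, 300 SNPs in 30 blocks, 12
  biomarkers, one duplicate pair and 10 planted effects with |beta|
  0.2–0.5 of alternating sign; varying magnitudes are both realistic and
  necessary for effect-correlation summaries to be informative (noise
  around a single common effect value carries no correlation signal).
* **Determinism.** One root seed; every stream (per cohort, per stage)
  derives from it by stable tag hashing, so identical configs give
  byte-identical outputs while cohorts stay independent.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: realistic human LD maps and
recombination hotspots, imputation uncertainty, genotyping batch and plate
effects, NMR technical variation (assumed removed upstream), relatedness
and population structure, X-chromosome dosage, and non-Gaussian biomarker
tails beyond what the inverse normal transform removes.

# Problem sizes and numerical choices

Tests and the acceptance script run at deliberately small scale: the demo
study (200/2000 individuals, 300 SNPs, 12 biomarkers) for the end-to-end
properties; 2000 SNPs x 5 biomarkers for null calibration of the
inflation factor; 50 replicates of 10,000 summary-statistic pairs at the
875/36,033 standard-error regime for heterogeneity type-I; 100 seeds of
5000-record null-heavy mixtures for winner's-curse shrinkage; and a
30-variant two-cluster summary matrix for decomposition recovery. The
demo-scale pipeline relaxes the decomposition censoring (p < 0.01,
se ≤ 0.1) because the biobank-scale defaults empty a 300-variant matrix;
the clustered decomposition checks keep the defaults.

Other numerical conventions: dosage is always minor-allele count, and
recoding a SNP flips $\hat\beta$'s sign leaving $se$ and $p$ unchanged
(tested); rank-deficient designs are an error naming the collinear
columns; per-pair failures inside the scan become flagged rows rather than
aborts; monomorphic-in-analysis-set variants are errors at the single-pair
level and flagged rows at scan level; the genomic inflation denominator is
the exact null median `qchisq(0.5, 1)`.

# Known limitations

* The MANOVA screen needs more complete rows than candidates; degenerate
  fits fall back to keeping candidates, with a warning.
* The winner's-curse bootstrap treats records within a biomarker as
  independent; residual LD between lead SNPs mildly correlates their
  draws, which affects efficiency, not validity, of the bias estimate.
* The decomposition is reported for one cohort at a time; no joint or
  contrastive factorization.
* Bed-file genotypes load fully into memory; the package targets
  hundreds-of-thousands-of-variants scale, not whole-genome sequencing.
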