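---
title: "Estimating and partitioning SNP heritability with snpher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and partitioning SNP heritability with snpher}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpher)
```

## The model

`snpher` estimates the fraction of phenotypic variance that common SNPs
on a genotyping array tag jointly — SNP heritability, h²_SNP — and
partitions it across genomic components. The underlying mixed linear
model treats the aggregate effect of all SNPs as a random effect:

$$
\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{g} + \mathbf{e},
\qquad
\mathbf{g} \sim N(\mathbf{0}, \mathbf{A}_G \sigma^2_g),
\qquad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I} \sigma^2_e),
$$

with $\mathbf{A}_G$ the genetic relationship matrix computed from
standardized dosages,

$$
A_{jk} = \frac{1}{m} \sum_{i=1}^{m}
\frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)},
$$

and $h^2_{SNP} = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$. Fitting $C$
GRMs built from disjoint SNP sets replaces $\mathbf{g}$ by
$\sum_c \mathbf{g}_c$ and decomposes the estimate into per-component
shares — per chromosome, or genic versus intergenic DNA, or a pathway's
genes versus the rest of the genome.

Key modelling assumptions, inherited from the standard GREML formulation:

* effects are drawn on **standardized** genotypes, so each causal SNP
  contributes variance independent of its allele frequency;
* relatedness among analysed individuals is negligible (enforced by
  pruning), so $\mathbf{A}_G$ carries only distant realized kinship;
* phenotypes are adjusted and standardized beforehand; the only fixed
  effect inside the variance-component fit is an intercept.

## Workflow and parameters that matter

1. **SNP QC** (`apply_snp_qc`): missingness rate > 0.05, then MAF < 0.01,
   then exact HWE test P < 1e-6, each on the survivors of the previous
   filter. The order affects only the attribution in the QC report, not
   the retained set. The HWE test is the exact conditional
   (hypergeometric) test — the convention of PLINK, which array QC
   pipelines use — with a 1-df chi-square variant behind a flag.
2. **GRM + pruning** (`compute_grm`, `select_unrelated`): allele
   frequencies come from the analysis sample itself; missing dosages are
   mean-imputed (zero after centering), which keeps the estimator a
   single matrix cross-product; per-pair non-missing counts are recorded
   for diagnostics. The diagonal uses the same cross-product form; the
   within-individual correction of the original GREML software is
   available via `gcta_diagonal = TRUE` (the two coincide in expectation
   under HWE). Pruning removes, greedily by over-cutoff pair count (ties
   by smallest id), until no retained pair exceeds the cutoff. The
   default cutoff 0.025 is calibrated for arrays with hundreds of
   thousands of SNPs: the null spread of a GRM entry is
   $1/\sqrt{m}$, so at desk-scale $m$ (thousands) the cutoff must be
   scaled up or pruning degenerates into removing everyone.
3. **Phenotype preparation** (`adjust_and_standardize`): within each
   cohort × sex group, OLS of the trait on age, residuals z-scored with
   the $n-1$ SD. Age-only regression (no age²) follows the simple-
   regression convention; a group with constant age falls back to
   mean-centering with a warning; groups need ≥ 3 non-missing
   observations.
4. **REML** (`fit_reml`): see below.
5. **GWA and θ_P** (`gwa_scan`, `theta_p`): per-SNP simple regression on
   mean-imputed dosages; θ_P is the fraction of SNPs with p below a
   threshold, a whole-scan enrichment summary whose correlation with
   h²_SNP across traits peaks at an intermediate threshold that depends
   on sample size. The default threshold grid is 0.001 to 0.201 in steps
   of 0.005.
6. **Partitioning** (`partition_by_chromosome`, `fit_region_partition`):
   one GRM per SNP subset, all components fitted jointly. Region
   membership is inclusive within intervals padded by ±0/20/50 kb
   (padding clips at position 1). Per-chromosome genic/intergenic
   estimates default to a 3-component model per chromosome (that
   chromosome's genic SNPs, its intergenic SNPs, rest of genome) rather
   than a joint 44-component fit — the smaller fits are far better
   conditioned at desk scale, and the joint alternative is available by
   fitting the component list directly with `fit_reml`.

## The REML engine

The restricted log-likelihood (constants dropped) is
$\log L = -\tfrac12 (\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| + \mathbf{y}'\mathbf{P}\mathbf{y})$.
Maximization uses **average-information (AI) updates with EM fallback**:
the first step is an EM step (safe but slow), subsequent steps are AI
steps with step-halving toward the current point whenever the proposal
would decrease the likelihood, and a guaranteed-uphill EM step when
halving fails. This is the approach of the widely used GREML
implementations; the AI matrix doubles as the SE source at convergence.

Numerical choices:

* **Starting values**: every component at $\hat\sigma^2_P/(C+1)$ — a
  neutral equal split.
* **Boundary handling**: components are floored at $10^{-6}\hat\sigma^2_P$
  during iteration; a component pinned at the floor for three consecutive
  iterations is constrained to exactly zero and the remaining components
  re-maximized (without this, the iteration approaches the boundary only
  geometrically and wastes its iteration budget "crawling"). Constrained
  components are flagged and keep a reported SE from the final AI matrix
  over all components.
* **Convergence**: relative change in restricted log-likelihood below
  `tol` (default 1e-8). The accepted-step likelihood trace is stored and
  is non-decreasing by construction.
* **Single-component fast path**: with one GRM, the model is rotated into
  the GRM's eigenbasis where $\mathbf{V}$ is diagonal; the variance ratio
  is profiled out and maximized in one dimension. This is exact (the same
  likelihood), orders of magnitude faster at large $n$, and lets one
  eigendecomposition be reused across traits (`reml_table`). The AI path
  and the eigen path are cross-checked against each other and against a
  brute-force likelihood grid search in the test suite.
* **Non-PD $\mathbf{V}$**: jitter-and-retry (three escalating ridge
  additions), then a hard error.
* **LRT**: $2(\log L - \log L_0)$ against the 50:50 mixture of a point
  mass at zero and $\chi^2_{df}$ — the standard reference distribution
  for a variance component on its boundary; at LRT = 0 the p-value is
  0.5. The plain $\chi^2$ is available via `mixture = FALSE`. Whether the
  original analyses used the mixture is not documentable from the
  published numbers; the mixture is the defensible default and is what
  the null-calibration acceptance test validates.
* **h² SEs**: delta method on the ratio using the full AI covariance.
* **Missing phenotypes**: listwise deletion per trait, so per-trait $n$
  varies naturally.

## What the simulator emulates — and what it does not

`simulate_genotypes` draws each SNP's allele frequency uniformly on
(0.01, 0.5) — an **array ascertainment** spectrum, not a neutral-site
spectrum; the source cohort's true MAF distribution is not documented, so the uniform
choice is a modelling decision, configurable via `maf_range`. Dosages are
Hardy–Weinberg by construction. SNPs land on chromosomes proportionally
to physical length (human GRCh37 autosome lengths by default), positions
uniform. Relatives are made by copying an individual and redrawing half
the SNPs — roughly sibling-level relatedness, enough to exercise the
pruning path. Missing calls are completely at random.

`simulate_phenotype` draws causal SNPs per chromosome proportionally to
length (or per explicit component fractions), draws effects i.i.d.
normal on standardized dosages, scales the genetic score so its sample
variance **equals** the target h² exactly, and adds Gaussian noise plus
optional age/sex/cohort effects (defaults: 0.03 per year of age, 0.5 for
sex, 0.3 for cohort, on a unit-variance trait scale — visible but not
dominant nuisance structure). Defaults describe the cohort the analysis
model assumes: 5% of SNPs causal (diffuse polygenicity), h² = 0.15 (the
middle of the 0–0.32 range the per-trait analyses produce), 2% of
individuals in related pairs, 1% missing calls.

The generator deliberately omits: linkage disequilibrium (independent
SNPs keep the oracles exact, and the estimator is defined irrespective of
LD), imputed dosages, X-chromosome inheritance, case–control
ascertainment, and population stratification. A green test therefore
establishes correctness of the estimation machinery under the model's own
assumptions — it says nothing about robustness to LD-induced biases or
confounding, which are properties of real data that cohort-scale
analyses must address by design (ancestry filtering, relatedness
pruning).

## Determinism and seeds

Every simulator entry point takes a single master seed; each named
sub-draw (genotypes, covariates, each trait, the equal-SNP subsample)
derives its own 31-bit stream from the seed and a label hash, so cohorts
are bitwise-reproducible and adding a trait does not shift the genotype
stream.

## Degenerate inputs and tie-breaks

* Monomorphic SNPs reaching `compute_grm` are a contract violation
  (error); the pipeline re-screens frequencies after pruning because a
  SNP can become monomorphic in the reduced sample.
* Pruning ties (equal over-cutoff degree) break by lexicographically
  smallest sample id, making the retained set deterministic.
* A θ_P threshold where the across-trait θ values are constant yields an
  undefined correlation, recorded as `NA` and skipped by the argmax.
* Traits whose total genetic estimate is zero are excluded from
  across-trait aggregation (they carry no information about how genetic
  variance splits) — mirroring the exclusion of boundary-constrained
  traits in multi-trait summaries.
* In `variance_explained_top_snps`, two significant SNPs within the
  independence window keep only the more significant one; with LD-free
  simulated data this is conservative and documented behaviour.

## Known limitations

* AI-REML with many components (≈ 20+) at small $n$ can be
  ill-conditioned; estimates remain valid but SEs inflate. The
  per-chromosome partition at desk scale therefore carries wide SEs —
  conclusions should rest on across-trait aggregates, as in the original
  analyses.
* Aggregate SEs across traits are empirical SDs divided by √(number of
  traits); phenotypically correlated traits make these optimistic.
* The boundary-mixture LRT is asymptotic; at very small $n$ the
  null-calibration test tolerates the resulting few-percent deviation.
* The PLINK codec reads SNP-major v1 files only (magic `6c 1b 01`);
  individual-major files are rejected rather than transposed.
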