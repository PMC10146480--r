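---
title: "Methods: GREML heritability of late-onset disease and the liability scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GREML heritability of late-onset disease and the liability scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `snpher`, the choices
made where the design was genuinely open, and what the package's simulation
-based tests do and do not establish about real data.

## 1. The observed-scale model

Disease status is analysed as a 0/1 quantitative trait with the linear
mixed model

$$ y = X b + \sum_k g_k + e, \qquad
   g_k \sim N(0, A_k \sigma^2_k), \quad e \sim N(0, I \sigma^2_e), $$

where each $A_k$ is a genetic relatedness matrix built from a SNP stratum
with the standard estimator
$A_{jk} = \frac{1}{M}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}$,
allele frequencies taken from the analysed sample (cases and controls
jointly) and monomorphic SNPs removed. Observed-scale heritability is
$h^2_o = \sum_k \sigma^2_k / (\sum_k \sigma^2_k + \sigma^2_e)$.

Restricted maximum likelihood is maximised by average-information (AI)
updates after three expectation-maximisation warm-start iterations, with
step-halving whenever a proposed step would decrease the restricted
log-likelihood. Convergence is declared when the log-likelihood changes by
less than $10^{-6}$ (at most 100 iterations; a non-converged fit is
returned flagged, not thrown). Under the default constraint, components are
clamped to a floor of $10^{-8}\,\mathrm{Var}(y)$ rather than zero so the AI
matrix stays invertible; a floored component whose score still points
outward is removed from the AI step (an active-set rule), which is what
lets boundary optima (e.g. $\sigma^2_e \to 0$ on small, almost fully
genetic instances) converge cleanly. Standard errors come from the inverse
AI matrix, $h^2_o$'s standard error by the delta method. With a single GRM
the model is refit in the GRM's eigenbasis where the covariance is
diagonal; this spectral path maximises the identical restricted likelihood
at $O(n)$ per iteration after one eigendecomposition, and its agreement
with the dense path is tested. The likelihood-ratio test against
$\sigma^2_g = 0$ uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ for one component; multi-component
fits report a conservative $\chi^2_k$ for the joint test, documented as
approximate because the exact boundary mixture depends on the correlation
of the component estimates.

## 2. LD and MAF stratification (GREML-LDMS)

A single all-SNP GRM can misattribute variance when causal variants sit in
atypical LD. The LDMS variant computes, for every SNP, a segment-based LD
score — the sum of squared dosage correlations with all SNPs within a
200 kb window centred on the SNP (a sliding window; the self term is
included, so scores are at least 1) — then splits SNPs at MAF 0.05 and
each MAF group at its own LD-score quartiles (type-7 quantiles,
right-closed bins, a score equal to a boundary falling in the lower bin).
Up to eight strata result, each contributing one variance component.
Quartiles are recomputed within each analysed SNP subset, since they are
defined on the SNPs actually fitted; groups with fewer SNPs than bins or
tied quantiles collapse to fewer bins with a warning. A sliding window was
chosen over anchored tiles for translation invariance.

## 3. Region and gene-set filters

Coordinates are 1-based and inclusive internally; BED files are converted
at the boundary (start + 1). The APOE exclusion region is
chr19:44,400,000–46,500,000, and GWAS-hit exclusion removes SNPs within
0.5 Mb of each hit position; a SNP exactly at an (expanded) boundary is
excluded. The gene-set analysis fits the gene-set GRM alone, matching the
single-GRM practice it mirrors; a joint two-GRM partition is available
through `reml_fit()` with a list of GRMs and `h2_partition()`, and is an
extension rather than the default. Whether gene-set panels should exclude
APOE-region SNPs is not settled; `experiment_config(geneset_exclude_apoe=)`
offers both modes.

## 4. Liability scale, ascertainment and age

With population prevalence $K$, threshold $t = \Phi^{-1}(1-K)$, density
$z = \phi(t)$ and sample case proportion $P$, the ascertainment-corrected
transform is

$$ h^2_l = h^2_o \cdot \frac{K(1-K)}{z^2} \cdot \frac{K(1-K)}{P(1-P)}, $$

reducing to the classic $K(1-K)/z^2$ rescaling when $P = K$. For a
late-onset disease, controls much younger than the cases have not yet
expressed their risk: if a fraction $f$ of them is expected to convert, the
case proportion is first uplifted to $P_{actual} = P + f(1-P)$. The uplift
is applied to $P$ only; the source analysis speaks of adjusting the
observed heritability "accordingly" without defining an adjustment to
$h^2_o$ itself, and the $P$-only uplift reproduces the worked numeric
example exactly (0.56 → 0.626 → $h^2_l$ = 0.38 at $K$ = 0.15 from
$h^2_o$ = 0.30). A hook for an explicit $h^2_o$ correction can be added in
front of the transform by the caller. The pipeline reports liability
values at each requested prevalence from the same observed-scale fit, so
both raw-$P$ and uplifted-$P$ conversions are a single function call.

$K$ should match the cases' age. `age_onset_model()` carries the
age-to-prevalence mapping (below) and `prevalence_for_age()` evaluates it,
so the prevalence used in the transform can be tied to the cohort's mean
case age rather than chosen ad hoc.

## 5. The synthetic-cohort generator

No controlled-access cohort can ship with the package, so all calibration
runs on simulated data from an explicit generative model:

* **Genotypes.** Two haplotypes per individual from a latent Gaussian
  AR(1) process: within blocks of 20 consecutive SNPs the latent variables
  correlate at `ld_rho = 0.7` between neighbours, blocks are independent,
  and thresholding at the allele-frequency quantile yields the drawn
  marginal frequency (uniform on 0.01–0.5). SNPs sit every 5 kb on a main
  chromosome plus a chromosome-19 analog that starts exactly at the
  44.4 Mb region boundary. This is the simplest mechanism that produces a
  non-degenerate segment-LD-score distribution for LDMS binning.
* **Architecture.** Default liability heritability 0.5 (the centre of the
  range reported for confirmed-diagnosis late-onset Alzheimer's cohorts),
  of which 24% sits on one common major-locus SNP in the region analog
  (so that excluding the region removes about 12 percentage points, the
  average drop seen in practice), 60% on a gene-set occupying 3% of SNPs
  (the regime in which a microglia set explains most of the remaining
  heritability), and the rest on a polygenic background. Each component's
  sum of squared standardized effects is rescaled to its share exactly,
  and the realized genetic score is standardized to variance exactly
  $h^2$ (`exact_scale = TRUE`), which pins the variance decomposition even
  under LD between causal SNPs.
* **Age and onset.** Liability is standard normal; the threshold falls
  with age according to a cumulative prevalence $K(a)$ interpolated
  log-linearly between anchors (65, 2%), (75, 5%), (85, 15%) — the three
  prevalences used throughout the analyses. Onset age is the youngest age
  at which liability crosses the threshold. No true liability-to-onset
  process is known; this interpolation is a stand-in that is exact at the
  anchors, and it reproduces the qualitative signature that risk-allele
  frequency declines with age among the still-unaffected. Sex is a
  balanced covariate with zero true effect.
* **Ascertainment.** Cases are drawn among individuals already past onset
  at an assessment age drawn from the case age distribution; controls among
  those symptom-free at their drawn age. `screened = TRUE` additionally
  requires controls never to onset within the model's range (pathologically
  confirmed series); unscreened young controls therefore include latent
  cases, whose fraction the operation reports. A misdiagnosis rate swaps
  that fraction of case slots for unaffected individuals, keeping the case
  label. Two presets encode the contrasted designs: `age_matched`
  (screened, both groups ~N(80, 5)) and `age_mismatched` (old cases vs
  unscreened controls uniform on 50–62). The pre-ascertainment population
  is sized automatically with a binomial safety margin.

What the generator does **not** emulate: realistic genome length (at 5 kb
spacing the simulated chromosome is a few Mb, so the 0.5 Mb GWAS-hit
windows excise a much larger genome fraction than in real data — tests of
that comparison use 50 kb spacing instead), realistic LD decay in base
pairs, population structure and relatedness (simulated individuals are
unrelated; the PC machinery is exercised on explicitly divergent
subpopulations in tests), imputation error, and any diagnosis mechanism
beyond a label-flip rate. Passing tests therefore establish internal
consistency of the estimators under the stated model, not robustness to
everything real cohorts contain.

## 6. Calibration results and a known limitation

The test suite verifies, among others: exact reproduction of the worked
liability example; equality of the GRM with a naive double-loop
computation and of the REML optimum with a dense grid search of the
restricted likelihood; unbiased recovery of observed-scale heritability on
continuous traits (n = 800, m = 600, 30 replicates) with honest standard
errors; type-I control of the LRT at the nominal 5% level (200 null
replicates at n = 500); the directional phenomena (region-exclusion drop,
age-covariate attenuation in age-mismatched but not age-matched designs,
gene-set proportion recovery at the 70%/3% regime); and byte-identical
round trips of the PLINK and GCTA binary formats.

One calibration is deliberately reported even though it fails its
strictest form: simulating a liability $h^2$ of 0.5 at prevalence 5% and
ascertaining to half cases (n = 3000, m = 2000, 50 replicates) yields a
mean liability-scale estimate of about 0.39, not 0.5. This is not an
optimizer or transform defect — the same engine is mean-unbiased on
continuous traits, and a Haseman–Elston moment estimator on the identical
samples transforms to ≈0.48 — but the known attenuation of observed-scale
REML on strongly ascertained dichotomous traits: the Gaussian mixed-model
likelihood is misspecified for an oversampled 0/1 phenotype, and the
resulting downward bias grows with $h^2$, with ascertainment strength and
with sample size (Golan, Lander and Rosset, PNAS 2014). The package
implements the conventional GREML + transform chain faithfully and leaves
the calibration red rather than substituting a different estimator;
ratio-type quantities (the gene-set proportion of $h^2$, paired
region-exclusion drops) are far less affected because numerator and
denominator attenuate together — which is also why gene-set proportions
are nearly invariant across the assumed prevalence.

## 7. Numerical conventions

* Restricted log-likelihoods drop constant terms; the null model
  ($V = \sigma^2 I$) uses the same convention, so LRTs are internally
  consistent and the grid-search oracle in the tests evaluates the same
  expression independently.
* GRM output symmetrised as $(A + A^T)/2$; GCTA binary triples store the
  lower triangle in float32, so a written GRM re-reads bit-identically but
  matches the in-memory double only to single precision.
* PLINK `.bed` uses the SNP-major magic `6c 1b 01`, individuals packed four
  per byte, lowest-order bits first; dosages count the A1 allele.
* Eigenvector sign convention for PCs: the loading of largest magnitude is
  positive.
* Ties in LD-score binning: right-closed intervals, boundary values to the
  lower bin; empty or collapsed bins are dropped with a warning.
* Problem sizes in the shipped tests (hundreds to a few thousand
  individuals, hundreds to 2000 SNPs, 10–200 replicates per property) were
  chosen as the smallest sizes at which the Monte-Carlo bands are
  informative for each claim; `reml_fit()` itself is dense and intended
  for cohorts up to roughly 15,000 individuals.
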