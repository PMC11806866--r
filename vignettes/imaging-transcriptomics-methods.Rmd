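---
title: "Methods: linking cortical atrophy signatures to regional gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking cortical atrophy signatures to regional gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Behavioral-variant frontotemporal dementia (bvFTD) shows different spatial
patterns of cortical thinning depending on its genetic cause (C9orf72
repeat expansions, GRN or MAPT variants). Imaging transcriptomics asks
whether those spatial patterns co-locate with the normal regional
expression of particular genes: regions that atrophy more in one genetic
form may be regions that, in the healthy brain, express a particular gene
program more (or less) strongly. `cortexpls` implements that analysis as a
reusable, tested pipeline: atrophy signatures from subject-level cortical
thickness, a one-component partial least squares (PLS1) association with a
region-by-gene expression matrix, bootstrap-based gene selection, receptor
density mapping with dominance analysis, and permutation gene-set overlap
tests — plus a synthetic-data generator that plants known structure so
every stage can be validated against ground truth.

# Cortical atrophy signatures

## The w-score model

Per region, thickness is regressed on intercept, age and sex in the
control arm only (ordinary least squares). A subject's w-score in region
$r$ is

$$ w_r = \frac{t_r - \hat t_r(\text{age}, \text{sex})}{\hat\sigma_r}, $$

the covariate-adjusted deviation from the control prediction in units of
the control residual SD. The residual SD uses an $n-3$ denominator (three
fitted parameters), the unbiased choice and standard w-score practice.
W-scores are dimensionless, so they are invariant to a consistent
rescaling of the thickness unit (a tested property). Controls with missing
covariates are dropped with a warning rather than imputed. The control
model uses age and sex only; scanner model and intracranial volume are not
modeled (the interface carries no such covariates), a deliberate
simplification documented here.

## Contrast maps

The atrophy signature of a genetic form is the per-region t-statistic of
the group indicator in an OLS of w-scores on group (target form coded 1,
sporadic reference 0) and disease duration. The sign convention is
*target minus reference*: negative t means thinner cortex in the genetic
form. All regions share one design matrix, so the fit is a single
vectorized least-squares solve. If duration is constant (as in null
simulations) the column is dropped and the statistic reduces exactly to
the pooled two-sample t — the oracle used in tests. Duration enters only
at the contrast stage, not in the w-score model itself.

# PLS1 association

## Model

With $X$ the $n \times p$ (regions × genes) centered expression matrix and
$y$ the contrast map, PLS decomposes

$$ X = Z V^\top + E, \qquad y = Z b + e, $$

fitted by NIPALS with X-deflation. For a single response the first weight
vector has closed form $w_1 \propto X_c^\top y_c$ — the normalized
cross-covariance — which serves as an independent oracle in the tests
(agreement to $|\cos| \ge 1 - 10^{-8}$ on random instances, and against
mixOmics for deflated components). Components are sign-fixed so
$\mathrm{cor}(Z_1, y) \ge 0$. Variance explained is $100\times R^2$ of $y$
on $Z_1$. Only PLS1 is consumed downstream; further components exist via
deflation for diagnostics. Expression columns are centered (not z-scored)
by default because the expression matrix is assumed to arrive already
normalized across regions; z-scoring is available and changes weight
scales, not sign patterns, on well-conditioned data.

## Significance of the component

The variance explained is compared with a resampling null in which the
contrast values are re-drawn over regions while $X$ stays fixed:
`method = "permute"` (default) shuffles without replacement, preserving
the marginal distribution of $y$ and breaking only the pairing;
`method = "bootstrap"` resamples with replacement. Both are offered
because the literal description of the null ("bootstrapping the thickness
vector") changes $y$'s marginal distribution as well; permutation is the
cleaner null for the question actually asked, so it is the default. The
empirical p-value uses add-one smoothing,
$p = (1 + \#\{v^{null} \ge v^{obs}\}) / (1 + n_{iter})$, so it is never 0.

## Bootstrap gene statistics

Regions are resampled with replacement jointly in $X$ and $y$ (replicates
with fewer than 3 distinct regions are redrawn); PLS1 is refit per
replicate; each replicate weight vector is sign-aligned to the original
(flipped when the dot product is negative — without alignment the
component's sign indeterminacy inflates every SE). The per-gene SE is the
SD of aligned replicate weights, $z_j = w_j / SE_j$, and p-values are
two-sided normal tails.

One numerical choice matters a great deal here. Replicate weight vectors
are kept on the raw cross-covariance scale and divided by the norm of the
*original* cross-covariance — a single constant — rather than each being
normalized to unit length. Per-replicate normalization couples all genes
through a replicate-specific random factor and makes the z test strongly
anticonservative (we measured ~0.17–0.21 rejection at nominal 0.05 on
null instances); the constant scaling leaves $z$ equal to the plain
bootstrap ratio of the raw linear statistic, which is calibrated
(~0.05). The normal approximation is itself asymptotic in the number of
resampled regions: at the 100 regions this analysis is designed around it
is accurate, while below roughly 50 regions it becomes mildly
anticonservative — a known limitation.

Implementation note: a replicate's centered cross-covariance satisfies
$X_b^\top y_b - n\,\bar x_b \bar y_b = X^\top(c \circ y - c\,\bar y_b)$
with $c$ the resample count vector, so a whole chunk of replicates is one
BLAS matrix product; means and SDs accumulate by Welford updates. This is
numerically identical to a replicate-by-replicate refit (tested) and lets
the full-scale problem (15,633 genes × 5,000 replicates) run in bounded
memory.

## VIP and gene selection

Variable importance in projection:

$$ VIP_j = \sqrt{p \cdot \frac{\sum_k SSY_k (w_{jk}/\lVert w_k \rVert)^2}{\sum_k SSY_k}}, $$

which for one component reduces to $\sqrt{p}\,|w_j| / \lVert w \rVert$ and
satisfies $\overline{VIP^2} = 1$ exactly (a tested identity). PLS1+ genes
have positive weight, $VIP > 1$ and $p < 0.05$ (strict inequalities,
uncorrected — the convention this analysis follows); PLS1− analogously.
BH-FDR adjustment is available behind `adjust = "BH"`. Flipping the sign
of $y$ exactly swaps the two sets (tested).

# Receptor mapping

Spatial correlations between a contrast map and each receptor/transporter
density column use Pearson (default) or Spearman, with a parametric
t-based p-value by default and an optional region-shuffle null; BH-FDR is
applied across the receptors. Spatial-autocorrelation-preserving ("spin")
nulls are out of scope and the parametric p-values should be read
accordingly.

Dominance analysis decomposes the full-model OLS $R^2$ of the contrast
map on all $m$ receptors: for every one of the $2^m$ predictor subsets
the subset $R^2$ is computed from precomputed cross-products; predictor
$i$'s incremental contributions $R^2(S \cup \{i\}) - R^2(S)$ are averaged
within each subset size and then across sizes (total dominance), and
expressed as a percentage of the full-model $R^2$ (relative importance).
Total dominances sum to the full-model $R^2$ exactly — an additive
decomposition asserted on every run — and the implementation agrees with
a brute-force `lm()` oracle to $10^{-10}$ and with the closed form
$r_i^2$ for orthogonal designs. Receptor columns are z-scored before
regression purely for conditioning; $R^2$ is scale invariant, so results
are unchanged (tested). $m \le 20$ is enforced ($2^m$ fits).

# Gene-set overlap and over-representation

The pathology-overlap test draws `n_perm` random gene sets of the query's
size uniformly from the background universe (the expression matrix's gene
set), counting overlap with the target list; one-sided (enrichment)
empirical p with add-one smoothing. Target lists are intersected with the
background first, and both raw and restricted sizes are reported, since
externally published pathology lists predate that restriction. The
permutation null converges to the exact hypergeometric tail (tested at
$n_{perm} = 10^4$ against direct binomial-coefficient summation), which is
also exposed as `hypergeometric_tail()` and drives the local ORA:
per-term hypergeometric enrichment with BH-FDR across terms
(`q < 0.05`). `bh_fdr()` validates and delegates to the standard step-up
procedure.

# Cross-form comparison

Shared genes between two forms are the intersection of their significant
sets; a shared gene is concordant when its sign class (PLS1+/PLS1−)
matches. A gene significant in only one form is *not* shared. The module
also emits the all-forms intersection and an upset-style membership
matrix so plotting stays decoupled from computation.

# The synthetic-data generator

No subject-level MRI cohort or expression download ships with the
package, so the generator defines the study conditions the tests run
under:

* **Expression** — $X = S G^\top + \varepsilon$ with `n_latent` smooth
  spatial factors over a 1-D region ordering (sinusoids plus smoothed
  noise), emulating anterior–posterior expression gradients without
  needing cortical geometry. The first `n_planted` genes load
  predominantly on factor 1 with random signs (mean absolute loading 1.5
  vs background SD 0.3; noise SD 0.5), so a contrast aligned with factor 1
  has a known gene signature split across PLS1+ and PLS1−. Defaults mirror
  the study's shape: 100 regions; 15,633 genes at full scale, 2,000 in
  routine runs.
* **Cohort** — controls follow
  `thickness = baseline + age_slope (age - 60) + sex_effect·sex + noise`
  (baseline ≈ 2.5 mm with smooth regional variation, age slope
  −0.01 mm/yr, sex effect 0.08 mm, noise SD 0.15 mm); age ~ U(45, 80),
  sex ~ Bernoulli(0.5), disease duration ~ Gamma matched to mean 3.9 y /
  SD 2.7 y — the cohort's published demographics. Arm sizes default to
  172 controls / 117 sporadic, with genetic arms per form. The genetic
  arm is shifted by `effect × noise_sd × atrophy_map`: the truth object
  records `effect` in w-score units, and multiplying by the thickness
  noise SD is what makes the *w-scored* group difference equal
  `effect × atrophy_map`. The sporadic arm gets its own distinct smooth
  map at half that amplitude, so the genetic-vs-sporadic contrast is a
  contrast between two atrophy patterns, as in the real design. One
  genetic arm is generated per call; multi-form runs reuse the first
  call's control and sporadic arms.
* **Receptor atlas** — each column is
  $\rho\, z(\text{map}) + \sqrt{1-\rho^2}\, z(\text{noise})$ shifted to
  positive pseudo-density units, so its expected correlation with the
  atrophy map equals the target $\rho$; 15 columns across the five
  neurotransmitter systems by default.
* **Pathology lists** — exactly
  `round(overlap_fraction · |signature|)` signature genes plus a uniform
  background remainder, giving an exact planted overlap.

Every generator is bit-reproducible given its seed (seeds are recorded in
outputs), and all sampled quantities for one call come from one seeded
stream.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: genuine cortical geometry and its spatial
autocorrelation structure (the 1-D smoothness is a stand-in, not an
estimate), hemispheric asymmetry, donor-level microarray noise,
scanner effects, and any causal link between expression and atrophy
beyond the planted linear one.

# Orchestration, determinism and problem sizes

`run_pipeline()` executes signature → alignment → PLS → selection →
receptor mapping → enrichment → cross-form from one nested configuration
(R list or YAML), with the analysis defaults: 5,000 bootstrap replicates
for gene weights and the variance-explained null, 1,000 permutations for
pathology overlap, VIP > 1, p < 0.05, q < 0.05. Each randomized stage
derives its own seed deterministically from the master seed, and an
identical configuration reproduces every artifact byte for byte (tested).
The numbered scripts under `analysis/` run the same computations as a
narrative workflow, writing tables under `results/`.

Routine validation runs use 100 regions × 2,000 genes with 200 planted
genes, 1,000 bootstrap replicates and 1,000 permutations; null-calibration
checks use 500 cohort replicates at 20 regions and 50 seed replicates of
the gene-level null at 100 regions × 150 genes. These sizes are the
package's own choices: large enough that Monte-Carlo error is controlled
by the stated 3-SE bands, small enough to run routinely.

# Known limitations

* Gene-level p-values are uncorrected by default (the convention
  followed here); treat the selected sets as a ranking, not an
  error-controlled discovery list, or switch on BH.
* Parametric receptor correlation p-values ignore spatial
  autocorrelation; with smooth maps they are optimistic. The shuffle null
  helps; a spin-style null would be better and is out of scope.
* The bootstrap z test is asymptotic in the region count (see above).
* The PLS association is correlational: co-location of expression and
  atrophy does not imply causation, and regional expression here is an
  atlas average, not cohort-matched.
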