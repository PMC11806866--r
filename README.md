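# cortexpls

Imaging transcriptomics of cortical atrophy signatures with partial least
squares.

`cortexpls` is for researchers relating *where* a disease thins the cortex
to *which genes* are regionally expressed there. Given subject-level
regional cortical thickness, a region × gene expression matrix, receptor
density maps and pathology-related gene lists, it:

1. normalizes thickness to **w-scores** against a control model
   (`w = (observed − predicted(age, sex)) / residual SD`, per region) and
   derives a per-region case-control **t-statistic contrast map**
   (target group vs reference, adjusting for disease duration);
2. fits **PLS1** — the single partial-least-squares component of
   `X = Z Vᵀ + E`, `y = Z b + e` whose gene-weighted score maximally
   covaries with the contrast map (for one response, `w₁ ∝ Xcᵀ yc`) —
   tests its variance explained against a resampling null, bootstraps the
   regions for per-gene standard errors (`z = weight / SE`, two-sided p),
   computes **VIP** (`√p·|w|/‖w‖` for one component) and selects the
   **PLS1+ / PLS1−** gene sets (VIP > 1, p < 0.05);
3. maps the contrast to **receptor/transporter densities** by spatial
   correlation (BH-FDR across receptors) and **all-subsets dominance
   analysis** (total dominance sums exactly to the full-model R²);
4. tests PLS1 gene sets for overlap with **pathology-related gene lists**
   via a random-gene-set permutation null, with an exact hypergeometric
   tail as oracle, plus a local over-representation analysis for GMT
   collections;
5. compares selections **across genetic forms** (shared genes, sign
   concordance, upset-style membership).

A synthetic-data generator (`make_expression`, `make_cohort`,
`make_receptor_atlas`, `make_pathology_sets`) plants known structure —
signature genes on a latent spatial factor, a group atrophy effect in
w-score units, target receptor correlations, exact pathology overlaps —
so the whole pipeline is testable without access to cohort MRI or atlas
downloads. See the methods vignette
(`vignettes/imaging-transcriptomics-methods.Rmd`) for the models,
parameter choices and limitations.

## Worked example

The numbered scripts under `analysis/` run the full workflow on
synthetic study-condition data (100 regions × 2,000 genes, 200 planted
signature genes; 172 controls, 117 sporadic, genetic arms of 32/11/13):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_cortical_signature.R
Rscript analysis/03_pls_association.R
Rscript analysis/04_receptor_mapping.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_cross_form.R
```

Output (abridged) from one run:

```
w-score model: 172 controls, 100 regions; mean residual SD 0.152 mm
[C9orf72] contrast: 100 regions, df = 146, mean t = -0.08, min t = -16.52
[C9orf72] PLS1 explains 90.7% of the contrast map (permutation p = 0.000999);
          189 PLS1+, 192 PLS1-; planted-gene sensitivity 1.00, precision 0.52
[GRN]     PLS1 explains 25.4% of the contrast map (permutation p = 0.016);
          247 PLS1+, 252 PLS1-; planted-gene sensitivity 0.96, precision 0.38
[C9orf72] strongest spatial correlation: 5HT1A (serotonin) r = +0.53 (q = 2.64e-07);
          top dominance: 5HTT (18.2% of full-model R^2 = 0.64)
[GRN vs tdp43_synthetic] observed overlap 138 (chance expectation 99.8), permutation p = 0.000999
[GRN vs tau_synthetic]   observed overlap 83 (chance expectation 99.8), permutation p = 0.985
shared across all 3 forms: 308 genes; pairwise concordance C9orf72-GRN 1.00; ...
```

Read: the large genetic arm recovers the planted gene signature
essentially completely (sensitivity 1.00) with precision well above the
10% planted base rate; the synthetic "TDP-43" list (40% planted overlap)
is detected as enriched while the near-null "tau" list correctly is not;
the receptor maps with large planted correlations dominate the R²
decomposition; and the three forms — planted on the same latent factor —
agree in sign for every shared gene. Tables land under `results/`.

The same computation is available as a single call:

```r
library(cortexpls)
res <- run_pipeline(list(seed = 1L), outdir = "results/run")
```

with every default (5,000 bootstraps, 1,000 permutations, VIP > 1,
p < 0.05, q < 0.05) overridable through a nested list or YAML file.

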