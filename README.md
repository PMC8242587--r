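# immunophen

Immunogenomic phenotyping of bulk tumor expression cohorts.

Bulk tumor profiles are mixtures of tumor cells and the immune/stromal cells
that infiltrate them. A recurring analysis arc — developed most thoroughly in
glioma, where the microenvironment is strongly immunosuppressive — scores
each sample for immune infiltration, stratifies the cohort into
immune-high/middle/low (immune-H/M/L) phenotypes, and asks how the strata
differ in mutations, survival and predicted drug response. `immunophen`
implements that arc end to end for anyone working with gene × sample
expression tables, MAF-like mutation tables and clinical outcome data:

* **ssGSEA** — single-sample gene set enrichment, implemented from scratch.
  For a ranked sample with rank values $v_i = N - i + 1$ the score of a set
  $G$ is $\sum_i (P_{in}(i) - P_{out}(i))$, where
  $P_{in}$ is the $v^\alpha$-weighted in-set CDF and $P_{out}$ the
  unweighted out-of-set CDF ($\alpha = 0.25$). Verified against an
  exhaustive direct-summation oracle.
* **ESTIMATE-style scores** — stromal + immune enrichment, their sum, and
  tumor purity via the cosine calibration
  $\cos(0.6049872 + 1.467884\times 10^{-4}\,\mathrm{ESTIMATE})$.
* **Phenotype classification** — Ward/Euclidean hierarchical clustering of
  z-scored enrichment profiles, cut at k = 3, clusters ordered by mean
  enrichment into immune-H/M/L; PCA projections for separation diagnostics.
* **Deconvolution** — NNLS or ν-SVR estimation of immune cell-type fractions
  against an LM22-style signature matrix, on the unit simplex.
* **Mutation statistics** — TMB (mutations/Mb), the MATH heterogeneity score
  ($100 \times 1.4826\,\mathrm{MAD}/\mathrm{median}$ of VAFs), recurrent-site
  counts (N > threshold), and Pearson chi-square contingency tests.
* **GET signature** — derivation of an exhausted CD8+ T-cell signature by
  PDCD1-anchored Pearson correlation filtering (BH-adjusted p < 0.05,
  |r| > 0.25, intersected across cohorts), ssGSEA scoring, median split.
* **Survival** — Kaplan–Meier/log-rank contrasts (overall + pairwise) and
  uni/multivariable Cox hazard tables (Breslow ties, collinearity flagged).
* **Drug response** — closed-form ridge regression of log IC50 on cell-line
  expression with 10-fold CV over a λ grid, transfer to tumor samples, and
  ANOVA / Kruskal–Wallis comparison across phenotypes.
* **Synthetic cohorts** — a generator that plants purity, cell fractions,
  phenotype labels, VAF distributions, survival hazards and IC50
  coefficients, so every stage is testable with known ground truth.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `plot_*()` / `autoplot()` helpers.

## Worked example

Simulate a 300-sample cohort with a planted infiltration gradient, score it,
classify it, and contrast survival:

```r
library(immunophen)

co   <- simulate_cohort(cohort_config(seed = 1))
sets <- simulate_gene_sets(co$truth)
enr  <- ssgsea_scores(co$expression, sets)
lab  <- classify_phenotypes(enr)
table(lab$phenotype)
#> immune-L immune-M immune-H
#>      120      120       60
```

The classifier recovers the planted 40/40/20 split. ESTIMATE-style scores
track the planted non-tumor content:

```r
est <- estimate_scores(co$expression, sets$stromal, sets$immune)
head(est, 3)
#> # A tibble: 3 × 5
#>   sample stromal_score immune_score estimate_score purity
#>   <chr>          <dbl>        <dbl>          <dbl>  <dbl>
#> 1 S0001           173.         195.           368.  0.791
#> 2 S0002           109.         121.           230.  0.803
#> 3 S0003           134.         108.           242.  0.802

correlate_scores(est$estimate_score, 1 - co$truth$purity[est$sample])
#> # A tibble: 1 × 3
#>   pearson_r   p_value     n
#> 1     0.966 2.40e-177   300
```

The ESTIMATE score correlates at r = 0.97 with the true non-tumor fraction.
The planted hazards (immune-H carries twice the immune-L hazard) surface in
the log-rank contrasts:

```r
km <- km_logrank(co$clinical, lab)
km
#> log-rank test: chi-square = 36.97, df = 2, p = 9.38e-09
km$pairwise
#> # A tibble: 3 × 4
#>   group1   group2   statistic       p_value
#> 1 immune-L immune-M     15.8  0.0000710
#> 2 immune-L immune-H     36.4  0.00000000163
#> 3 immune-M immune-H      6.45 0.0111
```

Contingency statistics across phenotypes use the same machinery as the
published cohort tables:

```r
tab <- phenotype_feature_table(lab, tibble::tibble(
  sample = co$clinical$sample,
  idh = ifelse(co$truth$purity[co$clinical$sample] > 0.7, "MT", "WT")))
chi_square_test(tab)
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#> 1       175     2 9.98e-39
```

`run_pipeline()` chains all stages from one YAML or list configuration and
writes per-stage tables plus a self-describing JSON manifest. See the
methods vignette (`vignettes/immune-phenotyping.Rmd`) for the models,
parameter rationale, and what the synthetic cohorts do and do not emulate.

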