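---
title: "Immunogenomic phenotyping of bulk tumor cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogenomic phenotyping of bulk tumor cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunophen)
```

# The problem

Bulk tumor expression profiles are mixtures: each sample blends one tumor
expression programme with the programmes of the immune and stromal cells that
infiltrate it. In glioma — an immunologically "cold" tumor where checkpoint
blockade has under-delivered — quantifying that infiltration, stratifying
cohorts into immune-high/middle/low (immune-H/M/L) phenotypes, and relating
the strata to mutations, survival and drug response is a standard analysis
arc. `immunophen` implements that arc as composable, tested, tidyverse-native
functions: every stage takes a data frame and returns a tibble, so the whole
pipeline chains with the pipe, and every stage can be validated against
synthetic cohorts whose ground truth is known.

# The models and procedures

## Single-sample enrichment (ssGSEA)

For one sample, rank all $N$ genes by expression, descending, and give the
gene at position $i$ the rank value $v_i = N - i + 1$. For a gene set $G$,
walk down the list accumulating a weighted in-set empirical CDF and an
unweighted out-of-set CDF:

$$P_{in}(i) = \frac{\sum_{k \le i,\, g_k \in G} v_k^{\alpha}}
                   {\sum_{g \in G} v_g^{\alpha}}, \qquad
  P_{out}(i) = \frac{\#\{k \le i : g_k \notin G\}}{N - |G|},$$

and score the set as $\sum_i \left(P_{in}(i) - P_{out}(i)\right)$ — the sum
over the full walk, not the maximum deviation, so the score reflects whether
the set's genes are *coherently* shifted up or down. Because only ranks
enter, the score is invariant under any strictly increasing transform of the
sample's values, which is why the pipeline is indifferent to TPM vs
log-intensity inputs. Ties are broken by gene identifier after expression, so
results do not depend on platform sort stability. The rank-weight exponent
defaults to $\alpha = 0.25$, the conventional choice; $\alpha = 0$ weights
all in-set genes equally. The implementation is verified exactly (to float
round-off) against an exhaustive direct-summation oracle over every placement
of up to 3 set genes among up to 8 ranks.

`normalize_enrichment()` divides all scores by the global max–min range. The
transform is monotone and deliberately *not* idempotent; a `normalized` flag
guards accidental reapplication with a warning.

## ESTIMATE-style scores and tumor purity

The stromal and immune scores of a sample are the unnormalized ssGSEA scores
of two signature gene lists; their sum (the ESTIMATE score) proxies total
non-tumor content, and purity is the cosine transform

$$\text{purity} = \cos(0.6049872018 + 0.0001467884 \cdot \text{ESTIMATE}),$$

clamped to $[0, 1]$ with a warning (the raw cosine leaves the valid range for
extreme scores). The constants are the published calibration of this
transform and are exposed as arguments; with the defaults, a score of 0 maps
to purity 0.8225. The real 141-gene stromal/immune signatures are not
reproduced here — the gene lists are inputs, and synthetic meta-sets stand in
for them in tests.

## Phenotype classification

`classify_phenotypes()` z-scores each gene-set row of the enrichment matrix
(putting heterogeneous signature scales on an equal footing), clusters
samples agglomeratively with Ward linkage on Euclidean distances, cuts at
$k = 3$, and orders the clusters by mean z-scored enrichment: highest =
immune-H, lowest = immune-L. Ward was chosen because it is the conventional
linkage for immune-subtype work and is fully deterministic — no random
initialisation, so identical input gives identical labels. Ties between
cluster means are broken by cluster size then cluster id, with a message.
Whether to cluster raw or normalized scores is left to the caller; both give
identical results because z-scoring absorbs any global rescaling.

`pca_projection()` centers features and projects samples onto the top
singular directions, fixing each component's sign so its largest-magnitude
loading is positive (a deterministic convention; PCA signs are otherwise
arbitrary).

## Deconvolution of cell fractions

`deconvolve()` estimates the composition of each mixture over the columns of
a signature matrix (the role an LM22-style leukocyte matrix plays in
practice). Mixture and signature columns are restricted to shared genes and
z-scored over them, and a non-negative weight vector minimising the squared
residual is found by NNLS (default; deterministic) or by linear
$\nu$-support-vector regression over $\nu \in \{0.25, 0.5, 0.75\}$, keeping
the lowest-RMSE fit. One subtlety matters: solving in z-space returns weights
$w_c = f_c \cdot \mathrm{sd}(S_c)/\mathrm{sd}(b)$, so the weights are divided
by each signature column's standard deviation *before* renormalising to the
simplex. Without that back-transform, fractions would be biased by column
scale; with it, noiseless mixtures are recovered to machine precision and
fractions are invariant to positive rescaling of a sample. Degenerate
all-zero fits fall back to uniform fractions with a warning rather than an
error, since one pathological sample should not kill a cohort run.
No per-sample permutation p-value is computed — the analyses downstream use
fractions only.

## Mutation statistics

* **TMB** — somatic records per megabase. The capture size is configurable
  (default 38 Mb, the usual exome convention) because published analyses
  rarely state their denominator; the variant-classification filter defaults
  to *all records* for the same reason, with an include-list option.
  `log2(TMB)` uses pseudocount 0 by default, reporting zero-burden samples as
  missing on the log scale.
* **MATH** — $100 \times 1.4826 \cdot \mathrm{MAD}/\mathrm{median}$ of a
  sample's variant allele fractions; the 1.4826 normal-consistency factor is
  fixed by convention. The ratio is scale-invariant and increases under
  mean-preserving spread.
* **Recurrent sites** — keyed by (chromosome, 1-based position) with a
  *strict* threshold (`count > min_n`), matching the $N > 5$ convention.
* **Contingency tests** — Pearson chi-square without continuity correction,
  expected counts from the margin product. Feature-by-phenotype tables order
  rows L, M, H and keep feature levels in first-seen order.

## The exhausted CD8+ T-cell (GET) signature

`derive_get_signature()` Pearson-correlates every candidate gene with the
anchor gene (`PDCD1`, the PD-1 gene) across samples, within each cohort;
p-values are Benjamini–Hochberg adjusted within cohort; a candidate passes at
`adjusted_p < 0.05` and `|r| > 0.25`; and the final signature is the
intersection of the per-cohort passing sets. Two open choices were resolved
as follows. First, the correlation reference: the procedure is anchored on
PDCD1 expression itself, the reading most consistent with an exhaustion
programme driven by distinct PD-1 upregulation (and with PDCD1 appearing in
the canonical 5-gene outcome — PDCD1, CD27, ICOS, RUNX2, CXCR6); the anchor
is a parameter, so any other reference variable can be substituted. Second,
multiple-testing adjustment is per cohort, not pooled, since each cohort is
an independent screen whose passing set enters an intersection. Both
thresholds are exclusive bounds, so tightening either can only shrink the
signature — a property the tests enforce.

`get_score()` is the one-set ssGSEA score with a median split (ties to the
low group, deterministically), and `correlate_scores()` provides the
Pearson-with-t-transform used to relate the GET score to the
microenvironment scores.

## Survival

Kaplan–Meier product-limit curves and the log-rank chi-square (overall and
all pairwise contrasts for three or more groups) come from the `survival`
package, cross-checked in the tests against a hand-tabulated
observed-minus-expected computation. Cox models use Breslow tie handling
(the simple, standard default; nothing in the analyses is sensitive to it at
the tie rates involved). Collinear terms — e.g. a grade level that is an
exact alias of a histology level — are flagged and reported with missing
hazard ratios rather than raised, mirroring how such rows appear as NA in
published cohort tables.

## Drug-response prediction

`train_ridge_model()` follows the cell-line-to-tumor transfer recipe:
drop the lowest-variance genes (default: bottom 20%), standardize the rest by
training mean/sd, choose the penalty $\lambda$ from a 25-point log-spaced
grid in $[10^{-3}, 10^3]$ by 10-fold cross-validated RMSE (fold assignment
seeded and recorded, so selection is reproducible), and solve the closed form
$(X^\top X + \lambda I)^{-1} X^\top y$ with an unpenalized intercept. No
iterative solver is involved, so coefficients match the closed form to
round-off at every $\lambda$, and $\|\beta\|_2$ is non-increasing in
$\lambda$. Tumor samples are standardized by the *training* parameters only —
no cross-cohort batch correction is attempted, which is the documented
simplification of the cited transfer approach; model genes missing from a
tumor matrix are imputed at the training mean (standardized 0), with a hard
error below 50% gene overlap. `compare_response()` applies one-way ANOVA or
Kruskal–Wallis by phenotype; in `"auto"` mode a per-group Shapiro–Wilk gate
at $\alpha = 0.05$ picks ANOVA only when every group looks normal (the
normality gate is rarely stated in this family of analyses; Shapiro–Wilk is
the one implemented).

# The synthetic-data generator

Every stage is validated against `simulate_cohort()`, which generates
expression as a purity-weighted mixture:

$$x_{gj} = \rho_j T_g + (1 - \rho_j) \sum_c f_{cj} C_{gc},
  \quad\text{then}\quad x_{gj} \leftarrow x_{gj} \cdot e^{\varepsilon},\;
  \varepsilon \sim \mathcal{N}(0, \sigma),$$

with $T$ a shared log-normal tumor profile, $C$ one profile per cell type
whose markers are elevated 8-fold, $f$ Dirichlet cell-type fractions, and
purity $\rho_j$ one minus a Beta draw centred on the planted phenotype's
infiltration level. Generation is on the linear scale and non-negative;
log-transforming is the consumer's choice, and the rank-based stages are
invariant to it.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 300 | a mid-sized cohort |
| `n_genes` | 1000 | enough rank resolution for stable enrichment scores |
| `phenotype_proportions` | 0.4 / 0.4 / 0.2 | the roughly 40/40/20 L/M/H split of large glioma cohorts |
| `infiltration_levels` | 0.10 / 0.30 / 0.60 | low/moderate/high non-tumor content |
| infiltration Beta concentration | 250 | planted groups ~7–10 sd apart: a *well-separated* planting, which is the premise of the recovery experiments |
| composition Dirichlet concentration | 25 | within-compartment composition CV ≈ 18%, so the infiltration gradient, not composition jitter, dominates every immune signature — matching the structure in which all immune signatures order H > M > L |
| `noise_sd` | 0.2 | ~20% multiplicative expression noise |
| `vaf_beta_params` | (2, 5) | right-skewed VAFs, mean 2/7, typical of impure tumors |
| `hazard_multipliers` | 1 / 1.4 / 2.0 | immune-H carries about twice the immune-L hazard, matching the univariable phenotype hazard ratios reported for large glioma cohorts |
| `base_median_survival` | 24 months | glioma-scale overall survival |

Survival uses exponential times with administrative censoring at the 75th
percentile of the drawn times, guaranteeing both events and censorings in
every cohort. Mutation tables draw VAFs from the Beta and convert to read
counts at fixed depth by rounding, so the realised VAF matches the draw to
half a read. Cell-line training data make log IC50 exactly linear in a known
set of effect genes plus Gaussian noise, recording the true coefficients.
`simulate_get_cohorts()` plants candidates at an exact Pearson correlation
with the anchor using shifted Gaussians, naming the planted genes after the
canonical exhaustion partners so the derivation can be checked by name.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: platform batch effects (microarray vs RNA-seq
harmonization is out of scope), gene–gene co-expression beyond the mixture
structure, copy-number-driven expression, clonal structure in VAFs (each
variant is independent), non-proportional hazards, and any relationship
between a gene's variance and its biological role. Recovery results here are
*correctness* checks of the machinery under a known model, not effect-size
claims about glioma.

# Numerical choices and degenerate inputs

* ssGSEA tie-break: stable sort by (expression desc, gene id asc); a set
  covering the whole universe is an error (the out-of-set CDF is undefined);
  empty-intersection sets are dropped with a warning in batch mode.
* Duplicate gene rows on file read collapse by maximum — deterministic and
  scale-free for the rank-based consumers. Missing expression values are
  rejected outright; ranks are undefined on missing data.
* Purity clamping to $[0,1]$ warns; constant enrichment matrices refuse to
  normalize; constant bulk samples deconvolve to uniform fractions with a
  warning; median-split ties go to the low group; zero-depth MAF records are
  excluded from VAF statistics.
* The chi-square test requires positive margins and integer counts; the MATH
  score requires at least two VAFs in $(0, 1]$.

# Problem sizes in the test-suite experiments

The recovery experiments run at sizes chosen to make the statistical
properties sharp while keeping the default suite quick: phenotype recovery on
20 cohorts of 300 samples x 1000 genes (adjusted Rand index vs planted
labels, observed ≥ 0.97); deconvolution on 50 noisy mixtures at 5%
multiplicative noise (mean absolute fraction error ~0.003); GET derivation on
20 paired 200-sample cohorts at planted r = 0.6 (sensitivity = specificity
= 1); ridge on 150 training / 50 held-out lines with 100 genes (held-out
r > 0.99; the variance pre-filter is disabled in the recovery experiments
because the generator assigns effects independently of variance, and an
earlier design with 100 training lines x 100 genes sat at the p = n
interpolation threshold where small-$\lambda$ ridge generalizes worst);
Cox recovery of a planted hazard ratio of 2 at n = 1000.

# Known limitations

* The ESTIMATE-style purity transform is a fixed cosine calibration; on
  cohorts whose score scale differs substantially from the calibration
  cohort, purity should be read as a monotone index, not an absolute
  fraction.
* Deconvolution is relative (simplex) mode only; absolute scoring and
  reference construction are out of scope.
* The classifier always returns exactly `k` clusters; it does not assess
  cluster stability (no consensus clustering or bootstrap).
* Ridge transfer assumes the training and target expression are comparable
  after per-gene standardization; strong platform effects violate that.

# A worked mini-run

```{r example, eval = FALSE}
library(immunophen)
co   <- simulate_cohort(cohort_config(seed = 1))
sets <- simulate_gene_sets(co$truth)
enr  <- ssgsea_scores(co$expression, sets)
lab  <- classify_phenotypes(enr)
est  <- estimate_scores(co$expression, sets$stromal, sets$immune)
km   <- km_logrank(co$clinical, lab)
glance(km)
```
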