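# cortexfate

Variation analysis of neural directed-differentiation outcomes from targeted
gene-expression panels.

Differentiating human pluripotent stem cells (PSCs) toward cerebral cortex
is reproducible on average, but individual differentiations drift along the
dorsoventral and rostrocaudal axes of the developing brain — toward
ventral-forebrain (LGE/MGE), mid/hindbrain or hypothalamic identities — and
PSC lines differ reproducibly in how often and in which direction they
drift. `cortexfate` is for labs that audit many differentiations with
nCounter-style probe panels and want that audit to be quantitative,
reproducible and statistically calibrated.

## What it computes

* **Normalization & QC** — background subtraction by the geometric mean of
  the negative control probes; positive-control and housekeeping
  normalization factors $p_s = R_P / P_s$, $h_s = R_H / H_s$ (dataset
  geometric-mean reference); removal and one-pass re-normalization of
  samples with factors outside $[0.25, 4]$; the "expressed above 30
  normalized counts in at least one sample" gene filter; log2 transform;
  bridge-sample merging of datasets from two codesets.
* **Variation analysis** — gene-centered PCA with Z-scored loading
  contributors ($|Z| > 2$), hierarchical clustering on the Pearson
  correlation distance $1 - r$ with size-ordered labels, early-to-late
  marker correlation tables, and the correlation-of-correlations summary of
  co-expression module persistence.
* **Regional-outcome classifier** — a five-class marker decision tree
  (dorsalized, partially/highly ventralized, partially/highly caudalized)
  over FOXG1, DLX5, NKX2-1 and PAX6 log2 cutoffs; cutoff re-derivation from
  paired early/late data by exhaustive midpoint search; per-line outcome
  frequencies with Newcombe/Wilson hybrid-score intervals for line bias, and
  line-weighted genotype summaries.
* **Atlas mapping** — region-selective gene discovery from expression-energy
  tables via pairwise-regression standardized residuals (> 2 against every
  other region) with automatic region pruning, and per-sample Spearman
  mapping scores, z-normalized across regions.
* **Statistics** — Welch's t, one-way ANOVA, one-sample t against zero,
  Benjamini–Hochberg FDR, and dpi-window pooling with
  replicate-averaging for time-course group comparisons.
* **Synthetic data** — a ground-truthed generator of full panel datasets:
  five regional expression programs mixed by Dirichlet draws whose
  log-odds are driven by latent Wnt/Hedgehog activity with line-specific
  biases, control probes, lane factors and negative-binomial noise; plus
  time-course, paired-treatment and atlas-fixture generators.

All user-facing functions take data frames first and return tibbles, so
steps chain with the pipe; fitted objects have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` ggplot2 helpers.

## Worked example

Simulate the default synthetic study (27 PSC lines, 149 differentiations),
normalize, classify every differentiation, and map samples to a reference
atlas fixture:

```r
library(cortexfate)

sim  <- simulate_dataset(seed = 1)
#> <simulated dataset: 149 samples x 148 probes, 27 lines>

expr <- normalize_dataset(sim$counts, sim$codeset) |>
  filter_expressed(floor = 30) |>
  log2_transform()
#> <expression: 149 samples x 127 genes, log2 scale>

pca <- run_pca(expr)
#> <PCA: 149 samples x 127 genes; variance explained 62.7/21.6/6.5%...>
head(top_contributors(pca, component = 1), 5)
#>   gene   loading     z
#> 1 NKX2-1   0.312  3.41
#> 2 LHX6     0.300  3.28
#> 3 SHH      0.297  3.25
#> 4 LHX8     0.290  3.17
#> 5 GSC      0.257  2.80
```

The first principal component is the dorsoventral axis: its top
contributors are the MGE program (NKX2-1, LHX6/8) and the Hedgehog ligand
SHH, exactly the genes that separate ventralized from cortical
differentiations. Classification against the generator-implied thresholds
recovers the ground-truth outcome for 98% of differentiations at this seed:

```r
labels <- classify_regional(expr, default_thresholds())
table(labels$label)
#>            dorsalized partially_ventralized    highly_ventralized
#>                    71                    28                    33
#>  partially_caudalized     highly_caudalized
#>                    11                     6
mean(labels$label == sim$truth$true_label)
#> [1] 0.9798658

line_frequencies(labels, sim$meta) |>
  dplyr::select(line, n, freq_dorsalized, dorsal_diff, biased_flag)
#>   line         n freq_dorsalized dorsal_diff biased_flag
#> 1 iPSC01.1    13               1       0.523 TRUE
#> 2 iPSC02.1     7               1       0.523 TRUE
#> ...
```

`biased_flag` marks lines whose dorsal-outcome frequency differs from the
overall rate (Newcombe/Wilson 95% interval excluding zero) — with strongly
line-dependent simulated tendencies, most lines are flagged. Atlas mapping
works from an expression-energy table; the packaged synthetic fixture
carries a 27-gene selective partition over five regions plus two derived
regions that the pruning step removes:

```r
prof <- make_atlas_fixture(seed = 1)
sel  <- select_region_specific_genes(prof, threshold = 2)
#> <selective genes: 27 genes over 5 regions (pruned: diencephalon, peduncular_hypothalamus)>

mapping_scores(expr, prof, sel) |>
  dplyr::arrange(sample_id, dplyr::desc(z)) |>
  head(3)
#>   sample_id region       rho      z
#> 1 UIN001    pallium   0.822   1.77
#> 2 UIN001    RSP       0.0910 -0.276
#> 3 UIN001    midbrain  0.0715 -0.331
```

UIN001 is a cortical (dorsalized) differentiation: it maps to the pallium
with Spearman ρ = 0.82 and to nothing else. `run_pipeline()` chains all
stages under one validated configuration and returns a single bundle.

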