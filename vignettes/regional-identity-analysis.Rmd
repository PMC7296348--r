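---
title: "Regional-identity analysis of neural differentiation panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional-identity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexfate)
```

## The problem

Directed differentiation of human pluripotent stem cells (PSCs) toward
cerebral-cortex tissue is reproducible on average but variable in detail:
individual differentiations drift along the dorsoventral and rostrocaudal
axes of the developing brain, acquiring ventral-forebrain (LGE/MGE),
mid/hindbrain, or hypothalamic identities instead of — or mixed with — the
intended dorsal-telencephalic (cortical) identity. Targeted expression
panels (nCounter-style codesets of one to two hundred probes) are a
practical way to audit many differentiations, because probe counts are
comparable across runs collected over months.

`cortexfate` implements the full analysis chain for such panels: control-probe
normalization with QC, expression filtering and log2 transform, cross-codeset
merging, axis-of-variation analysis (PCA and correlation-distance
clustering), an absolute marker-threshold classifier of regional outcome,
per-line outcome statistics with score-based confidence intervals,
reference-atlas mapping scores, the group-comparison statistics used around
these analyses, and a fully ground-truthed synthetic-data generator used to
validate the chain end to end.

## Normalization model

Raw counts for sample $s$ and probe $g$ are processed as:

1. **Background subtraction.** $b_s$ is the geometric mean of the 8 negative
   control probes; all non-negative-control counts are reduced by $b_s$ and
   clamped at 0. An all-zero negative set gives $b_s = 0$; otherwise zeros
   are replaced by 1 before the geometric mean (counts are integers, so 1 is
   the smallest observable signal).
2. **Positive-control factor.** $p_s = R_P / P_s$, where $P_s$ is the
   geometric mean of the 6 positive probes in sample $s$ and $R_P$ the
   geometric mean of the $P_s$ over all samples in the dataset being
   normalized. All counts are multiplied by $p_s$.
3. **Housekeeping factor.** $h_s = R_H / H_s$ computed the same way on the
   7 housekeeping genes (CLTC, GAPDH, GUSB, PPIA, RPLP1, RPS15A, RPS9),
   after step 2, and applied.
4. **Outlier removal.** Samples with $p_s$ or $h_s$ outside
   $[0.25, 4]$ are flagged and removed, and steps 1–3 are recomputed once on
   the survivors. We do not iterate to a fixed point: the workflow is
   described as a single re-normalization, and a second pass on an already
   cleaned dataset reproduces the same factors (tested).

Two consequences of the dataset-geometric-mean reference are worth knowing.
First, factors are only defined relative to the dataset being normalized, so
rescaling one sample's counts by $c$ changes every sample's output by the
common factor $c^{1/n}$ while leaving all between-sample structure exactly
unchanged; the package's invariance tests assert this exact form. Second, an
outlier's own counts participate in the reference, so a sample whose
housekeeping content is $1/k$ of everyone else's receives factor
$k^{(n-1)/n}$, not $k$.

Genes are kept when their normalized expression exceeds **30 counts in at
least one sample** (strictly above; a gene at exactly 30 everywhere is
dropped), a floor set above negative-control noise. Linear counts are
clamped at 1 and log2-transformed before every correlation, PCA, clustering
and classification step, to reduce skewness and stabilize variance.

**Cross-codeset merging.** Datasets from two codesets are merged through
bridge samples profiled with both. For each shared gene the scale factor is
the geometric mean over bridge pairs of $(a + \varepsilon)/(b + \varepsilon)$
with $\varepsilon = 0.5$; the factor multiplies every sample of the second
codeset, and bridge duplicates collapse to their first-codeset version. The
$\varepsilon$ stabilizes ratios at zero counts at the cost of exactness far
below one count; with $\varepsilon = 0$ the merge inverts an exact per-gene
rescaling to machine precision (tested both ways).

## Variation analysis

PCA is computed on gene-centered log2 data without unit-variance scaling
(log2 already stabilizes variance, and scaling would equalize markers with
flat background genes). Loading signs follow a fixed convention — the
largest-magnitude loading of each component is positive — so outputs are
reproducible across platforms. Contributor lists are genes whose loading,
Z-scored within a component, exceeds 2 in absolute value.

Samples are clustered on the Pearson correlation distance $1 - r$ computed
over genes, with complete linkage (the distance is what the upstream
analysis names; complete linkage is the default of the heatmap tooling it
uses, and the linkage is a visible, changeable argument). Labels at each cut
are numbered by decreasing cluster size with ties broken by first sample
position, so they are invariant to row order. Correlation distance ignores
per-sample affine transforms of expression, which is the desired behavior
for panel data where residual scale differences are nuisance.

Early-to-late predictability is quantified two ways: marker-level (Pearson
correlation between late-stage cluster-marker expression and every
early-stage gene across paired differentiations, with an optional
$|r| > 0.75$ reporting filter) and module-level (the correlation, over gene
pairs, between cross-time correlations and within-early correlations — near
1 when co-expression modules persist, near 0 for shuffled data).

## The regional-outcome classifier

Five outcomes are called from four markers on the log2 scale, in this order:

| rule | outcome |
|---|---|
| FOXG1 < very-low **and** DLX5 < very-low | highly caudalized |
| FOXG1 < low **and** DLX5 < low | partially caudalized |
| NKX2-1 ≥ high **and** PAX6 < low | highly ventralized |
| NKX2-1 ≥ high **and** PAX6 ≥ low | partially ventralized |
| otherwise | dorsalized |

Caudal calls take precedence: a culture that has lost forebrain identity
(low FOXG1) is caudal regardless of NKX2-1. The ventral branch uses a single
NKX2-1 cutoff shared by both ventral classes, with PAX6 deciding between
them — cultures high in both NKX2-1 and PAX6 retain enough dorsal progenitor
character to be only partially ventralized. Comparisons are strict below
cutoffs and non-strict at-or-above for "high", fixed here because the source
analysis does not state them; with continuous expression the choice is
measure-zero.

`fit_thresholds()` re-derives cutoffs from paired early/late data: caudal
cutoffs first (FOXG1, DLX5 jointly separating the caudal late cluster), then
ventral cutoffs on the remaining samples (NKX2-1, PAX6 separating the highly
ventral cluster). Candidate cutoffs are midpoints between adjacent training
values (plus sentinels beyond the range); among equally optimal candidates
the pair with the largest combined margin to the training data wins, then
the smallest cutoffs. One caveat is structural: three-class training cannot
locate the boundary between dorsalized and *partially* ventralized outcomes,
because both map to the same late cluster. The margin tie-break usually
lands the NKX2-1 cutoff in the wide dorsal/partial-ventral gap, but the
split is ultimately a configuration choice — which is why `threshold_set()`
treats cutoffs as first-class config values with recorded provenance, and
why the packaged default thresholds for simulated data
(`default_thresholds()`) are derived from the generator design itself (the
expected marker expression exactly at each ground-truth label boundary,
found by root-finding along the latent path between adjacent line types).

**Line statistics.** Outcome frequencies are tabulated per PSC line for
lines with at least 2 differentiations. A line is flagged as biased when the
95% confidence interval for the difference between its dorsal frequency and
the overall dorsal frequency excludes zero. The interval is Newcombe's
hybrid score construction built from the two Wilson intervals — the standard
reading of a "Wilson interval for a difference"; a Wald difference would not
involve Wilson at all. The overall proportion excludes the line under test
so the two proportions are independent, as the construction assumes. Under a
true zero difference the flag fires at about 5% (validated at 2,000
replicates). Genotype-level frequencies average per-line frequency vectors
so each line counts once regardless of its number of differentiations, and
genotypes with fewer than 3 lines are not reported.

## Atlas mapping

Most panel genes are correlated across embryonic brain regions; the mapping
step first isolates genes that break that shared profile. Energies are
log-transformed ($\log_2(e + 1)$; raw energies are right-skewed and the
residual threshold would otherwise be scale-dependent), then for each
ordered region pair (A, B) region-A values are regressed on region-B values
across genes by OLS. A gene is selective for A when its internally
standardized residual exceeds 2 in the A-regression against *every* other
retained region (the conjunctive reading of "each pairwise comparison"; the
regression runs across genes within a region pair because only that
orientation yields per-gene residuals). Regions with no selective genes are
removed — all at once, making the loop order-independent — and the procedure
repeats until every retained region has at least one; fewer than two
surviving regions is an error.

Each sample is then scored against each region by Spearman correlation
(midrank ties) over the union of selective genes, and scores are z-normalized
within each sample across regions. Spearman makes the score invariant to any
strictly monotone per-sample transform, so linear-vs-log and residual
normalization differences cannot move the ranking.

## Group-comparison statistics

Welch's unpaired two-sided t test (no equal-variance assumption,
Welch–Satterthwaite degrees of freedom) is the default two-group comparison;
one-way ANOVA covers multi-line comparisons; the one-sample t against
$\mu = 0$ tests per-gene mean log2 fold changes of treated-minus-control
pairs. Multiple testing uses Benjamini–Hochberg throughout, with explicit
families: all genes within one pooling window for time-course comparisons,
all genes within one treatment contrast. Time-course samples are pooled into
named dpi windows (defaults ~17.5 = 17–18 dpi and ~35 = 30–39 dpi; dpi =
days post-induction); replicates of the same differentiation are averaged
before testing so the differentiation, not the RNA sample, is the unit of
analysis. Windows where either group has fewer than two differentiations are
skipped with a warning rather than tested.

Degenerate inputs follow fixed conventions: two constant equal groups give
$p = 1$; constant unequal groups give the $p \to 0$ limit with a warning;
zero-variance input to the one-sample test is an error.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
full ground truth:

* **Regional programs.** Five expression programs (cortex, LGE, MGE,
  mid/hindbrain, hypothalamus) over a 127-gene endogenous panel. Marker
  genes are at least 8-fold elevated in their home program; FOXG1 is high in
  all forebrain programs, low in mid/hindbrain and intermediate in
  hypothalamus; pan-neural, progenitor, cell-state and signaling genes fill
  out the panel at shared levels, as in real neural codesets.
* **Line model.** Each differentiation draws latent Wnt and Hedgehog
  activities around its line's means (per-differentiation s.d. 0.2–0.3).
  A logistic (softmax) link maps the latents plus line-specific regional
  biases to Dirichlet concentrations over the programs: Wnt pushes mass
  toward the cortical and mid/hindbrain programs, Hedgehog toward MGE/LGE,
  low Wnt toward MGE. Dirichlet precision 120 keeps each line's outcome
  range tight, emulating the reported line-specific tendencies. Caudal-prone
  lines additionally suppress the LGE program, so caudalized cultures lose
  FOXG1 and DLX5 jointly — the empirical signature the caudal classifier
  branch relies on.
* **Observation model.** Expected expression is the proportion-weighted
  program mean; pathway readouts (SHH, PTCH1, GLI1 up and GAS1 down with
  Hedgehog; AXIN2, TNFRSF19 up with Wnt) scale as $2^{k \cdot \text{activity}}$.
  Counts are negative-binomial (size 80 for endogenous genes, ~11% CV at
  high abundance; size 150 for control probes) around lane-scaled means,
  with a log-normal lane factor (s.d. 0.12) and the full 8/6/7
  negative/positive/housekeeping control layout.
* **Ground truth.** Labels come from fixed proportion thresholds:
  mid/hindbrain fraction above 0.6 is highly caudalized, above 0.25
  partially caudalized; otherwise MGE above 0.4 is highly ventralized, above
  0.15 partially ventralized; everything else is dorsalized. The caudal
  thresholds sit higher than the ventral ones because bulk forebrain-marker
  dilution is sublinear in the caudal fraction: a culture needs a large
  mid/hindbrain component before its panel profile is meaningfully
  caudalized.
* **Default study design.** 27 lines with 2–26 differentiations each, 149
  in total: 16 dorsal-prone lines, two partially ventral-prone (one with 26
  differentiations), six highly ventral-prone, two partially caudal-prone,
  and one consistently highly caudal line, with control/Alzheimer's/trisomy-21/
  MAPT genotype annotations for genotype-level summaries.

Time courses reuse the machinery with a time-dependent latent trajectory:
identical across groups before the divergence day (default 17 dpi), then
ramping toward group-specific Wnt/Hedgehog targets, so dorsoventral markers
and pathway readouts split from that window onward. Treatment simulations
generate paired arms from one stream of uniform draws via quantile
transforms (normal, gamma, negative-binomial), so a zero-magnitude effect
reproduces the control arm byte-for-byte and any contrast isolates the
latent shift. The atlas fixture constructs a regions-by-genes energy matrix
with a shared correlated baseline, a 27-gene selective partition over RSP,
pallium, subpallium, midbrain and hindbrain (40-fold home elevation), and
two blend regions with no selective genes that the pruning loop must remove;
it is a synthetic stand-in, not downloaded atlas data.

What the generator does **not** emulate: spatial/colony effects and
cell-cell signaling, operator effects, batch chemistry beyond a scalar lane
factor, probe-level cross-hybridization, and any biophysically realistic
signaling dynamics. Passing tests therefore validate the analysis chain's
correctness and calibration on data with the assumed structure; they do not
show that real differentiations satisfy that structure.

## Numerical and design choices

* Geometric means are computed in the log domain; control-probe summaries
  treat an all-zero probe set as 0 signal and replace isolated zeros by 1.
* Background-subtracted values clamp at 0; linear values clamp at 1 before
  log2 (so "absent" maps to 0 on the log scale while ordering is preserved).
* The positive factor is applied before the housekeeping factor, and the
  housekeeping geometric mean uses background-subtracted, positive-normalized
  values, keeping $h_s$ interpretable as residual-content normalization.
* PCA sign and cluster-label conventions are fixed as described so repeated
  runs and platform changes cannot flip outputs.
* `fit_thresholds()` ties break by margin, then smallest cutoff — recorded
  here because any tie-break is arbitrary; the exhaustive-search oracle in
  the test suite implements the same rule independently.
* Probe identity is keyed on `probe_id` with a carried `gene_symbol` (1:1
  for these panels); merging operates on gene symbols.
* Pipeline provenance contains package version, configuration and seed but
  no timestamp, so identical inputs yield identical bundles.

## Problem sizes used in validation

The test suite and acceptance script run at the study's own scale: 149
differentiations from 27 lines for end-to-end classification, per-line
statistics and atlas mapping; 44-pair designs for early/late correlation;
7-differentiation, 4-line treatment contrasts; 2,000 replicates for the
Newcombe flag calibration, 4,000 for Welch type-I error and 2,000 for ANOVA;
50 random separable training sets and 1,000 random marker vectors against
the classifier oracles; 20 random profile sets against the selective-gene
oracle. These sizes give Monte-Carlo error well inside the asserted bands
while keeping a full run to tens of seconds.

## Known limitations

* The classifier's partially-ventral/dorsal boundary is not identifiable
  from three-class late-stage training; treat fitted `nkx21_high` values as
  a starting point and review them against the marker scatter.
* The normalization reference is dataset-relative; absolute levels are not
  comparable across independently normalized datasets unless merged through
  bridge samples.
* Cluster identities (EC/LC-style names) are label-compatible, not
  guaranteed identical to any particular published ordering: linkage
  tie-breaks and sample composition can renumber clusters.
* Mapping scores rank regional resemblance; they are not proportions of
  cell types, and z-normalization makes them relative within a sample.
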