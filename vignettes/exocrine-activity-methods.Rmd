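---
title: "Methods: regulon-based TF activity analysis of exocrine pancreas and pancreatic tumor single-cell data"
author: "exoactivity"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: regulon-based TF activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific problem

Master pancreatic transcription factors such as PDX1 are often nearly
invisible at the transcript level in single-nucleus RNA-seq — detection can
fall below a few percent of cells — while their regulatory programs remain
clearly active. `exoactivity` implements a pipeline for studying such a
TF's regulatory activity in the exocrine pancreas (acinar and ductal
compartments, across neonatal, adult and chronic-pancreatitis contexts)
and in pancreatic tumor cells along the Classical–Basal continuum. The
pipeline covers:

1. adaptive and fixed-threshold quality control;
2. marker-axis scoring and exocrine subtype assignment;
3. regulon-based TF activity inference with technical-covariate
   residualization;
4. per-gene two-part hurdle association models with combined evidence
   statistics and preranked GSEA export;
5. gene-module association models (global and subtype-stratified) and the
   clone genotype-dose expression model;
6. a tuned combined embedding, minimum-spanning-tree pseudotime with
   lineage prioritization, and the explicit three-family tumor classifier.

Every stage is validated on synthetic data with planted ground truth; the
generators are first-class, tested package code.

# Data model

`ExoExperiment` extends `SingleCellExperiment`: genes are rows and cells
columns (the Bioconductor convention), with a `counts` assay of
non-negative integers, an optional `lognorm` assay (natural log of
library-size-scaled counts, `ln(1 + c/total * 1e4)`; zero exactly where
counts are zero), and per-cell metadata (`donor`, `context`, `sample`,
`cluster`, `n_genes_detected`, `pct_mito`, `pct_ribo`, `contamination`).
The scale factor 10,000 is the community convention; it is a configurable
default, not an empirical claim. `n_genes_detected` is always recomputed
from the counts, never trusted from input files.

Regulons are signed, weighted TF→target edge lists (mode −1/+1, weight
> 0, unique pairs). Gene sets (marker axes, gene modules, NMF signatures)
are named, non-empty symbol lists read and written as GMT.

# Quality control

Cells are kept only if they pass all active criteria:

* detected genes within `median ± k·1.4826·MAD` (default `k = 3`),
  computed per sample, on the number of detected genes only;
* detected genes ≥ a floor (exocrine preset 150; tumor preset 500);
* `pct_mito`, `pct_ribo` and ambient `contamination` strictly below their
  caps (exocrine 10 / 35 / 0.5; tumor 25 / 20 / 0.5).

Keep-side comparisons are strict (`<`): the tumor pipeline's convention
("cells with ≥ 25 % mitochondrial reads were removed") is applied
uniformly, since the exocrine thresholds' strictness is not otherwise
determined. The removal report counts each criterion separately; a cell
failing several criteria counts under each, and the total removed is
reported on its own row. The MAD scale constant 1.4826 makes the MAD a
consistent estimator of a normal SD.

Exocrine cell selection scores each cluster for acinar and ductal marker
panels and for exclusion panels (endocrine, stromal, immune); a cluster is
retained when its best exocrine mean score beats its worst-case exclusion
score by a margin (default 0). With no exclusion panels, clusters with
positive exocrine score are kept.

# Marker-axis scores and subtype assignment

A module score is the mean log-normalized expression of the module genes
minus the mean over expression-matched control genes: all genes are binned
into 24 equal-count bins by mean expression, and each module gene draws
100 controls with replacement from the non-module members of its bin under
a fixed seed. Excluding module genes from the control pool makes the score
exactly linear in shifts of the module genes, which in turn makes the
operation property-testable; bin count and control count are conventional
defaults. Subtype assignment takes the argmax axis per cell (ties broken
by declared axis order and flagged), with the margin between the top two
axes mapped to confidence buckets at 0.05 / 0.15 / 0.30 (the bucket names
are fixed; the cut points are configurable defaults, since only the
buckets — not thresholds — are externally specified). Several axes may map
to one subtype label through the axis→label table, which is configuration,
not code.

# TF activity inference and residualization

Activity is inferred from the coordinated expression of regulon targets.
Per gene, `lognorm` is z-scored across cells; per TF and cell,

$$a_{\mathrm{TF},c} \;=\; \frac{\sum_t w_t\, m_t\, z_{t,c}}
{\sqrt{\sum_t w_t^2}},$$

summing over regulon targets present and non-constant in the matrix, with
mode $m_t \in \{-1,+1\}$ and weight $w_t > 0$; scores are then z-scaled
per TF. TFs with fewer than 5 usable targets are skipped. This weighted
signed Stouffer score is a deliberate replacement for rank-based
enrichment scoring with an analytic null: it preserves the operative
contract — signed, weighted, regulon-driven, z-scaled, robust to the TF's
own transcript sparsity — in a closed form that can be verified exactly in
tests. Absolute activity values are therefore not comparable to
enrichment-based scores; all downstream use is relative (associations,
orderings), where the two agree in structure.

Residualization fits, per TF, OLS of activity on an intercept plus five
technical covariates — detected genes per cell, percent mitochondrial,
percent ribosomal, ambient contamination, and PC1 of the structure space —
and keeps the re-z-scaled residuals as the primary activity measure.
Constant covariates are dropped with a warning; residuals whose SD falls
below numerical noise (1e-8, inputs being unit-scale) are flagged
degenerate and returned as zeros rather than amplified. When two regulon
collections are merged, the first collection wins `(tf, target)`
conflicts, including mode conflicts — a documented house rule, since no
external merge rule is specified.

# Hurdle association models

For each gene with at least 25 expressing cells, two fixed-effect models
are fit against (residualized) activity plus covariates — exocrine preset
covariates: subtype, donor, context, detected genes; tumor preset: cluster,
sample, detected genes:

* detection: logistic regression of `expr > 0`;
* magnitude: linear regression of `lognorm` among expressing cells.

The activity coefficient of each component yields a two-sided p-value and
a signed z, $z_i = \mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1-p_i/2)$,
clipped to ±10 ("reasonable bounds" made concrete). Evidence is combined
two ways:

* Stouffer-style signed z with weight-norm denominator
  $(w_d z_d + w_c z_c)/\sqrt{w_d^2+w_c^2}$ — equal weights in the exocrine
  pipeline, 2:1 detection:continuous in the tumor pipeline;
* Fisher's method on the two p-values (χ² survival with 4 df) for the
  overall p-value. The two pipelines' combination rules are implemented
  identically; whether they differed at the source is not determinable,
  and the shared implementation is flagged here deliberately.

Degenerate detection (all zero or all one) drops the detection component
and propagates the continuous one; collinear covariate columns are dropped
with a warning, and a dropped activity column is a `fit_error`, never a
silent estimate. Non-convergent logistic fits are likewise flagged.
Benjamini–Hochberg FDRs are computed per component and for the combined
p-value across all genes fit. Ranked exports (RNK, two columns, sorted
descending, clipped z) feed external preranked GSEA; enrichment itself is
out of scope.

# Module and genotype-dose models

Gene-module scores are regressed on activity with donor, context, detected
genes, percent mitochondrial/ribosomal and contamination as covariates;
subtype-stratified fits run the same design within each subtype. BH FDR is
computed jointly across the whole module × stratum table — one
multiplicity family, the most conservative reading of an FDR-starred
summary across strata.

The clone model emulates the CRISPR-edited clone RT-qPCR analysis:
expression values are rank-based inverse-normal transformed (mid-ranked
ties, Blom offset 3/8 — the transform is standard, the offset our default)
across all samples, then fit with `expression ~ dose + (1 | clone)` by
REML with Satterthwaite p-values. A zero clone-variance (singular) fit
coincides with OLS, and OLS is the explicit fallback if mixed-model
fitting fails outright.

# Embedding tuning

Two unit-total-variance PC spaces are built: a *structure* space (PCA of
per-batch mean-centered `lognorm` over the top highly variable genes) and
an *axis* space (PCA of the cell × axis score matrix, at most
`n_axes − 1` dimensions). Per-batch mean-centering is this package's
batch-correction step: it attenuates additive batch shifts at desk scale
and keeps the embedding contract (batch-shift attenuation before PCA)
exactly testable. The combined embedding concatenates
`α·structure` with `(1−α)·axis` over a grid (default 0, 0.1, …, 1);
subtype separation is the mean silhouette width over subtype labels,
batch/context mixing is one minus the mean silhouette over batch labels,
and the selected α maximizes their sum, ties (within 1e-9) resolving to
the smaller α. The silhouette-based metrics and additive objective are
this package's concrete choice for "balancing separation against mixing";
the grid and objective are configuration. Nonlinear 2-D layouts are
visualization-only and outside the tested surface.

# Pseudotime and lineage prioritization

The root cluster is the one with the highest fraction of cells labeled
Acinar or Acinar_REG+ (configurable). A minimum spanning tree over cluster
centroids in the combined PC space defines root-to-leaf lineages; a cell
belongs to every lineage containing its cluster, and its pseudotime is the
centroid-path distance to its cluster plus its signed projection onto the
cluster's incoming edge (the outgoing edge at the root), shifted to start
at 0 per lineage. This centroid-MST construction replaces simultaneous
principal-curve fitting; it preserves the root rule, root-to-leaf lineage
structure and per-lineage pseudotime while remaining deterministic and
geometrically checkable (rigid-motion invariant, monotone along collinear
clusters).

Per lineage, the metrics are cell count, pseudotime range, and the change
in ductal-like fraction between the bottom and top pseudotime quintiles
(`q = 0.2`; "early"/"late" are not externally defined). The ductal-like
label set defaults to the four ductal subtypes and is configurable.
Redundancy is the lineage × lineage Pearson correlation of pseudotime over
jointly assigned cells (undefined below 10 shared cells). Representative
selection scores each lineage by the mean of its z-scaled metrics
(equal weights) and greedily picks `k = 3` lineages, penalizing each
candidate by λ (default 1) times its maximum absolute redundancy with the
already-selected set. Profiles along each selected lineage cut min-max
scaled pseudotime into 20 equal-width bins, report per-bin subtype
fractions (summing to 1 over observed subtypes) and a running-mean
smoothed activity curve (window 3 bins, edge-truncated, empty bins
skipped).

# Tumor families

Four NMF signature scores (Sig1, Sig2, Sig6, Sig10) are the mean
`lognorm` over the signature genes present in the matrix. The classical
fraction is (Sig1 + Sig6) and the basal fraction (Sig2 + Sig10), each
normalized by the four-signature total; zero total signal gives missing
fractions. Families follow the explicit thresholds, applied in order with
first match winning — Classical (`p_classical ≥ 0.60` and
`p_basal ≤ 0.30`), then Basal (mirrored), then Hybrid (both ≥ 0.30) —
so the measure-zero boundary set is deterministic; anything else is
Unassigned. With non-negative mean-lognorm scores the two fractions are
complementary and Unassigned is only reachable through degenerate input,
but the category is kept defensively.

# Synthetic data: what it emulates, and what it does not

`simulateExocrine()` emulates a multi-donor, three-context snRNA-seq
exocrine dataset: negative-binomial counts (dispersion 0.4) whose log-means
add a gene baseline, marker-gene boosts, a signed regulon effect, a
per-donor batch shift (SD 0.2) and a log-normal library-size factor
(SD 0.5, matching the wide depth spread typical of snRNA-seq — and making
detection depth, not the planted TF program, the dominant technical axis).
Marker genes carry a discrete subtype-identity boost (1.5) plus a graded
component (0.8) weighted by a Gaussian kernel (bandwidth 0.12) of the
distance between the cell's stage position and the marker subtype's stage
position along the acinar→ductal axis (stage positions 0 to 0.96 in steps
of 0.16; per-cell jitter SD 0.05). The two components together keep the
seven subtypes cleanly separable while making stage-adjacent states share
partial marker expression — the gradual metaplastic continuum that makes
centroid geometry informative for trajectory inference. The TF transcript
itself is forced sparse (baseline ~2 % detection) while its latent
activity (SD 1) drives 100 signed targets at effect 0.5 per unit activity.
Technical covariates are drawn with mild library-size correlation, and an
optional confounder adds a multiple of a scaled technical covariate to the
activity that drives the regulon — the planted ground truth for
residualization tests. Defaults are 2,000 cells × 2,000 genes.

`simulateTumor()` draws a latent classical fraction per cell (uniform by
default over 3,000 cells in 15 samples), assigns the true family by the
threshold rules applied to the latent fractions, and gives the four
signatures' genes negative-binomial means calibrated — by numerically
inverting the expected `log1p` transform of NB counts — so the expected
mean-lognorm signature score is *linear* in the latent loading. Without
that calibration the concavity of `log1p` systematically inflates
estimated fractions toward the extremes. A latent TF activity increasing
with the classical fraction drives a 50-target regulon over background
genes. `simulateHurdleGene()` and `simulateCloneExpression()` plant exact
coefficients on the hurdle and mixed-model scales for calibration and
recovery checks (clone intercept SD 0.2, residual SD 0.3 — technical-scale
noise under which a −0.8 dose effect across 12 clones × 3 replicates is
estimable to ±0.2).

What the generators do **not** emulate: ambient-RNA mixture profiles
(contamination is a per-cell scalar only), doublets, UMI saturation,
transcriptional bursting kinetics, batch effects that are nonlinear in
log-space, and real marker co-expression structure. Passing tests
demonstrate that each stage recovers the structure it targets when that
structure is present as modeled — they do not certify performance on real
tissue, where violations of these simplifications (especially ambient
contamination structure and continuous subtype gradients) can be
stronger.

# Numerical and reproducibility choices

All stochastic functions take explicit seeds; generators seed a local RNG
and restore the caller's state, so library code never perturbs a session's
randomness. Workflow runs write provenance JSON per stage (parameters,
seed, input hashes by basename) and are byte-identical under identical
configuration and seed. Degenerate cases are contracts, not accidents:
zero-variance genes are excluded from z-scoring, zero-variance residuals
return flagged zeros, empty pseudotime bins are skipped by smoothing,
sub-minimum strata and lineages return flagged missing rows, and
boundary-valued family fractions resolve by rule order. The desk-scale
workflow defaults (800 cells; 600-gene exocrine / 1,300-gene tumor
universes) keep an end-to-end run near half a minute while leaving every
stage's statistics estimable; the validation suite uses 2,000-cell
simulations where recovery precision is asserted.

# Known limitations

* The activity score is a linear combination of target z-scores; strongly
  nonlinear target responses or heavy-tailed expression would be better
  served by rank-based enrichment, at the cost of exact testability.
* Batch correction by per-batch mean-centering ignores batch-by-gene
  interactions; the embedding tuning compensates only through the mixing
  term.
* MST pseudotime assumes cluster centroids trace the lineage; cycles,
  bridges between parallel branches, or very unequal cluster sizes can
  misroute paths where principal curves would bend.
* Hurdle components are combined under an independence assumption
  (Fisher); detection and magnitude are only asymptotically independent,
  and the combined p-value's calibration is verified empirically, not
  guaranteed.
* The tumor family thresholds are applied to noisy score fractions;
  agreement with latent truth concentrates its errors near the 0.30/0.60
  boundaries, as expected of any plug-in classifier.
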