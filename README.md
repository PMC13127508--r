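# exoactivity

Regulon-based transcription-factor activity analysis for exocrine
pancreas and pancreatic tumor single-cell RNA-seq data.

## The problem

Master pancreatic transcription factors — PDX1 foremost — are detected in
only a few percent of cells in single-nucleus RNA-seq, so their
transcript is a poor readout of their regulatory state. Their *activity*
is still measurable through the coordinated expression of dozens to
hundreds of target genes. `exoactivity` provides an end-to-end, fully
seeded pipeline for this kind of analysis, aimed at computational
biologists studying exocrine cell states (acinar and ductal subtypes in
neonatal, adult and chronic-pancreatitis pancreas) and pancreatic tumor
cells along the Classical–Basal continuum.

The statistical core:

* **TF activity** per cell from a signed, weighted regulon:
  `a = Σ w·m·z / sqrt(Σ w²)` over target-gene expression z-scores
  (mode m = ±1, weight w > 0, minimum regulon size 5), z-scaled per TF
  and then **residualized** by OLS against technical covariates
  (detected genes, %mito, %ribo, ambient contamination, structure PC1).
* **Two-part hurdle models** per gene: logistic regression for detection
  (`expr > 0`) and linear regression for magnitude among detected cells,
  both against residualized activity plus fixed-effect covariates
  (minimum 25 expressing cells). Evidence combines as weighted signed
  Stouffer z, `(w_d·z_d + w_c·z_c)/√(w_d²+w_c²)` (equal weights for the
  exocrine pipeline, 2:1 detection:continuous for tumors), and Fisher's
  method (χ², 4 df) for the overall p, with Benjamini–Hochberg FDRs and
  clipped preranked GSEA export.
* **Cell-state machinery**: MAD-adaptive QC, bin-controlled marker-axis
  scores with argmax subtype assignment and margin confidence, a tuned
  structure/axis combined embedding, MST pseudotime with redundancy-aware
  representative-lineage selection, module–activity association models,
  the rank-based inverse-normal genotype-dose clone model, and the
  explicit three-family tumor classifier
  (Classical if p_classical ≥ 0.60 & p_basal ≤ 0.30; Basal mirrored;
  Hybrid if both ≥ 0.30; ordered rules).

Synthetic-data generators with planted ground truth (latent activity,
subtypes, pseudotime, hurdle coefficients, tumor families) are exported,
tested package code — every downstream stage is validated against them.

## Worked example

```r
library(exoactivity)

sim <- simulateExocrine(exocrineSimConfig(seed = 1))
ee  <- applyQCFilter(sim$experiment, qcThresholds("exocrine"))$kept

axes   <- scoreGeneSets(ee, sim$panels, seed = 1)
labels <- sub("^axis_", "", colnames(axes))
calls  <- assignAxisSubtype(axes, setNames(labels, colnames(axes)))
table(calls$confidence)
#>     high      low moderate
#>     1935        1        6

act    <- inferActivity(ee, sim$regulon)
spaces <- computePCSpaces(ee, axes)
actR   <- residualizeActivity(act, SummarizedExperiment::colData(ee),
                              spaces$structure_pcs[, 1])
truth <- sim$truth$cells[match(colnames(ee), sim$truth$cells$cell_id), ]
cor(activityValues(actR)[, "PDX1"], truth$activity_true)
#> [1] 0.9104313
```

The correlation is between the inferred, residualized PDX1 activity and
the latent activity planted by the generator: at the default study
conditions (2,000 cells, 100-target regulon, effect 0.5 per unit
activity) the pipeline recovers the planted signal with r ≈ 0.91, even
though the PDX1 transcript itself is detected in ~2 % of cells. The
confidence table shows most cells assigned to their marker axis with a
large margin.

Full workflows (QC → selection → axes → activity → embedding → hurdle →
modules → trajectory → rank export; or the tumor variant ending in
family classification and 2:1-weighted hurdle models) run from one call
and write per-stage TSVs plus provenance JSON:

```r
runExocrineWorkflow("out/exocrine", seed = 1)
runTumorWorkflow("out/tumor", seed = 1)
```

Reruns with the same configuration and seed are byte-identical.

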