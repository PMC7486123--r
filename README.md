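# blamap

Resolving **discrete** and **graded** heterogeneity among excitatory neurons
of the basolateral amygdala (BLA), as a tested, reusable R pipeline.

The BLA comprises the lateral (LA) and basal (BA) nuclei. High-depth
single-cell RNA-seq separates their excitatory neurons into two discrete
clusters; multiplexed FISH maps that split back onto tissue, where the two
discrete markers *Negr1* (LA) and *Cplx1* (BA) transition sharply at the
LA/BA border while other markers vary smoothly within each nucleus. `blamap`
implements the complete analysis path behind that picture, for anyone who
wants to apply it to their own count matrices, segmented-cell tables or
imaging rounds — or to study its statistical behaviour on the bundled
synthetic generator, which emulates the study conditions (1231 cells, 27/73
LA/BA mixture, 415 planted marker genes, within-nucleus gradients) so every
stage runs with no data download.

## What is implemented

* **scRNA-seq**: QC (total counts >= 10,000), CPM, Snap25/Gad1 class gates,
  binned-dispersion variable genes, PCA, SNN-Jaccard + Louvain clustering
  (coarse resolution 0.2, fine 0.8), Wilcoxon rank-sum markers with
  Bonferroni adjustment, and the random-forest subsample-classification
  experiment (50–800 training cells x 100 replicates).
* **Registration**: six-landmark rigid Procrustes (no scaling, no
  reflection) onto section templates; point-in-polygon LA/BA assignment.
* **Image stage**: chromogenic / DAPI / Slc17a7 segmentation with the
  printed area bands (100–400, 40–200 + 5 um dilation, 75–450 um^2), FFT
  phase-correlation round alignment, per-cell counts-per-area (CPA).
* **Spatial statistics**: the phenotype index
  `(E_Cplx1 − E_Negr1) / (E_Cplx1 + E_Negr1)`, winner-take-all phenotyping
  gated on Slc17a7 CPA >= 0.004, 100-um distance-binned same/opposite
  correlation profiles, Ward-D2 clustering of sum-normalized CPA.
* **Projection nulls**: 1000-iteration Monte-Carlo enrichment and
  distance-restriction nulls with percentile 95% intervals and add-one
  empirical p-values; pairwise Mann-Whitney soma-area comparisons.
* **Orchestration**: `runAll()` executes every stage from one seeded config
  and emits a reproducible JSON report.

See `vignettes/blamap-methods.Rmd` for the model, conventions and numerical
choices.

## Worked example

```r
library(blamap)

sce <- computeCPM(qcFilter(simCounts(simCountConfig(seed = 11))))
vg  <- selectVariableGenes(sce)
lab <- clusterGraph(pcaEmbed(sce, vg), resolution = 0.2, seed = 42)
table(lab)
#> lab
#>   0   1
#> 899 332
de <- differentialExpression(sce, lab, 0L, 1L)
sum(de$significant)
#> [1] 416

cells <- binarizePhenotype(simSpatialCells(simSpatialConfig(seed = 5)))
round(bimodalitySummary(phenotypeIndex(cells))$extremeFraction, 3)
#> [1] 0.673
```

The clustering recovers the planted 27/73 mixture (332 of 1231 cells in the
smaller, LA-like cluster); the Bonferroni-corrected Wilcoxon scan returns
416 genes at adjusted p < 0.05 against 415 planted markers; and the
phenotype-index histogram of the simulated mFISH table is strongly bimodal
(67% of phenotyped cells at |index| >= 0.9), the signature of discrete LA/BA
identity coexisting with graded within-nucleus variation.

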