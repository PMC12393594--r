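# stcelldyn

Cell-type dynamics analysis for imaging-based spatial transcriptomics under
a genotype-by-treatment design.

`stcelldyn` re-implements, as a tested R package, an analysis chain for
per-cell spatial transcriptomes (CosMx-style: ~1,000-plex panels with
negative-control probes, fields of view, and atlas region labels) collected
from mice homozygous for either allele of a mu-opioid-receptor variant
(AA/GG) under saline or chronic morphine (SAL/MOR). It is aimed at
computational biologists who want each stage of such a pipeline available
as an auditable, separately testable function rather than a monolithic
script.

## What it does

1. **Quality control** — negative-probe screening by iterative two-sided
   Grubbs tests (P < 0.01); target-probe filtering against the
   negative-control background (50th-percentile cut plus a one-sided
   Poisson exceedance test); cell filters (>= 5 transcripts, <= 10%
   negative-probe counts, count/gene ratio > 1, segmentation-area
   outliers); two-stage FOV filters (mean counts >= 100/cell, mean
   negative counts <= 1.0/cell, >= 500 cells run-level; >= 10
   transcripts/cell pipeline-level); `LogNormalize`-style scaling to
   10,000 counts; a 5th-percentile depth filter.
2. **Clustering** — PCA with removal of components correlated (|r| > 0.7)
   with log2 library size, exact-kNN shared-neighbor graphs, Louvain with
   a modularity-maximizing resolution scan on the opioid-naive AA-SAL
   reference, random-forest label propagation (200 trees) to all other
   groups, and capped per-cluster t-SNE.
3. **Annotation** — rule-based neurotransmitter and glial identity calls
   (log2CPM > 3 with a two-component Gaussian-mixture diagnostic; a
   cluster takes an identity when > 30% of its cells pass), a four-level
   hierarchy, marker QC (>= 8 markers with adjusted P < 0.01 and
   q_diff >= 0.7, DE score = sum of -log10 adjusted P >= 150), and
   overlap scoring against reference marker sets (GMT).
4. **Differential expression and dynamics** — Wilcoxon + BH cluster and
   inter-regional DE (500-cell subsampling, adjusted P < 0.01,
   |log2FC| > 1.5), DEG-ratio z-scores, a transcriptional
   disproportionality score per cell type (z-scored composite DEG
   expression; flagged when |z| > 1.64 and mean |log2FC| > 1), and
   composition dynamics (percent change, symmetric-log scaling, Shannon
   diversity, Gini coefficients).
5. **Enrichment** — per-cell weighted gene-set scores with percentile
   verdicts, hypergeometric region-level over-representation with an
   AA-vs-GG composite bias, and GO-slim-style rollups.
6. **Co-expression** — region x group mean matrices, inter-regional
   correlation networks (r > 0.95) with degree centrality, and
   WGCNA-style module detection: biweight midcorrelation, soft power
   selected by signed scale-free fit (default 8), Zhang-Horvath
   topological overlap, average-linkage clustering with a dynamic tree
   cut (min module size 20, deep split 3), eigengene merging at
   dissimilarity 0.10, module-trait correlation, and Fisher enrichment
   capped at -log10 p = 10.
7. **Differential networks** — per-module MOR - SAL region-correlation
   differences normalized by the maximum |delta| (top 200 edges), ARACNe
   style mutual-information networks (equal-frequency binning, plug-in
   estimator, DPI pruning, permutation edge threshold), delta-hub gene
   ranking with <= 25-node subnetworks, and region-specific module flags
   (|z| > 1.5).
8. **Synthetic data** — a negative-binomial generator that plants cell
   types with markers, treatment-responsive DEG programs,
   region-structured co-expression modules, and inter-regional correlation flips,
   with full ground truth, so every stage above has a recovery test.

## Worked example

```r
library(stcelldyn)

cfg <- pipeline_config(out_dir = "run1", seed = 1)
st  <- run_pipeline(cfg)

st$qc$report$pass_rate
#> [1] 93.5

truth <- st$dataset$truth$cell_type_of_cell[st$qc$cells$cell]
adjusted_rand(st$assignment$cluster, truth)
#> [1] 0.9816

subset(st$dispro, flagged)
#>      cell_type composite_score      z mean_abs_log2fc valid_deg_fraction flagged genotype
#> 3 Dopaminergic          3.9485 2.6448          1.5599                  1    TRUE       AA
```

The default configuration simulates the standard study fixture: four
groups (AA/GG x SAL/MOR) of 1,600 cells each, eight planted cell types,
a 300-gene panel with 20 negative probes. 93.5% of cells survive QC;
clustering plus label propagation recovers the planted types at an
adjusted Rand index of 0.98; and the planted hyper-responsive
dopaminergic population is the only cell type flagged by the
disproportionality screen (its DEGs are concentrated there, so its
composite score z-stands out beyond the +/-1.64 gate with mean
|log2FC| above 1).

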