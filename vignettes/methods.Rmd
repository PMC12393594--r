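---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of
`stcelldyn`, the parameters that matter (with defaults and units), the
numerical conventions, and the design decisions that were genuinely open.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The synthetic-data model

Imaging-based spatial platforms produce per-cell counts over a fixed probe
panel, with negative-control probes estimating background, cells tiled
into fields of view (FOVs), and each cell annotated with nested atlas
region labels. `generate_dataset()` emulates this structure:

* **Counts.** Gene counts are gamma-Poisson (negative binomial):
  `n_cg ~ NB(mu = L_c * w_g(c) / W(c), size = 1/dispersion)` with
  log-normal library sizes `L_c` (median `libsize_mean`, default 500
  counts — inside the 367–697 per-cell mean range typical of these runs —
  log-sd 0.25) and dispersion 0.3, matching the overdispersion of
  imaging-based counts. `w_g(c)` is the cell's relative expression
  profile; it is renormalized per profile so library size is independent
  of planted programs. A consequence worth knowing: very large planted
  programs are compositionally damped (upregulating a big slice of the
  library deflates everything, including the program itself, after
  per-cell normalization), exactly as in real data. The generator's
  planted-effect calibration therefore holds for modest program
  footprints; the test suite checks a 5-gene, 1.5-log2-unit program
  recovers within ±0.2.
* **Negative probes.** Poisson at `neg_rate_frac` (1.5%) of the mean
  real-probe rate; at the defaults this keeps mean negative counts per
  cell near 0.5, under the 0.54 ceiling such runs report.
* **Cell types.** Eight planted types (five neurotransmitter, three
  glial), each with 200 cells per group at the defaults. Identity *rule
  genes* (e.g. `Slc6a3`/`Th`/`Ddc` for dopaminergic cells; disjoint
  across types so ground truth is unambiguous) follow an on/off program
  with contrast `identity_log2fc` (default 5): the threshold classifier
  keys on detection, and real transporter/biosynthesis genes are
  near-absent outside their type, which a modest fold change cannot
  imitate. Filler *marker genes* are elevated by `marker_log2fc`
  (default 2) over a baseline weight of `marker_base_weight` (0.3);
  they carry the clustering difficulty. Setting both contrasts to 0
  produces the no-signal fixture used for type-I-error checks.
* **Treatment DEG programs.** Each program names a cell type, a genotype,
  an optional depth-5 region, a baseline type concentration
  (`type_log2fc`, default 4 — like a neuron-specific program, 16-fold
  concentrated in its type) and a morphine-only effect (`log2fc`,
  default 2). The defaults make the planted program detectable by a
  within-type Wilcoxon and give a genotype-level fold change above the
  disproportionality gate of 1 after type dilution — design arithmetic,
  set before any recovery was measured.
* **Modules and rewiring.** Four 30-gene modules receive a shared latent
  score per region x group sample (active in one meso-structure each,
  amplitude 1 log2 unit, noise sd 0.4), creating co-expression across
  region-level samples. A planted rewiring event gives two named depth-7
  regions signed gene loadings (amplitude 1.5) whose sign flips in one
  region under morphine, so that region pair's module correlation flips
  between conditions.
* **Geometry.** Each FOV maps to one depth-7 region; cells choose FOVs
  uniformly. Region assignment is otherwise independent of FOV so FOV-
  and region-level filters exercise different axes.

What the generator does **not** emulate: spatial autocorrelation within
FOVs, segmentation errors and doublets, batch and slide effects, dropout
beyond NB sampling, and realistic gene-gene correlation outside the
planted modules. Passing recovery tests therefore demonstrates
correctness of the algorithms under the stated generative model, not
performance on real tissue.

## Quality control

Boundary conventions follow the stated rules exactly: cells need >= 5
transcripts, <= 10% negative fraction, count/detected-gene ratio
strictly > 1; FOVs fail below 100 mean counts/cell, above 1.0 mean
negative counts/cell, below 500 cells (run level), or below 10 mean
transcripts/cell (pipeline level). The 500-cell FOV floor is scaled by a
configurable factor (`cell_scale`, recorded in the QC report) because
fixtures of a few thousand cells cannot carry 500-cell FOVs; the
thresholds themselves are never changed.

Grubbs screening is iterative and two-sided at P < 0.01: the most extreme
value is tested against `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2/(n-2+t^2))`
with `t = qt(1 - alpha/(2n), n-2)`, removed if significant, and the test
repeats. "Background-corrected detection P-values" are implemented as a
one-sided Poisson exceedance test of a target's total count against the
mean retained-negative-probe total — a replaceable strategy, isolated in
`filter_probes()`. Whether the 50th-percentile background cut uses
per-probe totals or per-cell means was an open choice; totals are used.
Percentiles are type-7 (linear interpolation) throughout. Normalization
is natural-log (`ln(1 + 10^4 n/N)`); log2 appears only where the method
is defined on log2 units (CPM classification, fold changes).

## Clustering and propagation

Genes are standardized and clipped at ±10 before PCA. Components whose
scores correlate with log2 total counts beyond |r| > 0.7 are dropped;
the absolute value is deliberate — anti-correlated components are equally
technical. The retained count is derived, never hard-coded. The pipeline
default fits 30 components: the down-scaled panel supports fewer
informative directions than a 1,000-plex run, where 100 components with
the same bias filter are appropriate.

The reference graph uses exact k-nearest neighbors (k = 50) with
shared-neighbor Jaccard weights pruned below 1/15, Seurat-like; the
neighbor search is exact below a few thousand cells so tests are
deterministic. "Automatic" resolution scans 0.4–2.0 in steps of 0.2 and
keeps the modularity-maximizing Louvain partition. Propagation fits a
200-tree random forest on the reference embedding and predicts query
cells projected with the *reference* loadings (no re-fit — propagation
requires a single component space); reference cells are never relabeled.
t-SNE downsamples to 1,000 cells per cluster with a size-safe perplexity.

## Annotation

The operative classifier is the fixed consensus threshold log2(CPM+1) > 3;
the two-component Gaussian mixture is fit per gene only as a bimodality
diagnostic and never changes calls. `q_diff` is the detection-fraction
difference (fraction expressing inside minus outside the cluster).
Cluster identities require a strictly greater than 30% passing fraction;
multi-identity clusters keep all passing identities with a deterministic
(highest-fraction, then lexicographic) primary. The DE score caps each
gene's -log10 adjusted P at 300 to avoid infinities from numerical
underflow; the cap is recorded. The rule table ships as data the user can
replace, and encodes the canonical transporter/biosynthesis gene logic
as given — including the GABAergic alternative group "Gad1, Gad2, or
Aldh1a1", ambiguous as it may be.

## Differential expression and disproportionality

All DE uses the Wilcoxon rank-sum test on normalized expression with
Benjamini–Hochberg adjustment — including cluster markers, where
Bonferroni is the Seurat default; BH was chosen for internal consistency
and the divergence is deliberate. Fold changes are
`log2((mean_a + eps)/(mean_b + eps))` on the normalized-count scale with
`eps = 1/scale_factor`, stabilizing zero-mean groups.

The disproportionality composite averages, over DEGs with nonzero
expression in a type, the DEG's mean normalized expression; types with a
valid-DEG fraction below 0.25 (a configurable floor) are excluded. Scores are z-scored with
the population (divide-by-n) convention; a type is flagged when |z|
exceeds 1.6449 (stored at full precision, reported as 1.64) *and* its
mean |log2FC| exceeds 1. An |log2FC|-weighted composite is available via
`weighted = TRUE`; unweighted is the default since the methods text
describes a plain average while only a supplementary legend mentions
weighting. In the pipeline, DEG lists entering this score are first
restricted to confident, large-effect genes (adjusted P < 0.01,
|log2FC| > 1) — the noise-suppression step — and treatment DE runs within
cell types, since a type-restricted response is invisible to a rank test
across a pooled population.

For composition dynamics, "min–max normalization followed by log
transformation" is order-ambiguous for negative percent changes; the
implementation applies a symmetric log first (`sign(x) log1p(|x|/100)`)
and then a zero-preserving max-abs scaling onto [-1, 1], recorded in the
output. Shannon diversity uses natural log; Gini is the mean-absolute-
difference form.

## Enrichment

The per-cell "weighted GSEA-based" score is implemented as a weighted
mean difference — the |log2FC|-weighted mean of gene-standardized
expression over the term's DEG genes minus the unweighted mean over all
DEG genes — rather than a running-sum statistic: it is deterministic,
fast, exactly zero for a cell with uniform standardized expression, and
isolated behind one function so a running-sum variant can be swapped in.
Percentile verdicts default to the 90th/10th percentiles. Region-level
over-representation is the one-sided hypergeometric with BH across terms;
the composite is `-log10(q) * mean log2FC of hit genes` (signed so
direction survives), and the genotype bias is the AA minus GG composite.
The slim rollup ranks by frequency across region-module-group
combinations first and minimum FDR second, keeping the top 60.

## Co-expression modules

Biweight midcorrelation uses the standard Tukey construction (9-MAD
tuning); genes with zero MAD fall back to Pearson scaling. The network is
unsigned (`|bicor|^power`), matching common blockwise defaults; power
selection regresses log10 p(k) on log10 k over ten connectivity bins and
scores `-sign(slope) * R^2`, so a scale-free (negative-slope) degree
distribution scores positively — the stated "signed R-squared" criterion
read as the standard soft-threshold diagnostic. The lowest power
exceeding 0.8 wins, with 8 as the documented fallback and default.

Topological overlap is Zhang–Horvath:
`TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)`. Modules come from
average-linkage clustering of 1 - TOM with a dynamic **tree** cut: a
static cut at a deep-split-dependent fraction of the maximum merge height
(0.99 down to 0.97 for deep split 0–4) with clusters below the minimum
size (20) sent to grey. The full dynamic *hybrid* variant (PAM stage,
per-branch shape criteria) is intentionally not reproduced; on
region-mean matrices with tens to a few hundred samples the tree cut
recovers planted modules at adjusted Rand >= 0.8 (tested over five
seeds), and all cut parameters are exposed. Eigengenes are first
principal components, unit-norm, sign-oriented to correlate positively
with the module mean; merging is iterative on eigengene dissimilarity
below 0.10. "Consensus" detection across groups is a single pooled fit on
region x group rows, not a multi-set consensus
of per-group networks.

Module enrichment uses one-sided Fisher exact tests (equal to the
hypergeometric upper tail, verified by enumeration in the tests), capped
at -log10 p = 10 and normalized within each effect. DEG effect sets come
from paired region-wise t-tests across matched regions (FDR < 0.05,
|log2FC| > 0.25); the OUD-risk gene list is user-supplied.

## Differential networks and hubs

Differential connectivity is the MOR - SAL difference of region x region
Pearson correlations over a module's genes, normalized by the maximum
|delta| computed *before* truncation to the top 200 edges; ties break
lexicographically, and the statistic is exactly antisymmetric under
condition swap. Mutual information uses equal-frequency discretization
into ceiling(sqrt(n)) bins and the plug-in estimator; DPI removes, in
each triangle, the strictly weakest edge (tolerance 0, the usual
default). Because a raw MI network is a complete graph,
a permutation significance threshold (100 permutations, alpha 0.05,
seeded) is applied before degrees are counted — without it "hub degree"
is meaningless on a complete graph; the threshold is
exposed and can be disabled. Hub ties resolve by higher morphine-network
degree, then gene name; subnetworks keep the top hubs plus their
morphine-network neighbors, truncated to 25 nodes by edge strength.
Region-specific modules are flagged at |z| > 1.5 on region-averaged
eigengenes, with single-region status recorded separately.

## Problem sizes and determinism

The shipped defaults simulate 6,400 cells over a 320-probe panel — the
scale at which every recovery property in the test suite (clustering
ARI >= 0.9, module ARI >= 0.8, disproportionality and rewiring recovery)
is exercised across multiple seeds. Every stochastic step takes an
explicit seed; the pipeline derives per-stage seeds from the root seed
and stage name, so identical configurations produce byte-identical
outputs. The interfaces (`stcelldyn` functions, `run_pipeline()`, and
`scripts/acceptance.R`) are the package's command surface.

## Known limitations

* The generator's independence assumptions (no spatial autocorrelation,
  no batch structure) mean QC and clustering are tested under cleaner
  conditions than real tissue provides.
* The tree-cut module detector under-splits nested module structure that
  the hybrid cut's PAM stage would separate.
* Group-level Wilcoxon DE cannot detect responses confined to rare cell
  types; the pipeline's within-type DE addresses this but requires
  >= 50 cells per arm per type.
* The per-cell enrichment score is a linear statistic; strongly
  non-linear set effects would favor a running-sum variant.
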