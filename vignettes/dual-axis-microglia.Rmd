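---
title: "Decomposing microglial ageing and plaque phagocytosis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing microglial ageing and plaque phagocytosis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaxes)
```

# The problem

Microglia sorted from an amyloid mouse model fall into four populations:
adult wild type (WT6m), aged wild type (WT24m), and plaque-non-phagocytic
(XO4neg) versus plaque-phagocytic (XO4pos) cells from the disease model.
Two biological processes are entangled in their transcriptomes: a gradual
ageing programme and a switch-like phagocytic activation. `gliaxes`
implements the statistical machinery to pull those apart — covariate-aware
differential expression, a dual-axis pseudotime decomposition, consensus
clustering, regulon-activity scoring, signature scoring and projection onto
bulk references — together with a simulator whose ground truth exercises each
stage.

# The synthetic-data generator

`simulate_sc_counts()` draws, per cell, a latent ageing value
$a_j \sim \mathcal N(\mu_g, \sigma_g)$ (group-specific mean and sd) and a
phagocytosis switch $f_j \sim \mathrm{Bernoulli}(p_g)$, then counts

$$c_{gj} \sim \mathrm{NB}\!\left(\mu = s_j\,\tilde\mu_g\,
  2^{\,a_j \beta_g^{\mathrm{age}} + f_j \beta_g^{\mathrm{phago}}},\;
  \phi_g\right)$$

with relative expression $\tilde\mu_g$ (gamma-distributed, normalized to sum
to one), lognormal library size $s_j$, and a dispersion mean trend
$\phi_g = a_0 + a_1/m_g$ evaluated at the gene's expected baseline count.
Ageing is continuous and phagocytosis binary by design: the sorted
populations show a switch-like phagocytic signature with few intermediate
cells, while ageing progresses gradually, and the dual-axis recovery test is
only meaningful if the generator respects that asymmetry.

Defaults mirror the sorted populations such an experiment yields: 243/121/95/434 cells for
WT6m/WT24m/XO4neg/XO4pos; ageing means 0, 1, 0.5, 0.5 (sd 0.2 wild type, 0.3
in the disease groups, which show heterogeneous pseudoage); phagocytosis
probability 1 in XO4pos and 0 elsewhere; 200 ageing and 300 phagocytosis
effect genes with log2-effect scales 1 and 2 (the phagocytic shift dominates
variance, as it does in the sorted data); a median library size of 5,000
counts over 2,000 genes, reflecting deeply sequenced sorted microglia. One
regulon (100 targets, shared activity in phagocytosing cells) plants
co-expression structure for the AUC scorer; 5% of genes are mitochondrial and
5% of cells get a 10x mitochondrial boost to exercise QC.

Counts are drawn gene by gene under an RNG substream keyed by the gene id, so
results are reproducible and independent of gene order. What the generator
does **not** emulate: ambient RNA, doublets, UMI saturation, batch chemistry
effects in the single-cell data, or gene–gene correlation beyond the two axes
and the planted regulons. Tests that pass on these simulations therefore
certify the statistical machinery, not robustness to those artefacts.

# Quality control and normalization

`filter_cells_and_genes()` applies, in order: removal of all-zero genes;
removal of cells at or below the 5th percentile of total counts or detected
features (a relative rule, so it is applied once — reapplying it to filtered
data would re-derive a higher cutoff; the absolute rules are idempotent);
removal of cells with a mitochondrial fraction above 10%; an optional
microglia marker gate (summed counts over marker genes ≥ 10, exclusion genes
< 6 — "or" in the marker list is read as pooled evidence, with a per-gene
mode available); an optional blacklist (standing in for sex-gene and
cell-cycle removal, which require external training data); and finally gene
retention requiring a count ≥ 2 in ≥ 2 distinct cells (the strictest parse of
the rule; a detection-based alternative is configurable). Cell filters run
before gene filters; the QC report records each step.

`normalize_log_cpm()` produces $\log_2(\mathrm{CPM}+1)$ with either
library-size factors or zero-tolerant median-of-ratios factors. Pooled
deconvolution factors were considered and set aside for determinism at desk
scale; the median-of-ratios option covers the composition-bias case that
motivates them.

Feature selection (`select_features_danb()`) is a depth-adjusted
negative-binomial dropout test: each gene's expected zero count under
$\mu_{gj} \propto t_j$ (cell totals) with a moment dispersion is compared
with its observed zeros, and genes are ranked by the right-tailed z-score of
the excess; the top quartile of a 6,685-gene universe is exactly 1,671 genes.

# Differential expression

Two engines serve different designs:

* `kruskal_wallis_de()` — the non-parametric omnibus test across groups on
  normalized expression, used for cluster marker detection and regulon
  pruning.
* `nb_glm_lrt()` — the covariate decomposition. Per gene, an NB log-link GLM
  is fitted by IRLS under the full and reduced models and compared by a
  likelihood-ratio χ² test. All genes share the design matrix, so each IRLS
  update is a few matrix products plus a Cholesky solve batched across genes.

Two numerical choices matter. **Offsets** default to median-of-ratios size
factors (zero-tolerant variant): with several hundred genes shifted in one
direction (e.g. the phagocytic programme), raw library-size offsets transfer
the composition shift to every null gene, and at single-cell sample sizes
that inflates discoveries several-fold. **Dispersion** is estimated per gene
by maximizing the Cox–Reid adjusted profile likelihood on a log-spaced grid
given fitted means, then moderated by a robust mean–dispersion trend
$\phi(\mu) = a_0 + a_1/\mu$, taking the larger of trend and gene-wise value.
Plug-in moment estimates are biased low at 12-sample designs and make the
LRT badly anti-conservative; the CR adjustment plus conservative moderation
restores nominal false-discovery control (verified on 200 null simulations in
the test suite) at some cost in power, a deliberate trade since the LRT has
no analogue of the quasi-likelihood F-test's uncertainty propagation.
Non-converged genes get `p = NA` and are excluded from the BH correction with
a warning count. LRT statistics are invariant to factor-baseline
reparameterization, which the suite checks.

Gene cytometry scores each gene `|LFC| · (−log10 FDR)` per axis, capping
−log10(FDR) at 320 when the FDR underflows, and assigns quadrants
Q1 = XO4-only, Q2 = XO4-and-age, Q3 = age-only, Q4 = neither at the chosen
FDR threshold (default 0.05).

# Clustering

`consensus_cluster()` follows the consensus recipe: three cell–cell distances
(Euclidean, 1−Pearson, 1−Spearman), each transformed by PCA of the distance
matrix and by the eigenvectors of its normalized graph Laplacian, k-means
(k-means++ seeding, 10 restarts, fixed seed — the upstream defaults are not
stated, so reproducible choices were made) on the first $d$ components for
every $d$ spanning 4–7% of the cell count, a consensus matrix averaging the
binary co-clustering indicators, and a complete-linkage cut at $k$.
`estimate_k()` counts eigenvalues of the scaled cell–cell cross-product
exceeding a Tracy–Widom significance bound. Both raw Rand and the
Hubert–Arabie adjusted Rand index are provided; ARI is the default metric
because it is chance-corrected, with raw Rand available for comparison with
reports that do not specify the variant.

# Trajectories

`diffusion_map()` uses a Gaussian kernel with local bandwidth
$\sigma_i$ = distance to the 15th neighbour (configurable), density
normalization $W'_{ij} = W_{ij}/(q_i q_j)$ (α = 1), and the row-normalized
Markov operator, eigendecomposed through its symmetric conjugate; components
carry a deterministic sign convention. Duplicate cells that collapse the
kernel are separated by a seeded ε-jitter. Pseudotime is the average rank of
cells on the first nontrivial component, sign-flipped so the reference
group's mean rank is minimal.

`dual_axis_pseudotime()` thresholds the two DE tables at FDR < 0.05,
disjoints the gene lists by mutual set difference (lists of 536 and 104
sharing 62 members yield 474 and 42 axis-specific genes), and computes one
diffusion pseudotime per axis. On simulations with independent latents the
recovered axes stay nearly uncorrelated, and restricting the map to an axis's
own genes strictly improves recovery of that axis's latent — both are
properties in the test suite.

`mst_lineage_pseudotime()` joins group centroids (top principal components)
by a Euclidean minimum spanning tree, extracts the start→end path, and
projects every cell orthogonally onto the piecewise-linear path; arc length
from the path start is the pseudotime. `bootstrap_median_rank()` repeats
downsample → co-embed → rank B times and reports each group's median rank per
iteration plus the across-iteration medians; the output deliberately stays at
the group level, since mapping a distribution of median ranks back to
per-cell values would invent structure the procedure does not define.
Co-embedding uses joint per-gene standardization before PCA — a deterministic
substitute for anchor-based integration, adequate here because query and
reference are simulated on a shared gene universe; real cross-chemistry
integration would need more.

`knn_axis_score()` builds a mutual-kNN graph and uses the first nontrivial
eigenvector of its normalized Laplacian, min–max scaled to [0, 1] and
oriented so the reference group scores low. A force-directed layout
coordinate would be seed-dependent; the Laplacian eigenvector is its
deterministic counterpart. Disconnected graphs are scored per component with
a warning (singletons get 0.5).

# Regulons and signatures

Regulon gene lists are inputs (GMT); co-expression inference and motif
pruning are out of scope. `regulon_auc()` ranks each cell's genes by
expression (ties: average rank, then stable gene order) and computes the
recovery-curve area of the targets within the top 5% of ranks (the scorer's
conventional default), normalized by its maximum. The score is invariant to
monotone per-cell transformations. `binarize_activity()` fits a
two-component Gaussian mixture per regulon and thresholds at the
posterior-0.5 crossing, solved analytically from the weighted log densities
(no underflow for well-separated modes); when the component means are closer
than 0.5 pooled standard deviations, or the fit fails, the 75th percentile is
used. `prune_regulon()` intersects targets with the feature genes and keeps
the Kruskal–Wallis group-discriminating subset (BH < 0.05).
`summarize_regulon_activity()` drops regulons with fewer than 100 targets or
active in no more than 10% of cells (strict ">", the adopted reading of an
unstated boundary; configurable), rescales each surviving AUC row by its
maximum over cells, and reports group means.

`module_score()` bins genes by mean expression into 24 bins and samples 100
control genes per set gene from the matching bin (common defaults for this
scorer, configurable); set genes are excluded from the control pools so that
the score is exactly linear in the set genes' expression — a deliberate,
testable deviation from implementations that permit self-contamination.
`patient_cluster_stats()` computes, per cluster and disease status, the
proportion of patients represented and the median per-patient percentage of
cells in the cluster, excluding non-contributing patients from the median but
not from the proportion denominator.

# Projection

`project_cells_to_bulk()` correlates each cell's log2 CPM vector with each
bulk sample over the shared genes — consumed exactly as produced upstream,
with no further transformation — z-scores each cell across samples, and
orders the bulk samples by average-linkage hierarchical clustering on
1−Pearson (the reference tool's linkage is unstated; average linkage is the
configurable default here). Constant profiles yield NA rows/columns with a
warning rather than an error.

# Orchestration, seeds and problem sizes

`run_pipeline()` executes simulate/load → QC → features → clustering → DE →
cytometry → trajectory → regulons → projection from one config, writing
every intermediate table and a JSON report of versions, seeds, parameters,
per-stage counts and warnings. A single global seed fans out to per-stage
seeds through a fixed counter scheme (`stage_seed()`), so toggling one stage
never shifts another's random stream.

The test suite and the acceptance script run at deliberately desk-sized
problems: the four sorted populations (893 cells) with 2,000 genes for
dual-axis recovery; 12-sample, 1,000-gene null designs with 200 replicates
for LRT calibration; and a bootstrap of B = 100 iterations at 50 cells per
group (the full procedure uses 1,000 iterations at 200 cells per group — the
scaled-down version exercises the identical code path). Exhaustive-oracle
checks (permutation distributions, hypergeometric enumeration, closed forms,
step-up FDR, recovery-curve recomputation) pin the statistical primitives at
tiny sizes where brute force is exact.

# Known limitations

* The NB LRT moderates dispersion conservatively; borderline genes that a
  quasi-likelihood F-test with empirical-Bayes shrinkage would call may be
  missed.
* The percentile QC rule is relative by definition and therefore not
  idempotent under reapplication; all absolute rules are.
* The bootstrap's joint standardization is not a replacement for anchor-based
  integration across chemistries or species.
* Consensus clustering is O(n²) in cells (distance matrices, eigendecompositions);
  it is intended for the hundreds-to-few-thousands regime of sorted
  populations, not atlas-scale data.
* The simulator's independence of the two latent axes is an assumption to be
  tested against, not a claim about biology.
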