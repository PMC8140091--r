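# gliaxes

Separating what ageing does to microglia from what plaque phagocytosis does.

In Alzheimer's disease models, microglia that have internalized
methoxy-XO4-labelled amyloid plaques (XO4⁺) acquire a transcriptional state
distinct from that of their non-phagocytic neighbours (XO4⁻), and both kinds
of cell also age. `gliaxes` implements the computational machinery needed to
decompose bulk and single-cell RNA-seq of sorted microglia along these two
axes and to score the resulting states, with a ground-truth simulator so that
every stage can be validated without access to the original data.

## What it computes

* **Covariate-decomposed differential expression.** A negative-binomial
  log-link GLM is fitted per gene (IRLS, vectorized across genes) under a
  full model with all sample covariates (XO4 status, age, region, batch,
  genotype, sex) and a reduced model omitting the covariate of interest;
  genes are called by the likelihood-ratio statistic
  `2(ℓ_full − ℓ_reduced) ~ χ²(Δdf)` with BH correction. Dispersions are
  Cox–Reid adjusted profile-likelihood estimates moderated by a
  mean–dispersion trend; offsets use composition-robust median-of-ratios
  size factors.
* **Gene cytometry.** Each gene gets a score `|LFC| · (−log₁₀ FDR)` on the
  phagocytosis and age axes and a quadrant assignment (XO4-only, XO4-and-age,
  age-only, neither), with overlap percentages between the axes.
* **Consensus clustering** over three distances (Euclidean, 1−Pearson,
  1−Spearman), two spectral transforms (PCA, normalized-Laplacian
  eigenvectors) and k-means across dimensionalities spanning 4–7% of the
  cells, plus a Tracy–Widom random-matrix estimate of the cluster number and
  (adjusted) Rand indices.
* **Dual-axis diffusion pseudotime.** Ageing and phagocytosis DEG lists are
  disjointed by mutual set difference; a diffusion map (local-bandwidth
  Gaussian kernel, density-normalized Markov operator) restricted to each
  axis-specific gene set yields a per-cell rank along that axis.
* **MST lineage pseudotime and a downsampled median-rank bootstrap** for
  placing query cells (e.g. intermediate ages) on a reference ageing
  trajectory: B iterations of downsample → co-embed → rank, summarized by the
  distribution of per-group median ranks.
* **Regulon activity**: rank-based AUC of target recovery among each cell's
  top-expressed genes, Gaussian-mixture binarization, two-stage pruning
  (feature-gene overlap, then Kruskal–Wallis group discrimination), and
  normalized group-mean activity with size/activity filters.
* **Module scores** (expression-matched control genes) and patient-level
  cluster statistics for human cohorts.
* **Projection** of single cells onto bulk reference transcriptomes by
  z-scored Pearson correlation.
* **Overlap statistics**: upper-tail hypergeometric tests in log space,
  Fisher's combined p, one-sided two-proportion z-tests.
* **A two-axis count simulator**: NB counts with
  `μ_gj = s_j · μ_g · 2^(a_j β_g^age + f_j β_g^phago)`, continuous latent
  ageing `a`, switch-like phagocytosis `f`, regulon co-expression structure,
  mitochondrial QC failures, and full ground truth.

## Worked example

```r
library(gliaxes)

cfg  <- sim_config(seed = 2001)            # 4 populations: 243/121/95/434 cells
sim  <- simulate_sc_counts(cfg)
filt <- filter_cells_and_genes(sim$counts) # QC: depth percentile, mito, genes
norm <- normalize_log_cpm(filt)

de_age   <- pairwise_de(filt, "WT6m",   "WT24m")   # ageing contrast
de_phago <- pairwise_de(filt, "XO4neg", "XO4pos")  # phagocytosis contrast
axes <- dual_axis_pseudotime(norm, de_age, de_phago, reference_group = "WT6m")

truth <- sim$truth$cells
cor(axes$joint$ageing_rank,
    truth$a[match(axes$joint$cell_id, truth$cell_id)], method = "spearman")
#> [1] 0.8992814
cor(axes$joint$ageing_rank, axes$joint$phago_rank, method = "spearman")
#> [1] 0.1382487
```

The first number says the recovered ageing order tracks the latent ageing
value closely; the second says the two recovered axes are essentially
uncorrelated, as they were generated. On the same run the phagocytosis rank
separates phagocytosing from non-phagocytosing cells with a rank-sum AUC of
1.0.

The whole pipeline can also be driven from a YAML config:

```r
run_pipeline(list(seed = 1, out_dir = "run",
                  simulate = list(n_genes = 2000),
                  params = list(fdr = 0.05, k = 4)))
```

which writes the QC report, feature list, cluster assignments, DE tables,
gene-cytometry table, pseudotime tables and a JSON run report under `run/`.
A thin command-line wrapper lives at `inst/cli/gliaxes.R`.

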