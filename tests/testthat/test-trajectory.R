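two_group_norm <- function(n = 30, p = 25, gap = 6, seed = 2) {
  set.seed(seed)
  v <- cbind(matrix(rnorm(p * n, 0, 1), p, n),
             matrix(rnorm(p * n, gap, 1), p, n))
  as_norm(v, groups = rep(c("lo", "hi"), each = n))
}

test_that("diffusion map separates two groups on its first component", {
  x <- two_group_norm()
  dm <- diffusion_map(x, n_components = 2, knn = 10)
  grp <- x$cell_meta$group
  side <- sign(dm$components[, 1])
  expect_true(length(unique(side[grp == "lo"])) == 1)
  expect_true(all(side[grp == "lo"] != side[grp == "hi"]))
  # stochastic-matrix spectrum: trivial eigenvalue 1, all others below
  expect_equal(dm$trivial_eigenvalue, 1, tolerance = 1e-8)
  expect_true(all(dm$eigenvalues <= 1 + 1e-8))
  expect_error(diffusion_map(x, knn = 200), "knn")
})

test_that("cell order permutes diffusion components consistently", {
  x <- two_group_norm(seed = 8)
  dm <- diffusion_map(x, n_components = 1, knn = 10)
  perm <- sample(ncol(x$values))
  xp <- subset_norm(x, cells = x$cell_ids[perm])
  dmp <- diffusion_map(xp, n_components = 1, knn = 10)
  expect_equal(dmp$components[x$cell_ids, 1], dm$components[, 1],
               tolerance = 1e-6)
})

test_that("pseudotime ranks a monotone 1-D chain and orients by reference", {
  set.seed(4)
  pos <- seq(0, 10, length.out = 60)
  v <- rbind(a = pos + rnorm(60, 0, 0.05), b = 2 * pos + rnorm(60, 0, 0.05),
             c = -pos + rnorm(60, 0, 0.05))
  grp <- rep(c("start", "end"), each = 30)
  x <- as_norm(v, groups = grp)
  dm <- diffusion_map(x, n_components = 1, knn = 10)
  pt <- pseudotime_from_component(dm$components[, 1], grp, "start")
  expect_gt(cor(pt$rank, pos, method = "spearman"), 0.99)
  expect_lt(mean(pt$rank[grp == "start"]), mean(pt$rank[grp == "end"]))
  expect_setequal(pt$rank, 1:60)   # permutation when untied
  expect_error(pseudotime_from_component(rep(1, 10), rep("a", 10), "a"),
               "degenerate")
})

test_that("axis-specific gene sets are the mutual set differences", {
  phago <- sprintf("p%03d", 1:536)
  ageing <- c(sprintf("p%03d", 1:62), sprintf("a%03d", 1:42))
  sets <- axis_specific_genes(phago, ageing)
  expect_length(sets$phago_specific, 474)
  expect_length(sets$ageing_specific, 42)
  expect_length(intersect(sets$phago_specific, sets$ageing_specific), 0)
})

test_that("dual-axis pseudotime errors when an axis empties out", {
  x <- two_group_norm()
  de_same <- data.frame(gene = x$gene_ids[1:5], fdr = 0.001)
  expect_error(dual_axis_pseudotime(x, de_same, de_same, reference_group = "lo"),
               "empty_axis_genes")
})

test_that("MST lineage pseudotime: two groups order along the centroid axis", {
  x <- two_group_norm(n = 25, seed = 6)
  grp <- x$cell_meta$group
  pt <- mst_lineage_pseudotime(x, grp, n_pcs = 5, "lo", "hi")
  expect_equal(attr(pt, "path"), c("lo", "hi"))
  expect_lt(max(pt$rank[grp == "lo"]), min(pt$rank[grp == "hi"]))
  expect_equal(min(pt$value), 0)
  expect_error(mst_lineage_pseudotime(x, grp, 5, "lo", "lo"), "must differ")
})

test_that("MST path visits collinear centroids in spatial order", {
  set.seed(7)
  p <- 20
  dir <- rnorm(p); dir <- dir / sqrt(sum(dir^2))
  mk <- function(center, n) vapply(seq_len(n), function(i)
    center * dir + rnorm(p, 0, 0.1), numeric(p))
  v <- cbind(mk(0, 20), mk(5, 20), mk(10, 20))
  grp <- rep(c("g0", "g5", "g10"), each = 20)
  x <- as_norm(v, groups = grp)
  pt <- mst_lineage_pseudotime(x, grp, n_pcs = 4, "g0", "g10")
  expect_equal(attr(pt, "path"), c("g0", "g5", "g10"))
  med <- tapply(pt$value, grp, median)
  expect_true(med["g0"] < med["g5"] && med["g5"] < med["g10"])
})

test_that("bootstrap with B = 1 reproduces a single lineage run; seeds fix output", {
  set.seed(10)
  ref <- two_group_norm(n = 30, seed = 10)
  ref$cell_meta$group <- rep(c("start", "end"), each = 30)
  qv <- matrix(rnorm(25 * 40, 3, 1), 25, 40)
  rownames(qv) <- ref$gene_ids
  q <- as_norm(qv, groups = rep("mid", 40))
  q$values <- q$values[ref$gene_ids, ]   # shared gene universe
  b1 <- bootstrap_median_rank(q, ref, B = 1, n_per_group = 20,
                              start_group = "start", end_group = "end",
                              n_pcs = 4, seed = 3)
  b1b <- bootstrap_median_rank(q, ref, B = 1, n_per_group = 20,
                               start_group = "start", end_group = "end",
                               n_pcs = 4, seed = 3)
  expect_identical(b1, b1b)
  expect_equal(dim(b1$median_ranks), c(1L, 3L))
  # warning when a group is smaller than the downsample size
  expect_warning(bootstrap_median_rank(q, ref, B = 1, n_per_group = 100,
                                       start_group = "start", end_group = "end",
                                       n_pcs = 4, seed = 3),
                 "taken whole")
  expect_error(bootstrap_median_rank(q, ref, B = 0, n_per_group = 10,
                                     start_group = "start", end_group = "end"),
               "positive")
})

test_that("kNN axis score separates weakly linked cliques, oriented by reference", {
  set.seed(12)
  # k exceeds the clique size, so the closest cross-pairs form mutual edges
  # and the two dense cliques stay weakly linked in one component
  panel <- rbind(matrix(rnorm(12 * 5, 0, 0.3), 12, 5),
                 matrix(rnorm(12 * 5, 2, 0.3), 12, 5))
  rownames(panel) <- sprintf("cell%02d", 1:24)
  grp <- rep(c("ref", "other"), each = 12)
  sc <- knn_axis_score(panel, k = 14, grp, "ref")
  expect_true(all(sc >= 0 & sc <= 1))
  expect_lt(mean(sc[grp == "ref"]), mean(sc[grp == "other"]))
  expect_lt(max(sc[grp == "ref"]), min(sc[grp == "other"]))  # bimodal split
  # node-order invariance
  perm <- sample(24)
  scp <- knn_axis_score(panel[perm, ], k = 14, grp[perm], "ref")
  expect_equal(scp[rownames(panel)], sc, tolerance = 1e-8)
  # well-separated cliques under mutual kNN disconnect; scored per component
  far <- rbind(matrix(rnorm(40 * 5, 0, 0.3), 40, 5),
               matrix(rnorm(40 * 5, 6, 0.3), 40, 5))
  rownames(far) <- sprintf("f%02d", 1:80)
  expect_warning(knn_axis_score(far, k = 8, rep(c("a", "b"), each = 40), "a"),
                 "disconnected")
})

test_that("axis restriction improves recovery of its own latent variable", {
  sim <- small_sim()
  f <- filter_cells_and_genes(sim$counts)
  norm <- normalize_log_cpm(f)
  tr <- sim$truth$cells[match(norm$cell_ids, sim$truth$cells$cell_id), ]
  tg <- sim$truth$genes
  age_genes <- intersect(tg$gene_id[tg$is_ageing_gene & !tg$is_phago_gene],
                         norm$gene_ids)
  grp <- norm$cell_meta$group
  dm_axis <- diffusion_map(norm, genes = age_genes, n_components = 1, knn = 15)
  dm_full <- diffusion_map(norm, n_components = 1, knn = 15)
  pt_axis <- pseudotime_from_component(dm_axis$components[, 1], grp, "WT6m")
  pt_full <- pseudotime_from_component(dm_full$components[, 1], grp, "WT6m")
  r_axis <- cor(pt_axis$rank, tr$a, method = "spearman")
  r_full <- cor(pt_full$rank, tr$a, method = "spearman")
  expect_gt(r_axis, r_full)
})
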