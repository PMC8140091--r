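test_that("module score is exactly linear in the set genes' expression", {
  norm <- small_norm()
  set_genes <- norm$gene_ids[5:14]
  s0 <- module_score(norm, set_genes, seed = 7)
  bumped <- norm
  bumped$values[set_genes, 3] <- bumped$values[set_genes, 3] + 1.5
  s1 <- module_score(bumped, set_genes, seed = 7)
  expect_equal(unname(s1[3] - s0[3]), 1.5, tolerance = 1e-10)
  expect_equal(s1[-3], s0[-3])
  # same seed, same controls
  expect_identical(s0, module_score(norm, set_genes, seed = 7))
  expect_error(module_score(norm, c("nope1", "nope2")), "missing")
})

test_that("random gene sets score near zero on average", {
  norm <- small_norm()
  set.seed(30)
  means <- replicate(15, {
    gs <- sample(norm$gene_ids, 20)
    mean(module_score(norm, gs, seed = sample.int(1e6, 1)))
  })
  expect_lt(abs(mean(means)), 0.06)
})

test_that("regulon AUC hits its extremes and matches direct recomputation", {
  set.seed(21)
  G <- 120; n <- 50
  v <- matrix(rnorm(G * n), G, n)
  x <- as_norm(v)
  tmax <- ceiling(0.1 * G)
  # targets occupying the very top ranks of cell 1
  top_targets <- order(-v[, 1])[1:5]
  r_top <- regulon_auc(x, x$gene_ids[top_targets], top_fraction = 0.1)
  expect_equal(unname(r_top[1]), 1)
  # targets absent from the top window score zero
  bottom <- order(v[, 2])[1:5]
  r_bot <- regulon_auc(x, x$gene_ids[bottom], top_fraction = 0.1)
  expect_equal(unname(r_bot[2]), 0)
  # oracle: recompute every cell's recovery curve step by step
  targets <- sample(x$gene_ids, 12)
  auc <- regulon_auc(x, targets, top_fraction = 0.1)
  is_t <- x$gene_ids %in% targets
  for (j in seq_len(n)) {
    ord <- order(-v[, j], seq_len(G))
    hits <- cumsum(is_t[ord])[seq_len(tmax)]
    brute <- sum(hits) / sum(pmin(seq_len(tmax), sum(is_t)))
    expect_equal(unname(auc[j]), brute, tolerance = 1e-12)
  }
  expect_error(regulon_auc(x, c("zz1", "zz2")), "no genes")
})

test_that("rank-based AUC is invariant to monotone per-cell transforms", {
  norm <- small_norm()
  targets <- norm$gene_ids[10:40]
  a1 <- regulon_auc(norm, targets)
  mono <- norm
  mono$values <- norm$values^3 + 2 * norm$values   # strictly increasing
  a2 <- regulon_auc(mono, targets)
  expect_equal(a1, a2)
})

test_that("mixture binarization finds the gap between separated modes", {
  set.seed(14)
  scores <- c(rnorm(80, 0.1, 0.02), rnorm(60, 0.8, 0.02))
  a <- structure(list(auc = matrix(scores, 1, dimnames = list("R1", NULL)),
                      n_targets = c(R1 = 150L), binary = NULL,
                      thresholds = NULL), class = "glx_activity")
  b <- binarize_activity(a)
  expect_gt(b$thresholds[1], 0.2)
  expect_lt(b$thresholds[1], 0.7)
  expect_equal(unname(b$binary[1, ]), rep(c(0L, 1L), c(80, 60)))
  # constant scores: all inactive, with a warning
  flat <- a; flat$auc[1, ] <- 0.5
  expect_warning(bf <- binarize_activity(flat), "constant")
  expect_true(all(bf$binary == 0))
})

test_that("binarization threshold preserves 'higher score means active'", {
  set.seed(15)
  scores <- c(rnorm(100, 0.2, 0.05), rnorm(40, 0.6, 0.05))
  a <- structure(list(auc = matrix(scores, 1, dimnames = list("R", NULL)),
                      n_targets = c(R = 120L), binary = NULL,
                      thresholds = NULL), class = "glx_activity")
  b <- binarize_activity(a)
  act <- b$binary[1, ] == 1
  expect_gt(min(scores[act]), max(scores[!act]) - 1e-12)
})

test_that("regulon pruning applies the two-stage filter", {
  sim <- small_sim()
  f <- filter_cells_and_genes(sim$counts)
  norm <- normalize_log_cpm(f)
  groups <- norm$cell_meta$group
  tg <- sim$truth$genes
  strong <- intersect(tg$gene_id[tg$is_phago_gene], norm$gene_ids)[1:25]
  feature_genes <- norm$gene_ids
  r <- glx_regulon("TF1", strong)
  pruned <- prune_regulon(r, feature_genes, norm, groups)
  hist <- attr(pruned, "history")
  expect_equal(unname(hist["feature_overlap"]), 25)
  expect_gt(length(pruned$targets), 15)   # strongly DE targets survive
  expect_true(all(pruned$targets %in% strong))
  # disjoint from the feature set: empty result plus warning
  r2 <- glx_regulon("TF2", c("absent1", "absent2"))
  expect_warning(out <- prune_regulon(r2, feature_genes, norm, groups),
                 "no genes|feature")
  expect_length(out$targets, 0)
})

test_that("activity summaries filter by size and active fraction, then scale", {
  auc <- rbind(big = seq(0.1, 0.6, length.out = 20),
               small = seq(0.1, 0.6, length.out = 20),
               quiet = rep(0.2, 20))
  bin <- rbind(big = rep(c(0, 1), c(10, 10)),
               small = rep(c(0, 1), c(10, 10)),
               quiet = rep(c(0, 1), c(18, 2)))    # active in exactly 10%
  a <- structure(list(auc = auc, n_targets = c(big = 150L, small = 99L,
                                               quiet = 200L),
                      binary = bin, thresholds = c(0.3, 0.3, 0.9)),
                 class = "glx_activity")
  groups <- rep(c("g1", "g2"), each = 10)
  summ <- summarize_regulon_activity(a, groups)
  expect_equal(summ$retained, "big")                 # 99 targets -> excluded
  expect_equal(max(auc["big", ] / max(auc["big", ])), 1)
  expect_equal(unname(summ$group_means["big", "g2"]),
               mean(auc["big", 11:20] / max(auc["big", ])))
  # strict '>' on the active fraction: exactly 10% is excluded
  expect_false("quiet" %in% summ$retained)
  a_empty <- a; a_empty$n_targets[] <- 1L
  expect_warning(summarize_regulon_activity(a_empty, groups), "filtered out")
})

test_that("planted regulon is most active in the phagocytosing group", {
  sim <- small_sim()
  f <- filter_cells_and_genes(sim$counts)
  norm <- normalize_log_cpm(f)
  tg <- sim$truth$genes
  tf <- unique(tg$regulon[!is.na(tg$regulon)])
  targets <- intersect(tg$gene_id[!is.na(tg$regulon)], norm$gene_ids)
  act <- binarize_activity(regulon_activity(norm, list(R = glx_regulon(tf, targets))))
  summ <- summarize_regulon_activity(act, norm$cell_meta$group,
                                     min_targets = 50)
  gm <- summ$group_means["R", ]
  expect_equal(names(which.max(gm)), "XO4pos")
})

test_that("patient-level cluster statistics follow their definitions", {
  one <- data.frame(patient = "p1", status = "AD", cluster = 1)
  st <- patient_cluster_stats(one)
  expect_equal(st$proportion, 1)
  expect_equal(st$percentage, 100)
  # three contributing patients at 10/20/30% -> median 20
  mk_patient <- function(p, n_in, n_out)
    data.frame(patient = p, status = "AD",
               cluster = rep(c("c1", "c2"), c(n_in, n_out)))
  cells <- rbind(mk_patient("p1", 1, 9),   # 10% in c1
                 mk_patient("p2", 2, 8),   # 20%
                 mk_patient("p3", 3, 7),   # 30%
                 mk_patient("p4", 0, 10))  # none in c1
  st <- patient_cluster_stats(cells)
  c1 <- st[st$cluster == "c1" & st$status == "AD", ]
  expect_equal(c1$percentage, 20)          # p4 excluded from the median
  expect_equal(c1$proportion, 3 / 4)       # but counted in the denominator
})

test_that("regulons round-trip through GMT", {
  regs <- list(TFa = glx_regulon("TFa", c("g1", "g2", "g3")),
               TFb = glx_regulon("TFb", c("g9", "g10")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(regs, path)
  back <- read_gmt(path)
  expect_equal(names(back), c("TFa", "TFb"))
  expect_equal(back$TFa$targets, c("g1", "g2", "g3"))
})
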