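test_that("Kruskal-Wallis DE handles constants, shifts and group checks", {
  v <- rbind(flat = rep(2, 8), signal = c(1, 2, 1, 2, 8, 9, 8, 9))
  x <- as_norm(v)
  labels <- rep(c("a", "b"), each = 4)
  de <- kruskal_wallis_de(x, labels)
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_lt(de$p[de$gene == "signal"], 0.05)
  # adding a constant leaves the rank statistic unchanged
  de_shift <- kruskal_wallis_de(as_norm(v + 5), labels)
  expect_equal(de_shift$p, de$p)
  expect_error(kruskal_wallis_de(x, c("a", rep("b", 7))), ">= 2 cells")
})

test_that("Kruskal-Wallis p matches the exhaustive permutation distribution", {
  vals <- c(1, 3, 2, 5, 6, 8, 7, 9)
  labels <- rep(c("a", "b"), each = 4)
  de <- kruskal_wallis_de(as_norm(rbind(g = vals)), labels)
  # oracle: every one of the choose(8,4) relabellings
  kwH <- function(x, g) suppressWarnings(stats::kruskal.test(x, g)$statistic)
  H0 <- kwH(vals, factor(labels))
  splits <- utils::combn(8, 4)
  Hs <- apply(splits, 2, function(i)
    kwH(vals, factor(ifelse(seq_len(8) %in% i, "a", "b"))))
  p_exact <- mean(Hs >= H0 - 1e-12)
  expect_lt(abs(de$p[1] - p_exact), 0.01)
})

test_that("NB LRT reduces to the Poisson GLM in the zero-dispersion limit", {
  counts <- matrix(c(12, 15, 9, 30, 34, 28,
                     5, 7, 6, 6, 5, 7), 2, 6, byrow = TRUE)
  design <- data.frame(grp = rep(c("a", "b"), each = 3))
  X <- stats::model.matrix(~ grp, design)
  off <- rep(log(100), 6)
  fit <- gliaxes:::.nb_irls(counts, X, off, phi = c(0, 0))
  for (g in 1:2) {
    ref <- stats::glm(counts[g, ] ~ grp, data = design, family = stats::poisson(),
                      offset = off)
    expect_equal(fit$loglik[g], as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    expect_equal(fit$beta[g, ], unname(stats::coef(ref)), tolerance = 1e-6)
  }
})

test_that("NB LRT agrees with per-gene glm fits at fixed dispersion", {
  skip_if_not_installed("MASS")
  sim <- small_sim()
  sub <- subset_counts(sim$counts, genes = sim$counts$gene_ids[1:40])
  design <- data.frame(group = factor(sim$counts$cell_meta$group))
  de <- suppressWarnings(nb_glm_lrt(sub, design, ~ group, ~ 1))
  Y <- as.matrix(sub$counts)
  s <- gliaxes:::.de_size_factors(Y)
  off <- log(s * mean(colSums(Y)))
  pilot <- gliaxes:::.nb_irls(Y, stats::model.matrix(~ group, design), off,
                              rep(0, nrow(Y)))
  phi0 <- gliaxes:::.moment_dispersion(Y, exp(pilot$eta), 4)
  refit <- gliaxes:::.nb_irls(Y, stats::model.matrix(~ group, design), off, phi0)
  phi <- gliaxes:::.trended_dispersion(Y, stats::model.matrix(~ group, design),
                                       exp(refit$eta), 4)
  for (g in c(1, 7, 23)) {
    th <- 1 / phi[g]
    f1 <- stats::glm(Y[g, ] ~ group, data = design, offset = off,
                     family = MASS::negative.binomial(theta = th))
    f0 <- stats::glm(Y[g, ] ~ 1, data = design, offset = off,
                     family = MASS::negative.binomial(theta = th))
    p_ref <- stats::pchisq(2 * (stats::logLik(f1) - stats::logLik(f0)), 1,
                           lower.tail = FALSE)
    expect_equal(de$p[g], as.numeric(p_ref), tolerance = 1e-3)
  }
})

test_that("LRT is invariant to the factor baseline and rejects rank deficiency", {
  sim <- small_sim()
  sub <- subset_counts(sim$counts, genes = sim$counts$gene_ids[1:30])
  g <- sim$counts$cell_meta$group
  d1 <- data.frame(group = factor(g, levels = c("WT6m", "WT24m", "XO4neg", "XO4pos")))
  d2 <- data.frame(group = factor(g, levels = c("XO4pos", "XO4neg", "WT24m", "WT6m")))
  de1 <- suppressWarnings(nb_glm_lrt(sub, d1, ~ group, ~ 1))
  de2 <- suppressWarnings(nb_glm_lrt(sub, d2, ~ group, ~ 1))
  expect_equal(de1$p, de2$p, tolerance = 1e-5)
  dup <- data.frame(a = g, b = g)
  expect_error(nb_glm_lrt(sub, dup, ~ a + b, ~ a), "rank deficient")
})

test_that("gene cytometry scores, quadrants and overlap percentages", {
  xo4 <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    lfc = c(2, -1, 0.5, 3),
                    fdr = c(0.01, 0.02, 0.5, 1))
  age <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    lfc = c(1, 2, -2, 1),
                    fdr = c(0.04, 0.2, 0.01, 1))
  cyt <- gene_cytometry(xo4, age, fdr_threshold = 0.05)
  tab <- cyt$table
  expect_equal(tab$score_xo4[tab$gene == "g1"], 2 * -log10(0.01)) # lfc 2, fdr 0.01 -> 4
  expect_equal(tab$score_xo4[tab$gene == "g4"], 0)                # fdr 1 -> score 0
  expect_equal(tab$quadrant,
               c("XO4_and_age", "XO4_only", "age_only", "neither"))
  expect_equal(cyt$overlap$n_xo4, 2)
  expect_equal(cyt$overlap$n_both, 1)
  expect_equal(cyt$overlap$pct_both, 50)
  expect_equal(unname(cyt$quadrant_counts["XO4_only"]), 1L)
  # printed-precision reporting helper
  expect_equal(overlap_percentage(902, 2302, 0), 39)
  expect_equal(overlap_percentage(1320, 2364, 0), 56)
  expect_equal(overlap_percentage(2031, 2810, 1), 72.3)
  expect_equal(overlap_percentage(344, 536, 1), 64.2)
})

test_that("gene score is monotone in |LFC| and FDR", {
  fdrs <- c(0.5, 0.1, 0.01, 1e-5)
  base <- data.frame(gene = paste0("g", 1:4), lfc = 1, fdr = fdrs)
  cyt <- gene_cytometry(base, base, fdr_threshold = 0.05)
  expect_true(all(diff(cyt$table$score_xo4) > 0))
  lfcs <- data.frame(gene = paste0("g", 1:4), lfc = c(0.5, 1, 2, 4), fdr = 0.01)
  cyt2 <- gene_cytometry(lfcs, lfcs, fdr_threshold = 0.05)
  expect_true(all(diff(cyt2$table$score_xo4) > 0))
  # underflowing FDR is capped, not infinite
  tiny <- data.frame(gene = "g", lfc = 1, fdr = 1e-400)
  expect_equal(gene_cytometry(tiny, tiny)$table$score_xo4, 320)
})

test_that("hypergeometric upper tail matches brute-force enumeration", {
  # universe of 10 genes, 4 marked, draw 5: enumerate all draws
  u <- 10; marked <- 4; s <- 5
  draws <- utils::combn(u, s)
  for (ov in 0:4) {
    brute <- mean(apply(draws, 2, function(d) sum(d <= marked) >= ov))
    expect_equal(overlap_hypergeometric(ov, marked, u, s)$p, brute,
                 tolerance = 1e-12)
  }
  expect_equal(overlap_hypergeometric(0, 50, 1000, 100)$p, 1)
  expect_error(overlap_hypergeometric(10, 5, 100, 8), "inconsistent")
})

test_that("Fisher's method matches the two-test closed form", {
  p1 <- 0.03; p2 <- 0.2
  res <- combine_pvalues_fisher(c(p1, p2))
  k <- p1 * p2
  expect_equal(res$p, k * (1 - log(k)), tolerance = 1e-12)
  expect_equal(combine_pvalues_fisher(c(1, 1, 1))$statistic, 0)
  expect_equal(combine_pvalues_fisher(c(1, 1, 1))$p, 1)
  expect_equal(combine_pvalues_fisher(0.07)$p, 0.07, tolerance = 1e-12)
  expect_error(combine_pvalues_fisher(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("two-proportion z-test: symmetry, equality and exact-test agreement", {
  eq <- two_proportion_test(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)
  a <- two_proportion_test(20, 40, 10, 38)
  b <- two_proportion_test(10, 38, 20, 40)
  expect_equal(a$z, -b$z)
  # small counts stay close to the exact conditional (Fisher) test
  exact <- stats::fisher.test(matrix(c(20, 20, 10, 28), 2, byrow = TRUE),
                              alternative = "greater")$p.value
  expect_lt(abs(a$p - exact), 0.02)
  expect_warning(two_proportion_test(0, 5, 0, 8), "degenerate")
})

test_that("BH correction equals an independent step-up implementation", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(gliaxes:::.bh(p), bh_reference(p), tolerance = 1e-12)
  }
})
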