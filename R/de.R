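#' Kruskal-Wallis differential expression across groups
#'
#' Tie-corrected H statistic per gene on normalized expression, chi-squared
#' p-values on k-1 degrees of freedom, BH correction across genes. Genes that
#' are constant across all cells get H = 0, p = 1.
#'
#' @param x `glx_norm`.
#' @param labels Group label per cell (length = n cells, >= 2 groups with >= 2
#'   cells each).
#' @param alpha FDR threshold used to flag the significant set.
#' @return `data.frame(gene, lfc, p, fdr, significant, contrast)`; `lfc` is NA
#'   for this omnibus test.
#' @export
kruskal_wallis_de <- function(x, labels, alpha = 0.05) {
  stopifnot(inherits(x, "glx_norm"))
  labels <- as.factor(labels)
  if (length(labels) != ncol(x$values))
    stop("one label per cell required")
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) < 2)) stop("every group needs >= 2 cells")
  v <- x$values
  p <- apply(v, 1, function(row) {
    if (max(row) == min(row)) return(1)
    stats::kruskal.test(row, labels)$p.value
  })
  fdr <- .bh(p)
  data.frame(gene = x$gene_ids, lfc = NA_real_, p = p, fdr = fdr,
             significant = fdr < alpha, contrast = "kruskal_wallis",
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- negative-binomial GLM likelihood-ratio machinery -----------------------

# Batched Cholesky over G stacked p x p symmetric matrices held as rows of a
# G x p^2 matrix (column-major within the row). Returns the stacked lower
# factor plus a validity flag per gene; p is small (model coefficients), so
# the k/i/j loops are over at most p^3/6 elementwise vector operations across
# all genes at once.
.chol_batch <- function(A, p) {
  G <- nrow(A)
  L <- matrix(0, G, p * p)
  at <- function(M, i, j) M[, (j - 1) * p + i]
  ok <- rep(TRUE, G)
  for (j in seq_len(p)) {
    s <- at(A, j, j)
    if (j > 1) for (k in seq_len(j - 1)) s <- s - at(L, j, k)^2
    ok <- ok & (s > 0) & is.finite(s)
    Ljj <- sqrt(pmax(s, 1e-300))
    L[, (j - 1) * p + j] <- Ljj
    if (j < p) for (i in (j + 1):p) {
      s <- at(A, i, j)
      if (j > 1) for (k in seq_len(j - 1)) s <- s - at(L, i, k) * at(L, j, k)
      L[, (j - 1) * p + i] <- s / Ljj
    }
  }
  list(L = L, ok = ok)
}

# Solve (L L') b = c for all genes given the batched factor.
.chol_solve_batch <- function(L, C, p) {
  at <- function(M, i, j) M[, (j - 1) * p + i]
  Yv <- matrix(0, nrow(C), p)
  for (i in seq_len(p)) {
    s <- C[, i]
    if (i > 1) for (k in seq_len(i - 1)) s <- s - at(L, i, k) * Yv[, k]
    Yv[, i] <- s / at(L, i, i)
  }
  B <- matrix(0, nrow(C), p)
  for (i in rev(seq_len(p))) {
    s <- Yv[, i]
    if (i < p) for (k in (i + 1):p) s <- s - at(L, k, i) * B[, k]
    B[, i] <- s / at(L, i, i)
  }
  B
}

# Vectorized-across-genes IRLS for an NB log-link GLM with known per-gene
# dispersion phi (phi = 0 gives the Poisson limit). All genes share the design
# matrix X, so each IRLS update is a handful of matrix products plus a batched
# Cholesky solve across genes.
#
# Y: G x S counts; X: S x p full-rank design; offset: length-S log-exposure;
# phi: length-G dispersions. Returns beta (G x p), eta (G x S), loglik (G),
# converged (G).
.nb_irls <- function(Y, X, offset, phi, max_iter = 50, tol = 1e-8) {
  G <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  off <- matrix(offset, G, S, byrow = TRUE)
  # pairwise products of design columns, for XtWX assembled per gene
  pair_idx <- expand.grid(a = seq_len(p), b = seq_len(p))
  XX <- X[, pair_idx$a, drop = FALSE] * X[, pair_idx$b, drop = FALSE] # S x p^2
  Z0 <- log(Y + 0.5) - off
  B <- Z0 %*% X %*% solve(crossprod(X))
  failed <- rep(FALSE, G)
  PHI <- matrix(phi, G, S)
  ETA <- pmin(pmax(B %*% t(X) + off, -30), 30)
  for (it in seq_len(max_iter)) {
    MU <- exp(ETA)
    W <- MU / (1 + PHI * MU)
    Zw <- (ETA - off) + (Y - MU) / MU
    A <- W %*% XX            # G x p^2
    Cm <- (W * Zw) %*% X     # G x p
    ch <- .chol_batch(A, p)
    Bn <- .chol_solve_batch(ch$L, Cm, p)
    bad <- !ch$ok | rowSums(!is.finite(Bn)) > 0
    failed <- failed | bad
    Bn[bad, ] <- B[bad, , drop = FALSE]
    ETA_new <- pmin(pmax(Bn %*% t(X) + off, -30), 30)
    delta <- max(abs(ETA_new - ETA))
    B <- Bn
    ETA <- ETA_new
    if (delta < tol) break
  }
  MU <- exp(ETA)
  ll <- .nb_loglik_rows(Y, MU, phi)
  list(beta = B, eta = ETA, loglik = ll, converged = !failed)
}

.nb_loglik_rows <- function(Y, MU, phi) {
  G <- nrow(Y)
  ll <- numeric(G)
  pois <- phi < 1e-10
  if (any(pois))
    ll[pois] <- rowSums(stats::dpois(Y[pois, , drop = FALSE],
                                     MU[pois, , drop = FALSE], log = TRUE))
  if (any(!pois)) {
    idx <- which(!pois)
    SZ <- matrix(1 / phi[idx], length(idx), ncol(Y))
    ll[idx] <- rowSums(stats::dnbinom(Y[idx, , drop = FALSE], size = SZ,
                                      mu = MU[idx, , drop = FALSE], log = TRUE))
  }
  ll
}

.nb_deviance_rows <- function(Y, MU, PHI) {
  # 2 * (loglik at saturated mu = y) - loglik(mu); constant terms cancel in
  # the convergence check, so unit NB deviance is enough
  yl <- ifelse(Y > 0, Y * log(Y / MU), 0)
  tail <- (Y + 1 / pmax(PHI, 1e-12)) *
    log((1 + PHI * Y) / (1 + PHI * MU)) / ifelse(PHI < 1e-10, NA, 1)
  tail[PHI < 1e-10] <- (Y - MU)[PHI < 1e-10]
  rowSums(2 * (yl - tail))
}

# Size factors for DE offsets. Median-of-ratios (zero-tolerant variant: the
# per-gene reference is the geometric mean over samples with a positive
# count, and each sample's factor is the median ratio over its detected
# genes) corrects the composition bias that raw library sizes suffer when
# many genes shift in one direction. Factors are rescaled to mean 1.
.de_size_factors <- function(Y, method = c("median_ratio", "library_size")) {
  method <- match.arg(method)
  totals <- colSums(Y)
  if (method == "library_size") return(totals / mean(totals))
  logY <- log(Y)
  logY[!is.finite(logY)] <- NA
  logref <- rowMeans(logY, na.rm = TRUE)
  use <- is.finite(logref)
  s <- vapply(seq_len(ncol(Y)), function(j) {
    lr <- logY[use, j] - logref[use]
    lr <- lr[is.finite(lr)]
    if (!length(lr)) return(NA_real_)
    exp(stats::median(lr))
  }, numeric(1))
  if (anyNA(s)) s[is.na(s)] <- (totals / mean(totals))[is.na(s)]
  s / mean(s)
}

# Moment estimate of per-gene NB dispersion given fitted means MU. Solves the
# Pearson estimating equation sum (y-mu)^2 / (mu (1 + phi mu)) = S - p per
# gene (monotone decreasing in phi, bisection); genes whose Pearson statistic
# is below the residual df at phi = 0 are at the Poisson boundary.
.moment_dispersion <- function(Y, MU, df_model, floor = 1e-8) {
  S <- ncol(Y)
  df_res <- max(S - df_model, 1)
  MU <- pmax(MU, 1e-12)
  R2 <- (Y - MU)^2
  pearson_at <- function(phi) rowSums(R2 / (MU * (1 + phi * MU)))
  phi <- numeric(nrow(Y))
  active <- pearson_at(0) > df_res
  if (any(active)) {
    lo <- rep(0, sum(active)); hi <- rep(1, sum(active))
    Ra <- R2[active, , drop = FALSE]; Ma <- MU[active, , drop = FALSE]
    f <- function(phi_vec)
      rowSums(Ra / (Ma * (1 + phi_vec * Ma))) - df_res
    while (any(f(hi) > 0) && max(hi) < 1e8) hi <- ifelse(f(hi) > 0, hi * 10, hi)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      pos <- f(mid) > 0
      lo <- ifelse(pos, mid, lo)
      hi <- ifelse(pos, hi, mid)
    }
    phi[active] <- (lo + hi) / 2
  }
  pmax(phi, floor)
}

# Cox-Reid adjusted profile likelihood dispersion, maximized per gene on a
# log-spaced grid given fitted means MU (the REML-style adjustment
# -0.5 log det(X'WX) removes most of the downward bias that plug-in fitted
# means cause at bulk sample sizes).
.cr_ml_dispersion <- function(Y, X, MU, grid = 10^seq(-6, 2.5, length.out = 40)) {
  G <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  pair_idx <- expand.grid(a = seq_len(p), b = seq_len(p))
  XX <- X[, pair_idx$a, drop = FALSE] * X[, pair_idx$b, drop = FALSE]
  apl <- matrix(-Inf, G, length(grid))
  for (k in seq_along(grid)) {
    phi <- grid[k]
    ll <- rowSums(stats::dnbinom(Y, size = 1 / phi, mu = MU, log = TRUE))
    W <- MU / (1 + phi * MU)
    A <- W %*% XX
    ch <- .chol_batch(A, p)
    diag_idx <- (seq_len(p) - 1) * p + seq_len(p)
    cr <- 2 * rowSums(log(ch$L[, diag_idx, drop = FALSE]))
    cr[!ch$ok] <- 0
    apl[, k] <- ll - 0.5 * cr
  }
  grid[max.col(apl, ties.method = "first")]
}

# Trend-moderated dispersion: gene-wise estimates are noisy at typical bulk
# sample sizes and make the LRT anti-conservative, so a mean-dispersion trend
# phi(mu) = a0 + a1/mu is fitted across the CR-ML estimates (robust L1-style
# iterated reweighting) and each gene gets the larger of trend and gene-wise
# value -- erring on the conservative side, as the LRT has no analogue of the
# quasi-likelihood F-test's uncertainty propagation.
.trended_dispersion <- function(Y, X, MU, df_model, floor = 1e-8) {
  raw <- .cr_ml_dispersion(Y, X, MU)
  mu_bar <- pmax(rowMeans(MU), 1e-6)
  xv <- 1 / mu_bar
  w <- rep(1, length(raw))
  for (it in 1:5) {
    fit <- stats::lm.wfit(cbind(1, xv), raw, w)
    ab <- pmax(fit$coefficients, 0)
    resid <- raw - (ab[1] + ab[2] * xv)
    w <- 1 / pmax(abs(resid), stats::median(abs(resid)) + 1e-12)
  }
  trend <- ab[1] + ab[2] * xv
  pmax(trend, raw, floor)
}

#' Negative-binomial GLM likelihood-ratio test per gene
#'
#' Fits a log-link NB GLM to every gene under a full and a reduced covariate
#' model (IRLS, vectorized across genes) with a shared moment-based dispersion
#' estimated once under the full model (floored at 1e-8), and compares them by
#' a likelihood-ratio chi-squared test. Genes significant for a covariate are
#' those whose expression the dropped covariate explains.
#'
#' @param m `glx_counts` of bulk (or pseudo-bulk) samples.
#' @param design `data.frame` of sample covariates, rows aligned with the
#'   columns of `m`.
#' @param full,reduced One-sided formulas (or character vectors of term
#'   labels). `reduced` must nest inside `full`.
#' @param alpha BH-FDR threshold for the significant flag.
#' @param size_factors `"median_ratio"` (default; composition-robust) or
#'   `"library_size"` offsets.
#' @return `data.frame(gene, lfc, p, fdr, significant, contrast)`. `lfc` is
#'   the log2 fold change of the dropped covariate when that covariate is a
#'   single column (e.g. a two-level factor), else NA. Non-converged genes get
#'   p = NA, are excluded from the BH correction, and are counted in a
#'   warning.
#' @export
nb_glm_lrt <- function(m, design, full, reduced, alpha = 0.05,
                       size_factors = c("median_ratio", "library_size")) {
  stopifnot(inherits(m, "glx_counts"))
  design <- as.data.frame(design)
  if (nrow(design) != ncol(m$counts))
    stop("design rows must match the number of samples")
  to_formula <- function(f) {
    if (inherits(f, "formula")) f
    else if (length(f) == 0 || identical(f, "1")) ~ 1
    else stats::as.formula(paste("~", paste(f, collapse = " + ")))
  }
  Xf <- stats::model.matrix(to_formula(full), design)
  Xr <- stats::model.matrix(to_formula(reduced), design)
  if (!all(colnames(Xr) %in% colnames(Xf)))
    stop("reduced model terms must be a subset of the full model")
  if (qr(Xf)$rank < ncol(Xf) || qr(Xr)$rank < ncol(Xr))
    stop("design_rank_deficient: model matrix is rank deficient")
  ddf <- ncol(Xf) - ncol(Xr)
  if (ddf < 1) stop("full model must have more terms than the reduced model")

  Y <- as.matrix(m$counts)
  s <- .de_size_factors(Y, match.arg(size_factors))
  offset <- log(s * mean(colSums(Y)))
  # Poisson pilot fit under the full model -> moment dispersion shared by
  # both models
  pilot <- .nb_irls(Y, Xf, offset, phi = rep(0, nrow(Y)))
  phi0 <- .moment_dispersion(Y, exp(pilot$eta), df_model = ncol(Xf))
  refit <- .nb_irls(Y, Xf, offset, phi0)
  phi <- .trended_dispersion(Y, Xf, exp(refit$eta), df_model = ncol(Xf))
  fit_full <- .nb_irls(Y, Xf, offset, phi)
  fit_red <- .nb_irls(Y, Xr, offset, phi)

  lrt <- pmax(2 * (fit_full$loglik - fit_red$loglik), 0)
  ok <- fit_full$converged & fit_red$converged
  p <- ifelse(ok, stats::pchisq(lrt, df = ddf, lower.tail = FALSE), NA_real_)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " gene(s) did not converge; p set to NA and excluded from BH")
  fdr <- rep(NA_real_, length(p))
  fdr[ok] <- .bh(p[ok])

  dropped <- setdiff(colnames(Xf), colnames(Xr))
  lfc <- rep(NA_real_, nrow(Y))
  if (length(dropped) == 1L)
    lfc <- fit_full$beta[, match(dropped, colnames(Xf))] / log(2)
  data.frame(gene = m$gene_ids, lfc = lfc, p = p, fdr = fdr,
             significant = !is.na(fdr) & fdr < alpha,
             contrast = paste0("LRT:", paste(dropped, collapse = "+")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene cytometry: FDR-weighted fold-change scores on two contrast axes
#'
#' For each gene and each axis (plaque phagocytosis and age), the score is
#' `|LFC| * -log10(FDR)` (capped at -log10(FDR) = 320), with a signed variant
#' `sign(LFC) * score`. Genes are assigned to quadrants by which axes pass the
#' FDR threshold: Q1 = XO4-only, Q2 = XO4-and-age, Q3 = age-only,
#' Q4 = neither.
#'
#' @param xo4_de,age_de DE tables sharing a gene universe (columns `gene`,
#'   `lfc`, `fdr`).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return List with `table` (per-gene scores and quadrant), `quadrant_counts`,
#'   and `overlap`: `n_xo4` (genes significant on the XO4 axis), `n_both`, and
#'   `pct_both = 100 * n_both / n_xo4` (NA when `n_xo4` is zero).
#' @export
gene_cytometry <- function(xo4_de, age_de, fdr_threshold = 0.05) {
  shared <- intersect(xo4_de$gene, age_de$gene)
  if (!length(shared)) stop("DE results share no genes")
  a <- xo4_de[match(shared, xo4_de$gene), ]
  b <- age_de[match(shared, age_de$gene), ]
  score <- function(d) abs(d$lfc) * .neglog10(d$fdr)
  s_x <- score(a); s_a <- score(b)
  sig_x <- !is.na(a$fdr) & a$fdr < fdr_threshold
  sig_a <- !is.na(b$fdr) & b$fdr < fdr_threshold
  quadrant <- ifelse(sig_x & sig_a, "XO4_and_age",
              ifelse(sig_x, "XO4_only",
              ifelse(sig_a, "age_only", "neither")))
  tab <- data.frame(gene = shared,
                    score_xo4 = s_x, signed_score_xo4 = sign(a$lfc) * s_x,
                    score_age = s_a, signed_score_age = sign(b$lfc) * s_a,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  n_xo4 <- sum(sig_x); n_both <- sum(sig_x & sig_a)
  list(table = tab,
       quadrant_counts = table(factor(quadrant,
                                      levels = c("XO4_only", "XO4_and_age",
                                                 "age_only", "neither"))),
       overlap = list(n_xo4 = n_xo4, n_both = n_both,
                      pct_both = if (n_xo4 > 0) 100 * n_both / n_xo4
                                 else NA_real_))
}

#' Percentage of one count in another, at a chosen printed precision
#'
#' @param n_part,n_total Counts.
#' @param digits Decimal digits to round to.
#' @return `100 * n_part / n_total`, rounded.
#' @export
overlap_percentage <- function(n_part, n_total, digits = 0) {
  if (n_total == 0) return(NA_real_)
  round(100 * n_part / n_total, digits)
}

#' Upper-tail hypergeometric overlap probability
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe, marked, sample): the
#' chance of drawing at least `overlap` marked genes when `sample` genes are
#' drawn without replacement from a universe containing `marked` marked genes.
#' Computed in log space for stability.
#'
#' @param overlap Observed overlap count.
#' @param marked Number of marked genes in the universe.
#' @param universe Universe size.
#' @param sample Number of genes drawn.
#' @return List with `p` (upper-tail probability) and `log10_p`.
#' @export
overlap_hypergeometric <- function(overlap, marked, universe, sample) {
  for (v in c(overlap, marked, universe, sample))
    .assert_scalar_count(v + 1, "counts")  # allow zero
  if (overlap > min(marked, sample) || sample > universe || marked > universe)
    stop("inconsistent counts: need overlap <= min(marked, sample) and ",
         "marked, sample <= universe")
  lp <- stats::phyper(overlap - 1, marked, universe - marked, sample,
                      lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), log10_p = lp / log(10))
}

#' Fisher's method (sum of logs) for combining p-values
#'
#' @param ps Vector of p-values in (0, 1]. Exact zeros are rejected; floor
#'   them before calling.
#' @return List with `statistic` (X^2 = -2 sum log p), `df` (2m) and `p`.
#' @export
combine_pvalues_fisher <- function(ps) {
  if (!length(ps)) stop("no p-values supplied")
  if (any(is.na(ps)) || any(ps <= 0) || any(ps > 1))
    stop("all p-values must lie in (0, 1]; floor zeros before combining")
  x2 <- -2 * sum(log(ps))
  df <- 2 * length(ps)
  list(statistic = x2, df = df,
       p = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' One-sided two-proportion z-test (pooled variance)
#'
#' @param x1,n1,x2,n2 Successes and totals in the two groups.
#' @param alternative `"greater"` tests p1 > p2; `"less"` tests p1 < p2.
#' @return List with `z`, `p` and the two sample proportions. When the pooled
#'   proportion is 0 or 1 the test is degenerate: `p` is 1 (or 0 if the
#'   one-sided difference is already realized), with a warning.
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    warning("degenerate pooled proportion (0 or 1); p set by convention")
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(z = z, p = p, p1 = p1, p2 = p2, degenerate = FALSE)
}

#' Pairwise differential expression between two groups (NB LRT)
#'
#' Convenience wrapper: restricts the counts to two groups and runs the
#' NB GLM likelihood-ratio test of `~ group` against `~ 1`, reporting the
#' log2 fold change of `g2` relative to `g1`.
#'
#' @param m `glx_counts` with a `group` column in `cell_meta`.
#' @param g1,g2 Group labels (baseline, comparison).
#' @param alpha FDR threshold.
#' @return DE `data.frame` as in [nb_glm_lrt()].
#' @export
pairwise_de <- function(m, g1, g2, alpha = 0.05) {
  stopifnot(inherits(m, "glx_counts"))
  keep <- m$cell_meta$group %in% c(g1, g2)
  sub <- subset_counts(m, cells = m$cell_ids[keep])
  expressed <- Matrix::rowSums(sub$counts) > 0
  sub <- subset_counts(sub, genes = sub$gene_ids[expressed])
  design <- data.frame(group = factor(sub$cell_meta$group, levels = c(g1, g2)))
  out <- nb_glm_lrt(sub, design, full = ~ group, reduced = ~ 1, alpha = alpha)
  out$contrast <- paste0(g2, "_vs_", g1)
  out
}
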