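# Consensus clustering of single cells: several distance metrics, two
# spectral transformations, k-means over a range of dimensionalities, and an
# averaged co-clustering matrix cut by complete-linkage hierarchical
# clustering.

# k-means++ seeding followed by Lloyd iterations; `restarts` independent
# initializations, best total within-SS kept. RNG is the caller's stream.
.kmeans_pp <- function(pts, k, restarts = 10, iter_max = 100) {
  n <- nrow(pts)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(pts))
    centers[1, ] <- pts[sample.int(n, 1), ]
    if (k > 1) for (j in 2:k) {
      d2 <- apply(centers[seq_len(j - 1), , drop = FALSE], 1, function(cc)
        rowSums(sweep(pts, 2, cc)^2))
      mind2 <- if (is.matrix(d2)) apply(d2, 1, min) else d2
      probs <- if (sum(mind2) > 0) mind2 / sum(mind2) else rep(1 / n, n)
      centers[j, ] <- pts[sample.int(n, 1, prob = probs), ]
    }
    fit <- tryCatch(
      stats::kmeans(pts, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) stats::kmeans(pts, centers = k, iter.max = iter_max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

# Normalized graph Laplacian of a similarity built from a distance matrix
# (A = exp(-D / max(D))), eigenvectors ordered by increasing eigenvalue.
.laplacian_transform <- function(D) {
  A <- exp(-D / max(D))
  dd <- rowSums(A)
  L <- diag(nrow(A)) - t(A / sqrt(dd)) / sqrt(dd)
  e <- eigen(L, symmetric = TRUE)
  e$vectors[, order(e$values), drop = FALSE]
}

#' Consensus clustering of cells over distances, transforms and dimensions
#'
#' Distances (Euclidean, 1 - Pearson, 1 - Spearman) are each transformed by
#' PCA and by normalized-Laplacian eigendecomposition; k-means (k-means++
#' seeding, 10 restarts) is run on the first `d` components for every `d`
#' spanning 4-7% of the number of cells; the consensus matrix is the mean of
#' the binary co-clustering matrices, and the final partition cuts its
#' complete-linkage dendrogram at `k`.
#'
#' @param x `glx_norm`, typically restricted to the feature genes.
#' @param k Number of clusters (< number of cells).
#' @param seed Integer seed for the k-means restarts.
#' @param d_range Optional integer vector of component counts; default
#'   `floor(0.04 n) .. ceiling(0.07 n)`, clamped to `[2, n - 1]`.
#' @return List of class `glx_clusters`: `cluster` (named integer vector),
#'   `consensus` (cells x cells, entries are multiples of 1 / #runs),
#'   `k`, `n_runs`.
#' @export
consensus_cluster <- function(x, k, seed = 1L, d_range = NULL) {
  stopifnot(inherits(x, "glx_norm"))
  n <- ncol(x$values)
  .assert_scalar_count(k, "k")
  if (k >= n) stop("k must be smaller than the number of cells")
  if (nrow(x$values) < 2) stop("need >= 2 feature genes")
  pts <- t(x$values)
  if (is.null(d_range))
    d_range <- seq(floor(0.04 * n), ceiling(0.07 * n))
  d_range <- sort(unique(pmin(pmax(d_range, 2L), n - 1L)))

  dists <- list(
    euclidean = as.matrix(stats::dist(pts)),
    pearson = 1 - stats::cor(x$values),
    spearman = 1 - stats::cor(x$values, method = "spearman"))
  set.seed(seed)
  consensus <- matrix(0, n, n)
  n_runs <- 0L
  for (D in dists) {
    D[is.na(D)] <- max(D, na.rm = TRUE)
    scale_ok <- all(apply(D, 2, stats::sd) > 0)
    pca <- stats::prcomp(D, center = TRUE, scale. = scale_ok)$x
    lap <- .laplacian_transform(D)
    for (comp in list(pca, lap)) {
      for (d in d_range) {
        cl <- .kmeans_pp(comp[, seq_len(min(d, ncol(comp))), drop = FALSE], k)
        consensus <- consensus + outer(cl, cl, `==`)
        n_runs <- n_runs + 1L
      }
    }
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(x$cell_ids, x$cell_ids)
  final <- if (k == 1L) stats::setNames(rep(1L, n), x$cell_ids) else
    stats::cutree(stats::hclust(stats::as.dist(1 - consensus),
                                method = "complete"), k)
  structure(list(cluster = stats::setNames(as.integer(final), x$cell_ids),
                 consensus = consensus, k = as.integer(k), n_runs = n_runs,
                 d_range = d_range),
            class = "glx_clusters")
}

#' Estimate the number of clusters by a random-matrix (Tracy-Widom) bound
#'
#' Counts the eigenvalues of the scaled sample covariance (cells x cells
#' cross-product of the gene-standardized expression matrix) that exceed the
#' Tracy-Widom-based significance bound; at least 1 is returned.
#'
#' @param x `glx_norm`.
#' @return Integer cluster-number estimate.
#' @export
estimate_k <- function(x) {
  stopifnot(inherits(x, "glx_norm"))
  v <- x$values                      # genes x cells
  if (ncol(v) < 3) stop("need >= 3 cells")
  n <- nrow(v); p <- ncol(v)
  sds <- apply(v, 2, stats::sd)
  if (all(sds == 0) || stats::sd(as.vector(v)) == 0) {
    warning("degenerate (constant) matrix; returning k = 1")
    return(1L)
  }
  xs <- scale(v)
  xs[, sds == 0] <- 0
  muTW <- (sqrt(n - 1) + sqrt(p))^2
  sigmaTW <- (sqrt(n - 1) + sqrt(p)) * (1 / sqrt(n - 1) + 1 / sqrt(p))^(1 / 3)
  bound <- muTW + 3.273 * sigmaTW    # ~0.001 upper-tail significance point
  evals <- eigen(crossprod(xs), symmetric = TRUE, only.values = TRUE)$values
  max(1L, sum(evals > bound))
}

#' Adjusted (Hubert-Arabie) and raw Rand indices between two partitions
#'
#' @param labels_a,labels_b Cluster labels of the same items.
#' @return For [adjusted_rand_index()], the ARI; for [rand_index()], the raw
#'   Rand index (fraction of concordant pairs).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  ct <- .pair_contingency(labels_a, labels_b)
  sum_ij <- sum(choose(ct$tab, 2))
  sum_a <- sum(choose(rowSums(ct$tab), 2))
  sum_b <- sum(choose(colSums(ct$tab), 2))
  total <- choose(ct$n, 2)
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}

#' @rdname adjusted_rand_index
#' @export
rand_index <- function(labels_a, labels_b) {
  ct <- .pair_contingency(labels_a, labels_b)
  sum_ij <- sum(choose(ct$tab, 2))
  sum_a <- sum(choose(rowSums(ct$tab), 2))
  sum_b <- sum(choose(colSums(ct$tab), 2))
  total <- choose(ct$n, 2)
  (total + 2 * sum_ij - sum_a - sum_b) / total
}

.pair_contingency <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need >= 2 items")
  list(tab = table(a, b), n = length(a))
}
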