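# Diffusion-map pseudotime, the dual ageing/phagocytosis axis decomposition,
# MST lineage pseudotime, the downsampled median-rank bootstrap and the
# deterministic kNN-graph axis score.

#' Diffusion map with local-bandwidth Gaussian kernel
#'
#' Kernel `W_ij = exp(-d_ij^2 / (sigma_i sigma_j))` with local bandwidth
#' `sigma_i` = distance to the `knn`-th neighbour; density normalization
#' `W'_ij = W_ij / (q_i q_j)` with `q_i = sum_j W_ij` (alpha = 1); the
#' row-normalized Markov operator is eigendecomposed through its symmetric
#' conjugate. Components are the nontrivial eigenvectors ordered by
#' eigenvalue; the leading (trivial) eigenvalue is 1.
#'
#' @param x `glx_norm`.
#' @param genes Optional gene set to restrict to.
#' @param n_components Number of nontrivial components to return.
#' @param knn Neighbour index for the local bandwidth (default 15; must be
#'   < number of cells).
#' @return List: `components` (cells x n_components), `eigenvalues`
#'   (nontrivial, descending), `trivial_eigenvalue`.
#' @export
diffusion_map <- function(x, genes = NULL, n_components = 2, knn = 15) {
  stopifnot(inherits(x, "glx_norm"))
  if (!is.null(genes)) x <- subset_norm(x, genes = intersect(genes, x$gene_ids))
  n <- ncol(x$values)
  if (knn >= n) stop("knn must be smaller than the number of cells")
  if (n < n_components + 2) stop("need >= n_components + 2 cells")
  D <- as.matrix(stats::dist(t(x$values)))
  sigma <- apply(D, 1, function(row) sort(row)[knn + 1])   # knn-th neighbour
  if (any(sigma == 0)) {
    # duplicate cells collapse distances; break ties with a tiny seeded jitter
    jseed <- stage_seed(1L, "trajectory")
    message("duplicate cells detected; applying epsilon jitter (seed ", jseed, ")")
    set.seed(jseed)
    D <- D + matrix(stats::runif(n * n, 0, 1e-10), n, n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    sigma <- apply(D, 1, function(row) sort(row)[knn + 1])
  }
  W <- exp(-D^2 / outer(sigma, sigma))
  diag(W) <- 0
  q <- pmax(rowSums(W), 1e-300)
  Wp <- W / outer(q, q)
  d <- pmax(rowSums(Wp), 1e-300)
  S <- Wp / outer(sqrt(d), sqrt(d))
  e <- eigen(S, symmetric = TRUE)
  psi <- e$vectors / sqrt(d)
  # deterministic sign: largest-magnitude entry of each component positive
  psi <- apply(psi, 2, function(v) v * sign(v[which.max(abs(v))]))
  idx <- seq_len(n_components) + 1L
  comps <- psi[, idx, drop = FALSE]
  rownames(comps) <- x$cell_ids
  colnames(comps) <- paste0("DC", seq_len(n_components))
  list(components = comps, eigenvalues = e$values[idx],
       trivial_eigenvalue = e$values[1])
}

#' Pseudotime from a diffusion component, oriented by a reference group
#'
#' Cells are average-ranked by the component value; the sign is flipped when
#' needed so that the reference group has the minimal mean rank.
#'
#' @param comp Named numeric vector of component values (names = cell ids).
#' @param groups Group label per cell (same order as `comp`).
#' @param reference_group Group expected at the start of the axis.
#' @param axis Axis name recorded in the output.
#' @return `data.frame(cell_id, axis, value, rank, group)` of class
#'   `glx_pseudotime`.
#' @export
pseudotime_from_component <- function(comp, groups, reference_group,
                                      axis = "axis") {
  if (max(comp) == min(comp))
    stop("degenerate embedding: all component values equal")
  ref <- groups == reference_group
  if (!any(ref)) stop("reference group not present")
  r <- rank(comp, ties.method = "average")
  if (any(!ref) && mean(r[ref]) > mean(r[!ref])) {
    comp <- -comp
    r <- rank(comp, ties.method = "average")
  }
  out <- data.frame(cell_id = if (is.null(names(comp)))
                      sprintf("cell%05d", seq_along(comp)) else names(comp),
                    axis = axis, value = as.numeric(comp), rank = r,
                    group = groups, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("glx_pseudotime", class(out))
  out
}

#' Axis-specific gene sets by mutual set difference
#'
#' @param phago_genes,ageing_genes Significant gene lists for the two axes.
#' @return `list(phago_specific, ageing_specific)`; the two lists are
#'   disjoint by construction.
#' @export
axis_specific_genes <- function(phago_genes, ageing_genes) {
  list(phago_specific = setdiff(phago_genes, ageing_genes),
       ageing_specific = setdiff(ageing_genes, phago_genes))
}

#' Dual-axis (ageing vs phagocytosis) diffusion pseudotime
#'
#' Thresholds the two DE results at `fdr`, disjoints the gene lists by mutual
#' set difference, and computes one diffusion map + pseudotime per axis on its
#' specific genes, both oriented so the reference group starts the axis.
#'
#' @param x `glx_norm` with a `group` column in `cell_meta`.
#' @param ageing_de,phago_de DE tables (columns `gene`, `fdr`).
#' @param fdr FDR threshold (default 0.05).
#' @param reference_group Orientation reference (e.g. adult wild type).
#' @param knn Local-bandwidth neighbour index for both diffusion maps.
#' @return List of class `glx_dual_axes`: `ageing` and `phagocytosis`
#'   pseudotime tables, the two specific gene lists, and `joint`, a per-cell
#'   table of both ranks.
#' @export
dual_axis_pseudotime <- function(x, ageing_de, phago_de, fdr = 0.05,
                                 reference_group = "WT6m", knn = 15) {
  stopifnot(inherits(x, "glx_norm"))
  sig <- function(de) de$gene[!is.na(de$fdr) & de$fdr < fdr]
  sets <- axis_specific_genes(intersect(sig(phago_de), x$gene_ids),
                              intersect(sig(ageing_de), x$gene_ids))
  if (!length(sets$ageing_specific))
    stop("empty_axis_genes: no ageing-specific genes after disjointing")
  if (!length(sets$phago_specific))
    stop("empty_axis_genes: no phagocytosis-specific genes after disjointing")
  groups <- x$cell_meta$group
  one_axis <- function(genes, axis) {
    dm <- diffusion_map(x, genes = genes, n_components = 1, knn = knn)
    pseudotime_from_component(dm$components[, 1], groups, reference_group,
                              axis = axis)
  }
  ageing <- one_axis(sets$ageing_specific, "ageing")
  phago <- one_axis(sets$phago_specific, "phagocytosis")
  joint <- data.frame(cell_id = ageing$cell_id, group = groups,
                      ageing_rank = ageing$rank, phago_rank = phago$rank,
                      stringsAsFactors = FALSE)
  structure(list(ageing = ageing, phagocytosis = phago,
                 ageing_specific_genes = sets$ageing_specific,
                 phago_specific_genes = sets$phago_specific, joint = joint),
            class = "glx_dual_axes")
}

#' MST lineage pseudotime over group centroids
#'
#' Group centroids in the top `n_pcs` principal components are joined by a
#' Euclidean minimum spanning tree; the tree path from `start_group` to
#' `end_group` is extracted and every cell is orthogonally projected onto the
#' piecewise-linear path. Arc-length position along the path is the
#' pseudotime (0 at the path start), ranked with average ties.
#'
#' @param x `glx_norm`.
#' @param groups Group label per cell.
#' @param n_pcs Number of principal components.
#' @param start_group,end_group Path endpoints (must differ).
#' @return `glx_pseudotime` data.frame with a `path` attribute (ordered group
#'   labels along the lineage).
#' @export
mst_lineage_pseudotime <- function(x, groups, n_pcs = 10, start_group,
                                   end_group) {
  stopifnot(inherits(x, "glx_norm"))
  if (identical(start_group, end_group)) stop("start and end groups must differ")
  groups <- as.character(groups)
  for (g in c(start_group, end_group))
    if (!g %in% groups) stop("group not present: ", g)
  n_pcs <- min(n_pcs, ncol(x$values) - 1, nrow(x$values))
  pc <- stats::prcomp(t(x$values), rank. = n_pcs)$x
  levs <- unique(groups)
  cent <- do.call(rbind, lapply(levs, function(g)
    colMeans(pc[groups == g, , drop = FALSE])))
  rownames(cent) <- levs
  Dm <- as.matrix(stats::dist(cent))
  g_full <- igraph::graph_from_adjacency_matrix(Dm, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::mst(g_full)
  path_v <- igraph::shortest_paths(
    mst, from = match(start_group, levs), to = match(end_group, levs))$vpath[[1]]
  path_groups <- levs[as.integer(path_v)]
  P <- cent[path_groups, , drop = FALSE]
  seg_vec <- diff(P)
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum_len <- c(0, cumsum(seg_len))
  pt <- vapply(seq_len(nrow(pc)), function(i) {
    ci <- pc[i, ]
    best <- Inf; best_pt <- 0
    for (sgm in seq_len(nrow(seg_vec))) {
      u <- seg_vec[sgm, ]
      t_raw <- sum((ci - P[sgm, ]) * u) / sum(u^2)
      t_cl <- min(max(t_raw, 0), 1)
      proj <- P[sgm, ] + t_cl * u
      d2 <- sum((ci - proj)^2)
      if (d2 < best) { best <- d2; best_pt <- cum_len[sgm] + t_cl * seg_len[sgm] }
    }
    best_pt
  }, numeric(1))
  # arc-length convention: positions measured from the path start, so the
  # start group needs no orientation flip
  pt <- pt - min(pt)
  out <- data.frame(cell_id = x$cell_ids,
                    axis = paste0("lineage:", start_group, "->", end_group),
                    value = pt, rank = rank(pt, ties.method = "average"),
                    group = groups, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("glx_pseudotime", class(out))
  attr(out, "path") <- path_groups
  out
}

#' Downsampled median-rank bootstrap of a lineage pseudotime
#'
#' Repeats `B` times: downsample every query group to `n_per_group` cells,
#' co-embed with the reference cells (joint per-gene standardization over the
#' shared genes, then PCA inside the MST lineage), run
#' [mst_lineage_pseudotime()] from `start_group` to `end_group`, and record
#' each group's median rank. The final ordering is the across-iteration median
#' of median ranks.
#'
#' @param x_query `glx_norm` of the query cells (with `group` metadata).
#' @param x_reference `glx_norm` of the reference cells defining the axis
#'   (contains `start_group` and `end_group`).
#' @param B Number of iterations (>= 1).
#' @param n_per_group Downsample size per query group; groups with fewer cells
#'   are taken whole, with a warning.
#' @param start_group,end_group Lineage endpoints (reference groups).
#' @param n_pcs Principal components for the embedding.
#' @param seed Integer seed; iteration b uses `seed + b`.
#' @return List: `median_ranks` (B x groups matrix), `final` (named median of
#'   medians), `ordering` (group labels sorted by `final`).
#' @export
bootstrap_median_rank <- function(x_query, x_reference, B = 1000,
                                  n_per_group = 200, start_group, end_group,
                                  n_pcs = 10, seed = 1L) {
  .assert_scalar_count(B, "B")
  shared <- intersect(x_query$gene_ids, x_reference$gene_ids)
  if (length(shared) < 2) stop("query and reference share too few genes")
  xq <- subset_norm(x_query, genes = shared)
  xr <- subset_norm(x_reference, genes = shared)
  qgroups <- split(xq$cell_ids, xq$cell_meta$group)
  small <- names(qgroups)[lengths(qgroups) < n_per_group]
  if (length(small))
    warning("group(s) smaller than n_per_group taken whole: ",
            paste(small, collapse = ", "))
  all_groups <- unique(c(xr$cell_meta$group, xq$cell_meta$group))
  med <- matrix(NA_real_, B, length(all_groups),
                dimnames = list(NULL, all_groups))
  for (b in seq_len(B)) {
    set.seed(seed + b - 1L)
    take <- unlist(lapply(qgroups, function(ids)
      if (length(ids) <= n_per_group) ids
      else sample(ids, n_per_group)), use.names = FALSE)
    vq <- xq$values[, take, drop = FALSE]
    v <- cbind(xr$values, vq)
    grp <- c(xr$cell_meta$group,
             xq$cell_meta$group[match(take, xq$cell_ids)])
    # joint scaling: per-gene standardization across the combined cells
    mu <- rowMeans(v); sdv <- apply(v, 1, stats::sd)
    keep <- sdv > 0
    vs <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    xj <- glx_norm(vs - min(vs), rep(1, ncol(vs)),
                   data.frame(cell_id = colnames(v), group = grp,
                              stringsAsFactors = FALSE))
    ptb <- mst_lineage_pseudotime(xj, grp, n_pcs = n_pcs,
                                  start_group = start_group,
                                  end_group = end_group)
    med[b, ] <- vapply(all_groups, function(g)
      stats::median(ptb$rank[ptb$group == g]), numeric(1))
  }
  final <- apply(med, 2, stats::median)
  list(median_ranks = med, final = final,
       ordering = names(sort(final)))
}

#' Deterministic kNN-graph axis score
#'
#' Builds a mutual k-nearest-neighbour graph (Euclidean), takes the first
#' nontrivial eigenvector of its normalized graph Laplacian (the Fiedler-style
#' coordinate), min-max scales it to [0, 1], and orients it so the reference
#' group's mean score is low. Disconnected graphs are scored per component,
#' with a warning; singleton components get 0.5.
#'
#' @param panel Numeric matrix, cells x features.
#' @param k Number of neighbours (< number of cells).
#' @param groups Group label per cell.
#' @param reference_group Low-score reference.
#' @return Named numeric vector of per-cell scores in [0, 1].
#' @export
knn_axis_score <- function(panel, k, groups, reference_group) {
  panel <- as.matrix(panel)
  n <- nrow(panel)
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(panel))
  nn <- t(apply(D, 1, function(row) order(row)[2:(k + 1)]))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, nn[i, ]] <- TRUE
  A <- A & t(A)                      # mutual neighbours
  mode(A) <- "numeric"
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    warning("kNN graph is disconnected (", comp$no,
            " components); scoring components separately")
  score <- rep(0.5, n)
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    if (length(idx) < 3) next
    Ai <- A[idx, idx]
    dd <- pmax(rowSums(Ai), 1e-12)
    L <- diag(length(idx)) - t(Ai / sqrt(dd)) / sqrt(dd)
    e <- eigen(L, symmetric = TRUE)
    fied <- e$vectors[, length(idx) - 1L]
    rng <- range(fied)
    s <- if (diff(rng) == 0) rep(0.5, length(idx))
         else (fied - rng[1]) / diff(rng)
    ref <- groups[idx] == reference_group
    if (any(ref) && !all(ref) && mean(s[ref]) > mean(s[!ref])) s <- 1 - s
    score[idx] <- s
  }
  names(score) <- rownames(panel)
  score
}
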