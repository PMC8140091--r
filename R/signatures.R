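# Gene-set module scores, rank-AUC regulon activity, mixture binarization,
# regulon pruning, normalized group activity summaries and patient-level
# cluster statistics for human cohorts.

#' Expression-matched module score per cell
#'
#' Genes are binned by mean expression into `n_bins`; for every gene-set
#' member, `n_ctrl` control genes are drawn from the member's bin (set genes
#' themselves are excluded from the control pools, so the score is exactly
#' linear in the set genes' expression). The score is the mean expression of
#' the set genes minus the mean of the sampled control genes, per cell.
#'
#' @param x `glx_norm`.
#' @param gene_set Character vector of gene ids; at least one must be present.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100; sampled with
#'   replacement when a bin is smaller).
#' @param seed Integer seed for the control draws.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(x, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(x, "glx_norm"))
  present <- intersect(gene_set, x$gene_ids)
  if (!length(present))
    stop("no gene-set genes present in the matrix; missing: ",
         paste(utils::head(gene_set, 20), collapse = ", "))
  v <- x$values
  means <- rowMeans(v)
  brk <- unique(stats::quantile(means, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(brk) < 2) rep(1L, length(means))
         else cut(means, breaks = brk, include.lowest = TRUE, labels = FALSE)
  names(bin) <- x$gene_ids
  pool_by_bin <- split(setdiff(x$gene_ids, present), bin[setdiff(x$gene_ids, present)])
  set.seed(seed)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- pool_by_bin[[as.character(bin[g])]]
    if (is.null(pool) || !length(pool)) return(character(0))
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }), use.names = FALSE)
  if (!length(ctrl)) stop("control pools are empty; decrease n_bins")
  score <- colMeans(v[present, , drop = FALSE]) -
    colMeans(v[ctrl, , drop = FALSE])
  stats::setNames(score, x$cell_ids)
}

#' Rank-based AUC regulon activity per cell
#'
#' Per cell, genes are ranked by expression (descending; ties resolved by
#' average rank, then stable gene order). The recovery curve counts regulon
#' targets within the top `t` ranks for `t = 1..ceiling(top_fraction * G)`;
#' the activity is the area under this curve normalized by its maximum
#' possible value, so it reflects both the fraction of regulon genes expressed
#' in the cell and their expression relative to non-regulon genes.
#'
#' @param x `glx_norm`.
#' @param regulon `glx_regulon` (or character vector of targets).
#' @param top_fraction Fraction of the gene ranking considered (default 0.05).
#' @return Named numeric vector of per-cell AUC values in [0, 1].
#' @export
regulon_auc <- function(x, regulon, top_fraction = 0.05) {
  stopifnot(inherits(x, "glx_norm"))
  targets <- if (inherits(regulon, "glx_regulon")) regulon$targets
             else as.character(regulon)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must lie in (0, 1)")
  present <- intersect(targets, x$gene_ids)
  if (!length(present)) stop("regulon has no genes in the expression matrix")
  G <- nrow(x$values)
  tmax <- ceiling(top_fraction * G)
  is_target <- x$gene_ids %in% present
  K <- length(present)
  max_auc <- sum(pmin(seq_len(tmax), K))
  auc <- apply(x$values, 2, function(expr) {
    # stable integer positions: ties broken by gene order
    pos <- order(order(-expr, seq_along(expr)))
    pt <- pos[is_target]
    pt <- pt[pt <= tmax]
    if (!length(pt)) return(0)
    sum(tmax - pt + 1) / max_auc
  })
  stats::setNames(auc, x$cell_ids)
}

#' Score a list of regulons into an activity matrix
#'
#' @param x `glx_norm`.
#' @param regulons Named list of `glx_regulon`.
#' @param top_fraction Passed to [regulon_auc()].
#' @return `glx_activity` list: `auc` (regulons x cells), `n_targets`
#'   (targets present per regulon), optional `binary`/`thresholds` filled by
#'   [binarize_activity()].
#' @export
regulon_activity <- function(x, regulons, top_fraction = 0.05) {
  auc <- t(vapply(regulons, function(r) regulon_auc(x, r, top_fraction),
                  numeric(ncol(x$values))))
  rownames(auc) <- names(regulons)
  n_targets <- vapply(regulons, function(r) length(r$targets), integer(1))
  structure(list(auc = auc, n_targets = n_targets, binary = NULL,
                 thresholds = NULL),
            class = "glx_activity")
}

#' Binarize regulon activity with a two-component Gaussian mixture
#'
#' Per regulon, a two-component Gaussian mixture is fitted to the AUC scores
#' (EM via mclust); the threshold is the posterior-0.5 crossing between the
#' component means. When the mixture is degenerate -- component means closer
#' than 0.5 pooled standard deviations, or the fit fails -- the 75th
#' percentile is used instead. Cells above the threshold are active (1).
#'
#' @param a `glx_activity` with >= 10 cells per regulon.
#' @return `glx_activity` with `binary` and `thresholds` filled.
#' @export
binarize_activity <- function(a) {
  stopifnot(inherits(a, "glx_activity"))
  if (ncol(a$auc) < 10) stop("need >= 10 cells per regulon to binarize")
  thr <- apply(a$auc, 1, .mixture_threshold)
  a$thresholds <- thr
  a$binary <- (a$auc > thr) * 1L
  a
}

.mixture_threshold <- function(scores) {
  if (max(scores) == min(scores)) {
    warning("constant AUC vector; all cells set inactive")
    return(Inf)
  }
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller frame
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(scores, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  fallback <- stats::quantile(scores, 0.75)
  if (is.null(fit) || is.null(fit$parameters)) return(unname(fallback))
  mu <- fit$parameters$mean
  va <- fit$parameters$variance$sigmasq
  if (length(va) == 1) va <- rep(va, 2)
  va <- pmax(va, 1e-12)
  pro <- fit$parameters$pro
  pooled_sd <- sqrt(sum(pro * va))
  if (abs(diff(mu)) < 0.5 * pooled_sd) return(unname(fallback))
  # posterior-0.5 crossing: equate the two weighted log densities (quadratic)
  o <- order(mu)
  lo <- mu[o[1]]; hi <- mu[o[2]]
  v1 <- va[o[1]]; v2 <- va[o[2]]; p1 <- pro[o[1]]; p2 <- pro[o[2]]
  a <- 0.5 * (1 / v1 - 1 / v2)
  b <- hi / v2 - lo / v1
  cc <- 0.5 * (lo^2 / v1 - hi^2 / v2) + log(p2 / p1) + 0.5 * log(v1 / v2)
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots > lo & roots < hi]
  unname(if (length(roots)) roots[1] else (lo + hi) / 2)
}

#' Prune a regulon to feature genes and group-discriminating targets
#'
#' Two-stage filter: (1) intersect the regulon targets with the feature gene
#' set; (2) keep only targets that are differentially expressed across the
#' a-priori groups by the Kruskal-Wallis test (BH-adjusted p < `alpha`).
#'
#' @param r `glx_regulon`.
#' @param feature_genes Character vector (e.g. from
#'   [select_features_danb()]).
#' @param x `glx_norm`.
#' @param groups Group label per cell.
#' @param alpha FDR threshold (default 0.05).
#' @return Pruned `glx_regulon` (possibly with zero targets, with a warning);
#'   the sizes after each stage are stored in the `history` attribute.
#' @export
prune_regulon <- function(r, feature_genes, x, groups, alpha = 0.05) {
  stopifnot(inherits(r, "glx_regulon"), inherits(x, "glx_norm"))
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  stage1 <- intersect(r$targets, feature_genes)
  if (!length(stage1)) {
    warning("regulon shares no genes with the feature set; returning empty")
    out <- structure(list(tf = r$tf, targets = character(0),
                          provenance = r$provenance), class = "glx_regulon")
    attr(out, "history") <- c(input = length(r$targets), feature_overlap = 0L,
                              de = 0L)
    return(out)
  }
  present <- intersect(stage1, x$gene_ids)
  de <- kruskal_wallis_de(subset_norm(x, genes = present), groups,
                          alpha = alpha)
  stage2 <- de$gene[de$significant]
  if (!length(stage2))
    warning("no regulon targets are group-discriminating; returning empty")
  out <- structure(list(tf = r$tf, targets = stage2,
                        provenance = r$provenance), class = "glx_regulon")
  attr(out, "history") <- c(input = length(r$targets),
                            feature_overlap = length(stage1),
                            de = length(stage2))
  out
}

#' Group-mean normalized regulon activity with size/activity filters
#'
#' Regulons with fewer than `min_targets` target genes are dropped, as are
#' regulons whose binarized activity covers no more than `min_active_fraction`
#' of the cells (strict >). Remaining AUC rows are divided by their maximum
#' across cells, and the mean normalized activity per group is reported.
#'
#' @param a `glx_activity` (binarized; run [binarize_activity()] first).
#' @param groups Group label per cell.
#' @param min_targets Minimum regulon size (default 100).
#' @param min_active_fraction Minimum fraction of active cells (default 0.10).
#' @return List: `group_means` (retained regulons x groups), `retained`
#'   (regulon names), `active_fraction` (all regulons). Empty result warns.
#' @export
summarize_regulon_activity <- function(a, groups, min_targets = 100,
                                       min_active_fraction = 0.10) {
  stopifnot(inherits(a, "glx_activity"))
  if (is.null(a$binary))
    stop("binarized activity required; call binarize_activity() first")
  act_frac <- rowMeans(a$binary)
  keep <- a$n_targets >= min_targets & act_frac > min_active_fraction
  if (!any(keep)) {
    warning("all regulons filtered out")
    return(list(group_means = matrix(numeric(0), 0, length(unique(groups))),
                retained = character(0), active_fraction = act_frac))
  }
  auc <- a$auc[keep, , drop = FALSE]
  norm <- auc / apply(auc, 1, max)
  glev <- unique(groups)
  gm <- vapply(glev, function(g)
    rowMeans(norm[, groups == g, drop = FALSE]), numeric(nrow(norm)))
  gm <- matrix(gm, nrow = nrow(norm),
               dimnames = list(rownames(auc), glev))
  list(group_means = gm, retained = rownames(auc),
       active_fraction = act_frac)
}

#' Patient-level cluster proportions and percentages
#'
#' Per (cluster, disease status): the proportion is the number of patients of
#' that status with at least one cell in the cluster divided by the number of
#' patients of that status; the percentage is the median, over patients with
#' at least one cell in the cluster, of 100 * (patient's cells in the cluster
#' / patient's total cells). Patients without cells in a cluster count in the
#' proportion denominator but are excluded from the percentage median.
#'
#' @param cells `data.frame` with columns `patient`, `status`, `cluster`.
#' @return `data.frame(cluster, status, n_patients, n_patients_in_cluster,
#'   proportion, percentage)`.
#' @export
patient_cluster_stats <- function(cells) {
  stopifnot(all(c("patient", "status", "cluster") %in% names(cells)))
  if (anyNA(cells[, c("patient", "status", "cluster")]))
    stop("patient, status and cluster must be complete")
  pat_status <- unique(cells[, c("patient", "status")])
  status_n <- table(pat_status$status)
  pat_total <- table(cells$patient)
  out <- list()
  for (cl in sort(unique(cells$cluster))) {
    in_cl <- cells[cells$cluster == cl, ]
    pat_in <- table(in_cl$patient)
    for (st in names(status_n)) {
      pats <- pat_status$patient[pat_status$status == st]
      contrib <- intersect(pats, names(pat_in))
      prop <- if (status_n[[st]] > 0)
        length(contrib) / status_n[[st]] else NA_real_
      pct <- if (length(contrib))
        stats::median(100 * as.numeric(pat_in[contrib]) /
                        as.numeric(pat_total[contrib])) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, status = st, n_patients = status_n[[st]],
        n_patients_in_cluster = length(contrib),
        proportion = prop, percentage = pct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
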