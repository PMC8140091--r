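#' Quality-control rules for cell and gene filtering
#'
#' Encodes the filtering recipe applied to droplet microglia data: cells at or
#' below the 5th percentile of total counts or detected features are dropped,
#' then cells with a mitochondrial fraction above 10%, then (optionally) cells
#' failing a microglia marker gate, and finally genes without >= `gene_min_count`
#' counts in >= `gene_min_cells` cells. Filters are applied cells-then-genes,
#' in that order, and the QC report records each step.
#'
#' @param percentile Lower-tail percentile for the total-count and
#'   detected-feature cell filters (cells <= this quantile are dropped; 0
#'   disables the step).
#' @param max_mito_frac Maximum tolerated mitochondrial count fraction.
#' @param mito_genes Gene ids counted as mitochondrial; default: ids matching
#'   `^mt-` (case-insensitive).
#' @param marker_genes,marker_min Microglia identity gate: keep cells whose
#'   marker evidence reaches `marker_min` counts. `NULL` disables the gate.
#' @param exclusion_genes,exclusion_max Companion exclusion gate: cells with
#'   `>= exclusion_max` counts of these genes are dropped.
#' @param marker_mode `"pooled"` sums counts across the marker (exclusion)
#'   set; `"per_gene"` requires a single gene to reach the threshold.
#' @param gene_min_count,gene_min_cells Gene retention rule. Under
#'   `gene_rule = "per_cell"` a gene needs a count >= `gene_min_count` in at
#'   least `gene_min_cells` distinct cells (strictest reading); under
#'   `"detected"` it needs to be detected (count > `gene_min_count - 1` total)
#'   in >= `gene_min_cells` cells.
#' @param gene_rule See above.
#' @param blacklist Gene ids removed unconditionally (e.g. sex-linked or
#'   cell-cycle genes).
#' @return A list of class `glx_qc_rules`.
#' @export
qc_rules <- function(percentile = 0.05, max_mito_frac = 0.10,
                     mito_genes = NULL,
                     marker_genes = NULL, marker_min = 10,
                     exclusion_genes = NULL, exclusion_max = 6,
                     marker_mode = c("pooled", "per_gene"),
                     gene_min_count = 2, gene_min_cells = 2,
                     gene_rule = c("per_cell", "detected"),
                     blacklist = NULL) {
  structure(list(percentile = percentile, max_mito_frac = max_mito_frac,
                 mito_genes = mito_genes, marker_genes = marker_genes,
                 marker_min = marker_min, exclusion_genes = exclusion_genes,
                 exclusion_max = exclusion_max,
                 marker_mode = match.arg(marker_mode),
                 gene_min_count = gene_min_count,
                 gene_min_cells = gene_min_cells,
                 gene_rule = match.arg(gene_rule),
                 blacklist = blacklist),
            class = "glx_qc_rules")
}

#' Filter cells and genes by quality rules
#'
#' @param x `glx_counts`.
#' @param rules `glx_qc_rules`.
#' @return `glx_counts` with a `qc_report` attribute: a `data.frame` of the
#'   steps in application order (percentile, mito, markers, genes) and how
#'   many cells/genes each removed.
#' @export
filter_cells_and_genes <- function(x, rules = qc_rules()) {
  stopifnot(inherits(x, "glx_counts"))
  m <- x$counts
  report <- list()
  note <- function(step, what, removed)
    report[[length(report) + 1L]] <<- data.frame(step = step, axis = what,
                                                 removed = removed)

  # genes with no counts anywhere carry no information for the cell filters
  nonzero <- Matrix::rowSums(m) > 0
  note("empty_genes", "gene", sum(!nonzero))
  m <- m[nonzero, , drop = FALSE]

  if (rules$percentile > 0) {
    totals <- Matrix::colSums(m)
    feats <- Matrix::colSums(m > 0)
    thr_tot <- stats::quantile(totals, rules$percentile)
    thr_feat <- stats::quantile(feats, rules$percentile)
    keep <- totals > thr_tot & feats > thr_feat
    note("percentile", "cell", sum(!keep))
    m <- m[, keep, drop = FALSE]
  } else note("percentile", "cell", 0L)

  mito <- rules$mito_genes
  if (is.null(mito)) mito <- grep("^mt-", rownames(m), ignore.case = TRUE,
                                  value = TRUE)
  mito <- intersect(mito, rownames(m))
  if (length(mito)) {
    frac <- Matrix::colSums(m[mito, , drop = FALSE]) / Matrix::colSums(m)
    keep <- frac <= rules$max_mito_frac
  } else keep <- rep(TRUE, ncol(m))
  note("mito", "cell", sum(!keep))
  m <- m[, keep, drop = FALSE]

  if (!is.null(rules$marker_genes)) {
    mk <- rules$marker_genes
    unknown <- setdiff(mk, rownames(m))
    if (length(unknown)) {
      warning("unknown marker genes skipped: ", paste(unknown, collapse = ", "))
      mk <- setdiff(mk, unknown)
    }
    ok_in <- if (length(mk)) {
      sub <- m[mk, , drop = FALSE]
      if (rules$marker_mode == "pooled")
        Matrix::colSums(sub) >= rules$marker_min
      else apply(as.matrix(sub), 2, max) >= rules$marker_min
    } else rep(TRUE, ncol(m))
    ex <- intersect(rules$exclusion_genes, rownames(m))
    ok_ex <- if (length(ex)) {
      sub <- m[ex, , drop = FALSE]
      if (rules$marker_mode == "pooled")
        Matrix::colSums(sub) < rules$exclusion_max
      else apply(as.matrix(sub), 2, max) < rules$exclusion_max
    } else rep(TRUE, ncol(m))
    keep <- ok_in & ok_ex
    note("markers", "cell", sum(!keep))
    m <- m[, keep, drop = FALSE]
  } else note("markers", "cell", 0L)

  if (!is.null(rules$blacklist)) {
    keep_g <- !(rownames(m) %in% rules$blacklist)
    note("blacklist", "gene", sum(!keep_g))
    m <- m[keep_g, , drop = FALSE]
  }

  keep_g <- if (rules$gene_rule == "per_cell")
    Matrix::rowSums(m >= rules$gene_min_count) >= rules$gene_min_cells
  else
    Matrix::rowSums(m > (rules$gene_min_count - 1)) >= rules$gene_min_cells
  note("genes", "gene", sum(!keep_g))
  m <- m[keep_g, , drop = FALSE]

  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("empty_after_filter: no cells or genes survive the QC rules")
  out <- glx_counts(m, rownames(m), colnames(m),
                    x$cell_meta[match(colnames(m), x$cell_meta$cell_id), ,
                                drop = FALSE])
  attr(out, "qc_report") <- do.call(rbind, report)
  out
}

#' Normalize counts to log2(CPM + 1)
#'
#' `value_gj = log2(1e6 * c_gj / (s_j * T) + 1)` where `T` is the mean total
#' count and `s_j` the per-cell size factor rescaled to mean 1. With
#' `method = "library_size"`, `s_j * T` is exactly the cell's total count;
#' `"median_ratio"` uses median-of-ratios factors against the per-gene
#' geometric-mean reference (computed over genes with no zero counts).
#'
#' @param x `glx_counts`.
#' @param method `"library_size"` or `"median_ratio"`.
#' @return `glx_norm`.
#' @export
normalize_log_cpm <- function(x, method = c("library_size", "median_ratio")) {
  stopifnot(inherits(x, "glx_counts"))
  method <- match.arg(method)
  m <- x$counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("zero_total_cell: cell(s) with zero total count: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  if (method == "library_size") {
    s <- totals / mean(totals)
  } else {
    dm <- as.matrix(m)
    full <- rowSums(dm == 0) == 0
    if (!any(full))
      stop("median_ratio needs at least one gene with no zero counts; ",
           "use method = 'library_size'")
    logref <- rowMeans(log(dm[full, , drop = FALSE]))
    s <- apply(dm[full, , drop = FALSE], 2,
               function(col) exp(stats::median(log(col) - logref)))
    s <- s / mean(s)
  }
  eff <- s * mean(totals)
  vals <- log2(Matrix::t(Matrix::t(m) * (1e6 / eff)) + 1)
  glx_norm(as.matrix(vals), s, x$cell_meta)
}

#' Depth-adjusted negative-binomial (dropout-excess) feature selection
#'
#' For every gene, the expected number of zero counts under a depth-adjusted
#' NB model (per-cell mean proportional to the cell's total count; gene
#' dispersion by moments) is compared with the observed number; genes are
#' ranked by the right-tailed z-score of the dropout excess and the top
#' `floor(top_fraction * G)` are returned.
#'
#' @param x `glx_counts` (already QC-filtered).
#' @param top_fraction Fraction of genes to keep, in (0, 1].
#' @return Character vector of gene ids ordered by decreasing dropout-excess
#'   score, with the scores as a `scores` attribute (full ranking).
#' @export
select_features_danb <- function(x, top_fraction = 0.25) {
  stopifnot(inherits(x, "glx_counts"))
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  m <- as.matrix(x$counts)
  G <- nrow(m)
  tj <- colSums(m)
  Tt <- sum(tj)
  gsum <- rowSums(m)
  mu <- outer(gsum, tj) / Tt                      # depth-adjusted means
  # moment dispersion: Var = mu + phi mu^2 summed over cells
  num <- rowSums((m - mu)^2) - rowSums(mu)
  den <- rowSums(mu^2)
  phi <- pmax(num / pmax(den, 1e-12), 0)
  p0 <- matrix(0, G, ncol(m))
  pois <- phi < 1e-10
  if (any(pois)) p0[pois, ] <- exp(-mu[pois, , drop = FALSE])
  if (any(!pois))
    p0[!pois, ] <- (1 + phi[!pois] * mu[!pois, , drop = FALSE])^(-1 / phi[!pois])
  exp_drop <- rowSums(p0)
  var_drop <- rowSums(p0 * (1 - p0))
  obs_drop <- rowSums(m == 0)
  z <- (obs_drop - exp_drop) / sqrt(pmax(var_drop, 1e-12))
  ord <- order(z, decreasing = TRUE)
  n_keep <- floor(top_fraction * G)
  out <- x$gene_ids[ord][seq_len(n_keep)]
  attr(out, "scores") <- stats::setNames(z, x$gene_ids)
  out
}
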