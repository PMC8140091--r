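#' Project single cells onto bulk reference transcriptomes
#'
#' Computes the Pearson correlation between every cell's log2(CPM) vector and
#' every bulk sample's, over the shared genes, then z-scores each cell's
#' correlations across the bulk samples. Bulk samples are ordered by
#' average-linkage hierarchical clustering on 1 - Pearson between bulk
#' profiles. Input units are consumed exactly as produced by
#' [normalize_log_cpm()]; no further transformation is applied.
#'
#' @param sc `glx_norm` of single cells.
#' @param bulk `glx_norm` of bulk samples (>= 2 samples; >= 3 shared genes).
#' @return List of class `glx_projection`: `z` (cells x samples z-scores,
#'   rows mean 0 / sd 1 where defined), `r` (raw correlations),
#'   `shared_genes`, `sample_order` (dendrogram order of the bulk samples).
#'   Constant cell or sample vectors yield NA rows/columns, with a warning.
#' @export
project_cells_to_bulk <- function(sc, bulk) {
  stopifnot(inherits(sc, "glx_norm"), inherits(bulk, "glx_norm"))
  shared <- intersect(sc$gene_ids, bulk$gene_ids)
  if (length(shared) < 3) stop("need >= 3 shared genes")
  if (ncol(bulk$values) < 2) stop("need >= 2 bulk samples")
  vs <- sc$values[shared, , drop = FALSE]
  vb <- bulk$values[shared, , drop = FALSE]
  sd_c <- apply(vs, 2, stats::sd)
  sd_s <- apply(vb, 2, stats::sd)
  if (any(sd_c == 0))
    warning("constant cell profile(s) flagged NA: ",
            paste(colnames(vs)[sd_c == 0], collapse = ", "))
  if (any(sd_s == 0))
    warning("constant bulk profile(s) flagged NA: ",
            paste(colnames(vb)[sd_s == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(vs, vb))      # cells x samples
  r[sd_c == 0, ] <- NA_real_
  r[, sd_s == 0] <- NA_real_
  z <- t(apply(r, 1, function(row) {
    if (anyNA(row) || stats::sd(row) == 0) return(rep(NA_real_, length(row)))
    (row - mean(row)) / stats::sd(row)
  }))
  dimnames(z) <- dimnames(r)
  ok <- sd_s > 0
  ord <- colnames(vb)
  if (sum(ok) >= 2) {
    cb <- stats::cor(vb[, ok, drop = FALSE])
    hc <- stats::hclust(stats::as.dist(1 - cb), method = "average")
    ord <- c(colnames(vb)[ok][hc$order], colnames(vb)[!ok])
  }
  structure(list(z = z, r = r, shared_genes = shared, sample_order = ord),
            class = "glx_projection")
}
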