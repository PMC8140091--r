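#' Gene-by-cell count container
#'
#' Lightweight container for an integer count matrix (genes in rows, cells or
#' bulk samples in columns) plus per-cell metadata. Counts are stored sparse.
#'
#' @param counts Non-negative integer matrix or `Matrix::sparseMatrix`,
#'   genes x cells.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell/sample identifiers
#'   (columns).
#' @param cell_meta `data.frame` keyed by `cell_id`; one row per cell. A
#'   `cell_id` column is added if absent (from `cell_ids`).
#' @return An object of class `glx_counts` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
glx_counts <- function(counts, gene_ids = rownames(counts),
                       cell_ids = colnames(counts), cell_meta = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("id lengths inconsistent with matrix dimensions")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, stringsAsFactors = FALSE)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (is.null(cell_meta$cell_id)) cell_meta$cell_id <- cell_ids
    if (!setequal(cell_meta$cell_id, cell_ids))
      stop("cell_meta cell_id does not match cell_ids")
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
    rownames(cell_meta) <- NULL
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "glx_counts")
}

#' @method print glx_counts
#' @export
print.glx_counts <- function(x, ...) {
  cat(sprintf("<glx_counts> %d genes x %d cells; metadata: %s\n",
              length(x$gene_ids), length(x$cell_ids),
              paste(setdiff(names(x$cell_meta), "cell_id"), collapse = ", ")))
  invisible(x)
}

#' @export
dim.glx_counts <- function(x) dim(x$counts)

#' Subset a count container by gene and/or cell identifiers
#'
#' @param x `glx_counts`.
#' @param genes,cells Character vectors of ids to keep (NULL keeps all).
#' @return `glx_counts` restricted to the requested ids, in the given order.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "glx_counts"))
  if (is.null(genes)) genes <- x$gene_ids
  if (is.null(cells)) cells <- x$cell_ids
  missing_g <- setdiff(genes, x$gene_ids)
  if (length(missing_g)) stop("unknown genes: ", paste(missing_g, collapse = ", "))
  missing_c <- setdiff(cells, x$cell_ids)
  if (length(missing_c)) stop("unknown cells: ", paste(missing_c, collapse = ", "))
  glx_counts(x$counts[genes, cells, drop = FALSE], genes, cells,
             x$cell_meta[match(cells, x$cell_meta$cell_id), , drop = FALSE])
}

#' Normalized expression container (log2 CPM)
#'
#' @param values Dense numeric matrix of log2(CPM + 1) values, genes x cells.
#' @param size_factors Positive per-cell size factors, mean-centred to 1.
#' @param cell_meta Per-cell metadata `data.frame` with a `cell_id` column.
#' @return An object of class `glx_norm`.
#' @export
glx_norm <- function(values, size_factors, cell_meta = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("normalized values must be >= 0")
  if (length(size_factors) != ncol(values)) stop("one size factor per cell")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell_id = colnames(values), stringsAsFactors = FALSE)
  structure(list(values = values, size_factors = size_factors,
                 gene_ids = rownames(values), cell_ids = colnames(values),
                 cell_meta = cell_meta),
            class = "glx_norm")
}

#' @method print glx_norm
#' @export
print.glx_norm <- function(x, ...) {
  cat(sprintf("<glx_norm> log2(CPM+1), %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.glx_norm <- function(x) dim(x$values)

#' Restrict a normalized matrix to a gene set and/or cell set
#' @param x `glx_norm`.
#' @param genes,cells ids to keep (NULL keeps all).
#' @return `glx_norm`.
#' @export
subset_norm <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "glx_norm"))
  if (is.null(genes)) genes <- x$gene_ids
  if (is.null(cells)) cells <- x$cell_ids
  missing_g <- setdiff(genes, x$gene_ids)
  if (length(missing_g)) stop("unknown genes: ", paste(missing_g, collapse = ", "))
  glx_norm(x$values[genes, cells, drop = FALSE],
           x$size_factors[match(cells, x$cell_ids)],
           x$cell_meta[match(cells, x$cell_meta$cell_id), , drop = FALSE])
}

#' Transcription-factor regulon (TF plus target gene set)
#'
#' @param tf Gene id of the transcription factor.
#' @param targets Character vector of target gene ids (non-empty).
#' @param provenance Free-text tag recording where the regulon came from.
#' @return An object of class `glx_regulon`.
#' @export
glx_regulon <- function(tf, targets, provenance = NA_character_) {
  stopifnot(is.character(tf), length(tf) == 1L)
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("regulon targets must be non-empty")
  structure(list(tf = tf, targets = targets, provenance = provenance),
            class = "glx_regulon")
}

#' @method print glx_regulon
#' @export
print.glx_regulon <- function(x, ...) {
  cat(sprintf("<glx_regulon> %s: %d targets\n", x$tf, length(x$targets)))
  invisible(x)
}
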