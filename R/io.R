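# Readers/writers for the standard on-disk formats used by the pipeline:
# Matrix Market count bundles (matrix.mtx + genes.tsv + barcodes.tsv +
# metadata.csv), GMT gene-set files, and plain CSV tables.

#' Write a count container as a Matrix Market bundle
#'
#' Writes `matrix.mtx` (coordinate integer), `genes.tsv`, `barcodes.tsv` and
#' `metadata.csv` into `dir`.
#'
#' @param x `glx_counts`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "glx_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.csv(x$cell_meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a Matrix Market count bundle written by [write_counts_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `metadata.csv`.
#' @return `glx_counts`.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "metadata.csv")
  meta <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  glx_counts(m, genes, cells, meta)
}

#' Read regulons / gene sets from a GMT file
#'
#' Each GMT line is `set-name<TAB>description<TAB>member1<TAB>member2...`; the
#' set name is taken as the transcription factor.
#'
#' @param path GMT file path.
#' @return Named list of `glx_regulon`.
#' @export
read_gmt <- function(path) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    stats::setNames(lapply(lines, function(f) f[-(1:2)]),
                    vapply(lines, `[`, "", 1L))
  }
  out <- lapply(names(sets), function(nm)
    glx_regulon(nm, sets[[nm]], provenance = path))
  stats::setNames(out, names(sets))
}

#' Write regulons / gene sets to a GMT file
#'
#' @param regulons Named list of `glx_regulon` (or plain character vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(regulons, path) {
  lines <- vapply(names(regulons), function(nm) {
    r <- regulons[[nm]]
    targets <- if (inherits(r, "glx_regulon")) r$targets else as.character(r)
    paste(c(nm, "gliaxes", targets), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a differential-expression result table as CSV
#'
#' Columns: `gene`, `lfc`, `p`, `fdr`, `contrast`.
#' @param de `data.frame` as returned by the DE engines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_csv <- function(de, path) {
  utils::write.csv(de[, c("gene", "lfc", "p", "fdr", "contrast")], path,
                   row.names = FALSE)
  invisible(path)
}
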