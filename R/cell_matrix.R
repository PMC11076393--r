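#' Annotated cell-by-gene expression matrix
#'
#' The substrate for all activity, correlation and safety features: a sparse
#' non-negative cells x genes matrix together with per-cell annotations
#' (cell type, tissue of origin, patient). Tissue must be `"tumor"` or
#' `"normal"`; cells with a missing tissue label are kept for activity
#' features but excluded from the tumor-versus-normal safety computation.
#'
#' @param counts A cells x genes matrix (dense or sparse) of non-negative
#'   expression values, with unique column names (gene symbols) and row names
#'   (cell ids).
#' @param meta A data.frame with columns `cell_id`, `cell_type`, `tissue`,
#'   `patient`; one row per cell of `counts`.
#' @return An object of class `cell_matrix` with elements `counts`
#'   (dgCMatrix), `meta` (data.frame, rows aligned to the matrix) and
#'   `genes`/`cells` index vectors.
#' @export
cell_matrix <- function(counts, meta) {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) {
    stop("expression matrix contains negative entries", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry cell ids as rownames and gene symbols as colnames",
         call. = FALSE)
  }
  genes <- trimws(colnames(counts))
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  colnames(counts) <- genes
  required <- c("cell_id", "cell_type", "tissue", "patient")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("cell metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta$cell_id <- as.character(meta$cell_id)
  bad_tissue <- !is.na(meta$tissue) & !(meta$tissue %in% c("tumor", "normal"))
  if (any(bad_tissue)) {
    stop("invalid tissue value '", meta$tissue[which(bad_tissue)[1L]],
         "' in metadata row ", which(bad_tissue)[1L],
         " (must be 'tumor' or 'normal')", call. = FALSE)
  }
  keep <- rownames(counts) %in% meta$cell_id
  if (!all(keep)) {
    message("dropping ", sum(!keep), " cell(s) absent from metadata")
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no annotated cells remain", call. = FALSE)
  meta <- meta[match(rownames(counts), meta$cell_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta,
                 genes = colnames(counts), cells = rownames(counts)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      length(unique(x$meta$cell_type)), "cell types;",
      sum(x$meta$tissue == "tumor", na.rm = TRUE), "tumor /",
      sum(x$meta$tissue == "normal", na.rm = TRUE), "normal cells\n")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Normalized expression values
#'
#' Library-size normalizes each cell to 10,000 counts and applies log1p
#' (`"cpm_log1p"`), or returns raw values (`"counts"`). All features are
#' computed on this scale.
#'
#' @param x A [cell_matrix()].
#' @param normalization Scale, see [run_config()].
#' @return A sparse cells x genes matrix.
#' @export
normalize_expression <- function(x, normalization = c("cpm_log1p", "counts")) {
  normalization <- match.arg(normalization)
  m <- x$counts
  if (normalization == "counts") return(m)
  lib <- Matrix::rowSums(m)
  scale <- ifelse(lib > 0, 1e4 / lib, 0)
  out <- Matrix::Diagonal(x = scale) %*% m
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  methods::as(out, "CsparseMatrix")
}

#' Read an annotated expression matrix from MatrixMarket + index files
#'
#' Expects the package's own on-disk dialect: a MatrixMarket triplet file with
#' rows = cells and columns = genes, a one-symbol-per-line gene index, a
#' one-id-per-line cell (barcode) index, and a tab-separated metadata table
#' with columns `cell_id`, `cell_type`, `tissue`, `patient`. Cells missing
#' from the metadata are dropped with a message.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param genes_path,cells_path Paths to the gene and cell index files.
#' @param meta_path Path to the metadata TSV.
#' @return A [cell_matrix()].
#' @export
read_expression <- function(matrix_path, genes_path, cells_path, meta_path) {
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    stop("malformed MatrixMarket file '", matrix_path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  genes <- read_gene_list(genes_path)
  cells <- readLines(cells_path)
  cells <- trimws(cells[nzchar(trimws(cells))])
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop("matrix is ", nrow(m), "x", ncol(m), " but index files list ",
         length(cells), " cells and ", length(genes), " genes", call. = FALSE)
  }
  dimnames(m) <- list(cells, genes)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  cell_matrix(m, meta)
}

#' Write an annotated expression matrix
#'
#' Inverse of [read_expression()]; writes the four files into `dir`.
#'
#' @param x A [cell_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named list).
#' @export
write_expression <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    cells = file.path(dir, "barcodes.tsv"),
    meta = file.path(dir, "cell_meta.tsv")
  )
  Matrix::writeMM(x$counts, paths$matrix)
  writeLines(x$genes, paths$genes)
  writeLines(x$cells, paths$cells)
  utils::write.table(x$meta, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
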