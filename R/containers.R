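#' Count matrix with sample metadata
#'
#' Light-weight container for feature-by-sample count data, in the style of
#' edgeR's `DGEList`: an integer matrix plus a per-sample annotation frame.
#' The same container carries RNA-seq gene counts and H3K27ac peak counts.
#'
#' @param counts Integer matrix, features in rows, samples in columns. Must
#'   carry unique row and column names.
#' @param meta `data.frame` with one row per sample (matched to columns of
#'   `counts` by the `sample` column) holding at least `sample`, `region`,
#'   `condition` (one of `"sham"`, `"treated"`) and `replicate`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta`.
#' @export
count_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample", "region", "condition", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(meta$condition %in% c("sham", "treated")))
    stop("condition must be 'sham' or 'treated'")
  if (!setequal(meta$sample, colnames(counts)) ||
      anyDuplicated(meta$sample))
    stop("metadata samples must match count matrix columns one-to-one")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  regions: %s\n",
              paste(unique(x$meta$region), collapse = ", ")))
  cat(sprintf("  conditions: %s\n",
              paste(sort(unique(x$meta$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x A [count_matrix()].
#' @param features,samples Character, integer or logical index into rows /
#'   columns; `NULL` keeps everything.
#' @return A `count_matrix` restricted to the selection.
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  if (!is.null(features)) cts <- cts[features, , drop = FALSE]
  if (!is.null(samples)) cts <- cts[, samples, drop = FALSE]
  meta <- x$meta[match(colnames(cts), x$meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = cts, meta = meta), class = "count_matrix")
}

#' Combine two count matrices column-wise
#'
#' Binds the samples of two matrices over the same feature universe, e.g.
#' the sham and treated halves of a simulated design.
#'
#' @param a,b [count_matrix()] objects with identical features.
#' @return A `count_matrix` with the samples of both inputs.
#' @export
combine_counts <- function(a, b) {
  stopifnot(inherits(a, "count_matrix"), inherits(b, "count_matrix"))
  if (!identical(rownames(a$counts), rownames(b$counts)))
    stop("feature universes differ")
  count_matrix(cbind(a$counts, b$counts), rbind(a$meta, b$meta))
}

#' Cell-level count matrix with per-cell metadata
#'
#' Container for single-cell data: genes in rows, cells in columns (sparse
#' `dgCMatrix` or dense), plus a per-cell annotation frame. Normalized
#' expression, when computed, is stored as the `logcounts` element.
#'
#' @param counts Gene-by-cell count matrix (coerced to sparse).
#' @param meta `data.frame` with columns `cell`, `replicate`, `condition`,
#'   `region`; rows matched to columns of `counts`.
#' @param logcounts Optional gene-by-cell matrix of log-normalized values.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, meta, logcounts = NULL) {
  counts <- if (inherits(counts, "sparseMatrix"))
    methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  else Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene (row) and cell (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("cell", "replicate", "condition", "region")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("cell metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(meta$cell, colnames(counts)) || anyDuplicated(meta$cell))
    stop("metadata cells must match count matrix columns one-to-one")
  meta <- meta[match(colnames(counts), meta$cell), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, logcounts = logcounts),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%s normalized layer)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$logcounts)) "no" else "with"))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)
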