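# TSV/MTX/BED/GMT readers and writers. All numeric TSV output goes through
# fmt_num() so that repeated runs are byte-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v) && v == round(v) && abs(v) < 1e15) {
      format(v, scientific = FALSE, trim = TRUE)
    } else if (is.numeric(v)) {
      formatC(v, digits = 6, format = "g")
    } else {
      as.character(v)
    }
  }, character(1))
  out
}

#' Write a data frame as TSV with stable numeric formatting
#'
#' Numeric columns are rendered with 6 significant digits so identical runs
#' produce byte-identical files.
#'
#' @param df A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !all(out[[j]] == round(out[[j]]), na.rm = TRUE))
      out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Write a count matrix (and its metadata) to TSV
#'
#' Counts go to `<stem>.counts.tsv` (first column `featureId`, then one
#' column per sample) and metadata to `<stem>.samples.tsv`.
#'
#' @param x A [count_matrix()].
#' @param stem Path stem without extension.
#' @return The two paths, invisibly.
#' @export
write_counts_tsv <- function(x, stem) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- data.frame(featureId = rownames(x$counts),
                    x$counts, check.names = FALSE)
  p1 <- paste0(stem, ".counts.tsv")
  p2 <- paste0(stem, ".samples.tsv")
  utils::write.table(cts, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  write_tsv(x$meta, p2)
  invisible(c(p1, p2))
}

#' Read a count matrix written by [write_counts_tsv()]
#' @param stem Path stem without extension.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(stem) {
  cts <- read_tsv(paste0(stem, ".counts.tsv"))
  meta <- read_tsv(paste0(stem, ".samples.tsv"))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$featureId
  count_matrix(m, meta)
}

#' Write single-cell counts as MatrixMarket triplet plus sidecar TSVs
#'
#' Emits `<stem>.mtx` (genes x cells), `<stem>.features.tsv`,
#' `<stem>.barcodes.tsv` and `<stem>.cells.tsv` (metadata).
#'
#' @param x A [cell_matrix()].
#' @param stem Path stem.
#' @export
write_cells_mtx <- function(x, stem) {
  stopifnot(inherits(x, "cell_matrix"))
  Matrix::writeMM(x$counts, paste0(stem, ".mtx"))
  writeLines(rownames(x$counts), paste0(stem, ".features.tsv"))
  writeLines(colnames(x$counts), paste0(stem, ".barcodes.tsv"))
  write_tsv(x$meta, paste0(stem, ".cells.tsv"))
  invisible(stem)
}

#' Read single-cell counts written by [write_cells_mtx()]
#' @param stem Path stem.
#' @return A [cell_matrix()].
#' @export
read_cells_mtx <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  rownames(m) <- readLines(paste0(stem, ".features.tsv"))
  colnames(m) <- readLines(paste0(stem, ".barcodes.tsv"))
  meta <- read_tsv(paste0(stem, ".cells.tsv"))
  cell_matrix(m, meta)
}

#' Write genomic intervals as 4-column BED
#'
#' 0-based half-open `chrom start end name`.
#'
#' @param bed Data frame with columns `chrom`, `start`, `end`, `name`.
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(bed)))
  if (any(bed$end <= bed$start)) stop("malformed interval: end <= start")
  utils::write.table(bed[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column BED file
#' @param path Input path.
#' @return Data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "name")
  if (any(df$end <= df$start)) stop("malformed interval: end <= start")
  df[, 1:4]
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path Input path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a named list of gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, ids)
    paste(c(nm, d, ids), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
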