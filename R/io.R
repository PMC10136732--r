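#' Write a count matrix and its metadata as TSV
#'
#' Counts are written with variant ids in the first column (`variant_id`)
#' and one column per sample; metadata with header `sample_id`, `label`,
#' `cohort`, `site`.
#'
#' @param x a [tep_counts()].
#' @param counts_path,meta_path output files.
#' @return `counts_path`, invisibly.
#' @export
write_counts_tsv <- function(x, counts_path, meta_path) {
  stopifnot(inherits(x, "tep_counts"))
  df <- data.frame(variant_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Read a count matrix and metadata written by [write_counts_tsv()]
#'
#' @param counts_path,meta_path input files.
#' @return a [tep_counts()].
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  df <- read.table(counts_path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, colClasses = "character")
  tep_counts(m, meta)
}

#' Write counts as MatrixMarket with id sidecar files
#'
#' Writes the sparse integer matrix to `<stem>.mtx` plus `<stem>.rows.txt`
#' (variant ids) and `<stem>.cols.txt` (sample ids).
#'
#' @param x a [tep_counts()].
#' @param stem output path stem.
#' @return the `.mtx` path, invisibly.
#' @export
write_counts_mtx <- function(x, stem) {
  stopifnot(inherits(x, "tep_counts"))
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), mtx)
  writeLines(rownames(x$counts), paste0(stem, ".rows.txt"))
  writeLines(colnames(x$counts), paste0(stem, ".cols.txt"))
  invisible(mtx)
}

#' Read counts written by [write_counts_mtx()]
#'
#' @param stem path stem used at write time.
#' @param meta_path metadata TSV.
#' @return a [tep_counts()].
#' @export
read_counts_mtx <- function(stem, meta_path) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".rows.txt"))
  colnames(m) <- readLines(paste0(stem, ".cols.txt"))
  storage.mode(m) <- "integer"
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, colClasses = "character")
  tep_counts(m, meta)
}

#' Write / read an annotation table as TSV
#'
#' Header: `variant_id`, `gene_name`, `status`, `level`.
#'
#' @param annot annotation data.frame.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_annotation_tsv <- function(annot, path) {
  write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as TSV
#'
#' Floats are serialized with 12 significant digits; the first column
#' (`feature_id`) holds feature names.
#'
#' @param expr a [tep_expr()].
#' @param values_path,meta_path file paths.
#' @return `values_path` (write) or a [tep_expr()] (read).
#' @export
write_expr_tsv <- function(expr, values_path, meta_path) {
  stopifnot(inherits(expr, "tep_expr"))
  df <- data.frame(feature_id = rownames(expr$values),
                   signif(expr$values, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(values_path, meta_path) {
  df <- read.table(values_path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, colClasses = "character")
  tep_expr(m, meta)
}
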