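#' Construct a validated expression matrix
#'
#' An `ExpressionMatrix` couples a genes-by-samples matrix of non-negative
#' expression values (FPKM scale) with per-sample metadata: cell type,
#' replicate number and an optional time point in hours.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `cell_type`,
#'   `replicate` and optionally `time_hours`; one row per column of
#'   `values`, in the same order.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  if (is.null(rownames(values))) stopf("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids in expression matrix")
  if (any(!is.finite(values))) stopf("expression values must be finite")
  if (any(values < 0)) stopf("expression values must be non-negative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "replicate")
  if (!all(need %in% names(samples)))
    stopf("sample metadata must have columns: %s", paste(need, collapse = ", "))
  if (!"time_hours" %in% names(samples)) samples$time_hours <- NA_real_
  if (nrow(samples) != ncol(values))
    stopf("metadata rows (%d) do not match sample columns (%d)",
          nrow(samples), ncol(values))
  if (!is.null(colnames(values)) &&
      !identical(as.character(samples$sample_id), colnames(values)))
    stopf("metadata sample_id order does not match expression columns")
  colnames(values) <- samples$sample_id
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1L)) stopf("replicate numbers must be positive")
  key <- paste(samples$cell_type, samples$replicate, samples$time_hours)
  if (anyDuplicated(key))
    stopf("sample records must be unique on (cell_type, replicate, time_point)")
  structure(list(values = values, samples = samples), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d cell types)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$cell_type))))
  invisible(x)
}

#' Gene identifiers of an expression matrix
#' @param expr an `ExpressionMatrix`.
#' @return Character vector of gene ids, in row order.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' Read an expression matrix and its sample metadata from delimited text
#'
#' The expression table holds gene ids in the first column and one column
#' per sample; the metadata table has columns `sample_id`, `cell_type`,
#' `replicate` and optionally `time_hours`, with rows matching the sample
#' columns in order.
#'
#' @param path path to the expression TSV/CSV (tab- or comma-delimited;
#'   delimiter sniffed from the header line).
#' @param metadata_path path to the sample metadata table.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  if (!file.exists(metadata_path)) stopf("metadata file not found: %s", metadata_path)
  sep <- sniff_sep(path)
  tab <- read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stopf("expression table needs a gene id column plus samples")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stopf("duplicate gene id in %s", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  meta <- read.delim(metadata_path, sep = sniff_sep(metadata_path), header = TRUE,
                     comment.char = "#", stringsAsFactors = FALSE)
  expression_matrix(vals, meta)
}

#' Write an expression matrix (and optionally its metadata) to TSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output path for the expression table.
#' @param metadata_path optional output path for the sample metadata.
#' @param seed optional seed recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, metadata_path = NULL, seed = NULL) {
  df <- data.frame(gene_id = gene_ids(expr), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path, header = output_header(seed))
  if (!is.null(metadata_path))
    write_tsv_atomic(expr$samples, metadata_path, header = output_header(seed))
  invisible(path)
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param expr an `ExpressionMatrix`.
#' @param genes character vector of gene ids to keep (default all).
#' @param sample_ids character vector of sample ids to keep (default all).
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
subset_expression <- function(expr, genes = NULL, sample_ids = NULL) {
  v <- expr$values
  s <- expr$samples
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) stopf("genes not in expression matrix: %s",
                               paste(head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, s$sample_id)
    if (anyNA(keep)) stopf("unknown sample ids")
    v <- v[, keep, drop = FALSE]
    s <- s[keep, , drop = FALSE]
    rownames(s) <- NULL
  }
  expression_matrix(v, s)
}

#' @noRd
sniff_sep <- function(path) {
  l <- readLines(path, n = 25L)
  l <- l[!startsWith(l, "#")]
  if (length(l) && grepl("\t", l[1])) "\t" else ","
}
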