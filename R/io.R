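# TSV serialization for enrichment tables and time courses

#' Write an enrichment table as TSV
#'
#' The `enriched_cells` list-column is serialized comma-separated.
#'
#' @param et an `EnrichmentTable`.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(et, path, seed = NULL) {
  df <- as.data.frame(et)
  df$enriched_cells <- vapply(et$enriched_cells, paste, "", collapse = ",")
  write_tsv_atomic(df, path, header = output_header(seed))
}

#' Read an enrichment table written by [write_enrichment()]
#' @param path path to the TSV.
#' @return An `EnrichmentTable` (without the fold-change matrix attribute).
#' @export
read_enrichment <- function(path) {
  df <- read_tsv_comments(path)
  cells <- strsplit(ifelse(is.na(df$enriched_cells), "", df$enriched_cells), ",")
  df$enriched_cells <- lapply(cells, function(x) x[nzchar(x)])
  class(df) <- c("EnrichmentTable", "data.frame")
  df
}

#' Write a time course's replicate-mean matrix as TSV
#'
#' Columns are `t<hours>`; replicate structure is not preserved.
#'
#' @param tc a `TimeCourse`.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path, seed = NULL) {
  df <- data.frame(gene_id = rownames(tc$values), tc$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("t", format(tc$time_points, trim = TRUE))
  write_tsv_atomic(df, path, header = output_header(seed))
}

#' Read a time course written by [write_timecourse()]
#' @param path path to the TSV.
#' @return A [time_course()] of replicate means.
#' @export
read_timecourse <- function(path) {
  df <- read_tsv_comments(path)
  tp <- as.numeric(sub("^t", "", names(df)[-1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  time_course(m, tp)
}

#' Write a trajectory as TSV (time in rows, one column per species)
#' @param traj a `Trajectory`.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  df <- data.frame(time = traj$time, t(traj$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_atomic(df, path, header = output_header(seed))
}
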