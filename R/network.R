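#' Construct a directed, optionally signed, edge list
#'
#' @param regulator,target character vectors of gene ids.
#' @param weight non-negative edge weights (default 1).
#' @param sign +1 activation, -1 repression, 0 unknown (default 0).
#' @param cell_type optional cell-type label per edge (NA = unlabeled).
#' @param support consensus support in `[0, 1]` (default 1).
#' @return A `grn_network`: data.frame with columns `regulator`, `target`,
#'   `weight`, `sign`, `cell_type`, `support`.
#' @export
grn_network <- function(regulator = character(0), target = character(0),
                        weight = 1, sign = 0L, cell_type = NA_character_,
                        support = 1) {
  n <- length(regulator)
  if (length(target) != n) stopf("regulator/target length mismatch")
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   weight = rep_len(as.numeric(weight), n),
                   sign = rep_len(as.integer(sign), n),
                   cell_type = rep_len(as.character(cell_type), n),
                   support = rep_len(as.numeric(support), n),
                   stringsAsFactors = FALSE)
  validate_network(df)
}

#' @noRd
validate_network <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("regulator", "target")
  if (!all(need %in% names(df))) stopf("network needs regulator and target columns")
  if (!"weight" %in% names(df)) df$weight <- 1
  if (!"sign" %in% names(df)) df$sign <- 0L
  if (!"cell_type" %in% names(df)) df$cell_type <- NA_character_
  if (!"support" %in% names(df)) df$support <- 1
  df <- df[, c("regulator", "target", "weight", "sign", "cell_type", "support")]
  if (any(df$regulator == df$target)) stopf("self-edges are not allowed")
  if (any(df$weight < 0, na.rm = TRUE)) stopf("edge weights must be >= 0")
  if (!all(df$sign %in% c(-1L, 0L, 1L))) stopf("edge sign must be -1, 0 or +1")
  if (any(df$support < 0 | df$support > 1, na.rm = TRUE))
    stopf("support must lie in [0, 1]")
  key <- paste(df$regulator, df$target, df$cell_type)
  if (anyDuplicated(key))
    stopf("at most one edge per (regulator, target, cell_type)")
  rownames(df) <- NULL
  class(df) <- c("grn_network", "data.frame")
  df
}

#' Coerce a data.frame to a grn_network
#' @param df data.frame with at least `regulator` and `target` columns.
#' @return A validated `grn_network`.
#' @export
as_grn_network <- function(df) validate_network(df)

#' Write a network as TSV or Cytoscape SIF
#'
#' The TSV dialect writes all six edge columns and round-trips through
#' [read_network()]. The SIF dialect writes `regulator <relation> target`
#' lines with the relation mapped from the sign: +1 "activates",
#' -1 "represses", 0 "regulates".
#'
#' @param net a `grn_network`.
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param seed optional seed recorded in the TSV header.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif"), seed = NULL) {
  net <- validate_network(net)
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    write_tsv_atomic(net, path, header = output_header(seed))
  } else {
    rel <- c(`-1` = "represses", `0` = "regulates", `1` = "activates")
    lines <- sprintf("%s %s %s", net$regulator,
                     rel[as.character(net$sign)], net$target)
    tmp <- paste0(path, ".tmp")
    writeLines(lines, tmp)
    file.rename(tmp, path)
  }
  invisible(path)
}

#' Read a network written by [write_network()] (TSV dialect)
#' @param path path to the TSV edge list.
#' @return A `grn_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  df <- read_tsv_comments(path)
  if (nrow(df)) {
    df$cell_type <- as.character(df$cell_type)
    df$sign <- as.integer(df$sign)
  }
  validate_network(df)
}

#' In- and outdegree of every gene in a network
#'
#' @param net a `grn_network`.
#' @param genes optional gene universe; defaults to genes present in edges.
#' @return data.frame with columns `gene_id`, `indegree`, `outdegree`.
#'   Parallel edges in different cell types count once per (regulator,
#'   target) pair.
#' @export
degree_stats <- function(net, genes = NULL) {
  net <- validate_network(net)
  pairs <- unique(net[, c("regulator", "target")])
  if (is.null(genes)) genes <- sort(unique(c(pairs$regulator, pairs$target)))
  data.frame(gene_id = genes,
             indegree = as.integer(table(factor(pairs$target, levels = genes))),
             outdegree = as.integer(table(factor(pairs$regulator, levels = genes))),
             stringsAsFactors = FALSE)
}
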