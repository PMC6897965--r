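#' Classify genes as stem-cell enriched, ubiquitous or specific
#'
#' A gene passes the control gate when its differential-expression q-value
#' against the non-stem-cell control is below `q_threshold` and its
#' fold-change over the control exceeds `fc_threshold` (defaults 0.06 and
#' 2). For genes passing the gate, per-cell-type membership is decided
#' from replicate-mean expression: a cell type is enriched when the gene's
#' mean there exceeds `fc_threshold` times the strongest (default) or mean
#' competing cell type. Genes passing the gate but clearing the per-cell
#' bar nowhere are treated as equally expressed and assigned to every cell
#' type whose mean lies within `fc_threshold` of the top cell. Genes
#' enriched in at least four cell types (of six) are called ubiquitous,
#' one to three specific, none not_enriched.
#'
#' @param expr an [expression_matrix()] containing the stem-cell samples
#'   and the control samples.
#' @param de data.frame with columns `gene_id`, `q_value`, `fc_vs_control`
#'   covering every gene of `expr` (q-values are consumed as given, e.g.
#'   from a count-based differential-expression method).
#' @param q_threshold q-value gate versus the control (default 0.06).
#' @param fc_threshold fold-change gate, used both versus the control and
#'   between cell types (default 2).
#' @param control name of the control cell type in the sample metadata
#'   (default "NSC").
#' @param pseudocount added to every mean before forming ratios, so
#'   dropout genes do not divide by zero (default 1 FPKM).
#' @param denominator compare each cell type against the `"max"` (default)
#'   or the `"mean"` of the other cell types.
#' @param ubiquitous_min minimum number of enriched cell types for the
#'   ubiquitous call (default 4).
#' @return An `EnrichmentTable`: data.frame with columns `gene_id`,
#'   `q_value`, `fc_vs_control`, `n_enriched`, `ubiquity_class` and a
#'   list-column `enriched_cells`; attribute `fc_per_celltype` holds the
#'   genes-by-cell-types fold-change matrix.
#' @export
classify_enrichment <- function(expr, de, q_threshold = 0.06, fc_threshold = 2,
                                control = "NSC", pseudocount = 1,
                                denominator = c("max", "mean"),
                                ubiquitous_min = 4L) {
  denominator <- match.arg(denominator)
  de <- as.data.frame(de, stringsAsFactors = FALSE)
  need <- c("gene_id", "q_value", "fc_vs_control")
  if (!all(need %in% names(de)))
    stopf("de table must have columns: %s", paste(need, collapse = ", "))
  g <- gene_ids(expr)
  idx <- match(g, de$gene_id)
  if (anyNA(idx)) stopf("de table does not cover all genes")
  de <- de[idx, , drop = FALSE]

  cts <- unique(expr$samples$cell_type)
  if (!control %in% cts)
    stopf("control cell type '%s' not present in sample metadata", control)
  cells <- setdiff(cts, control)
  if (length(cells) < 2) stopf("need at least two non-control cell types")

  means <- cell_means(expr)[, cells, drop = FALSE]
  m <- means + pseudocount
  fc <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_along(cells)) {
    other <- m[, -j, drop = FALSE]
    den <- if (denominator == "max") apply(other, 1, max) else rowMeans(other)
    fc[, j] <- m[, j] / den
  }

  gate <- de$q_value < q_threshold & de$fc_vs_control > fc_threshold
  enriched <- vector("list", length(g))
  for (i in seq_along(g)) {
    if (!isTRUE(gate[i])) { enriched[[i]] <- character(0); next }
    hit <- cells[fc[i, ] > fc_threshold]
    if (!length(hit)) {
      # equally expressed: every cell within fc_threshold of the top cell
      top <- max(m[i, ])
      hit <- cells[top / m[i, ] <= fc_threshold]
    }
    enriched[[i]] <- hit
  }
  n_enr <- lengths(enriched)
  cls <- ifelse(n_enr >= ubiquitous_min, "ubiquitous",
                ifelse(n_enr >= 1L, "specific", "not_enriched"))
  out <- data.frame(gene_id = g, q_value = de$q_value,
                    fc_vs_control = de$fc_vs_control,
                    n_enriched = n_enr, ubiquity_class = cls,
                    stringsAsFactors = FALSE)
  out$enriched_cells <- enriched
  attr(out, "fc_per_celltype") <- fc
  attr(out, "cell_types") <- cells
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Per-gene mean expression by cell type
#' @param expr an `ExpressionMatrix`.
#' @return genes x cell-types matrix of replicate means.
#' @export
cell_means <- function(expr) {
  ct <- expr$samples$cell_type
  cts <- unique(ct)
  out <- vapply(cts, function(c)
    rowMeans(expr$values[, ct == c, drop = FALSE]), numeric(nrow(expr$values)))
  out <- matrix(out, nrow = nrow(expr$values),
                dimnames = list(rownames(expr$values), cts))
  out
}

#' Genes enriched in a given cell type
#' @param et an `EnrichmentTable`.
#' @param cell cell-type name.
#' @return Character vector of gene ids enriched in `cell`.
#' @export
enriched_in <- function(et, cell) {
  et$gene_id[vapply(et$enriched_cells, function(s) cell %in% s, logical(1))]
}
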