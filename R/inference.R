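#' Inference configuration for the consensus GRN pipeline
#'
#' @param numiter number of clustering restarts voted into the consensus
#'   (default 100).
#' @param maxprop minimum fraction of restart networks an edge must appear
#'   in to be retained (default 1/3; 0.45 is used for time-point networks).
#' @param n_trees trees per regression ensemble (default 1000).
#' @param trim_factor edges kept per cluster = `ceiling(trim_factor * nTF)`
#'   (default 5), so clusters with more transcription factors keep more
#'   edges.
#' @param k cluster count; `NULL` (default) uses [choose_default_k()].
#' @param seed base seed; restart i uses seed + i.
#' @return A list of class `InferenceConfig`.
#' @export
inference_config <- function(numiter = 100L, maxprop = 1 / 3, n_trees = 1000L,
                             trim_factor = 5, k = NULL, seed = 1L) {
  if (numiter < 1) stopf("numiter must be >= 1")
  if (maxprop <= 0 || maxprop > 1) stopf("maxprop must lie in (0, 1]")
  if (n_trees < 1) stopf("n_trees must be >= 1")
  if (trim_factor <= 0) stopf("trim_factor must be > 0")
  structure(list(numiter = as.integer(numiter), maxprop = maxprop,
                 n_trees = as.integer(n_trees), trim_factor = trim_factor,
                 k = if (!is.null(k)) as.integer(k), seed = as.integer(seed)),
            class = "InferenceConfig")
}

#' Tree-ensemble importance of candidate regulators for one target
#'
#' Fits a random forest of regression trees predicting the target's
#' unit-variance-scaled expression from the regulators' expression across
#' samples; a regulator's weight is its summed impurity (variance
#' reduction) importance, normalized to sum to one over regulators.
#'
#' @param target gene id of the target.
#' @param regulators character vector of candidate regulator gene ids
#'   (must not include the target).
#' @param expr an `ExpressionMatrix` containing target and regulators.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; result is deterministic given the seed.
#' @return Named numeric vector of weights >= 0 over `regulators`
#'   (all zero for a zero-variance target).
#' @export
importance_scores <- function(target, regulators, expr, n_trees = 1000L, seed = 1L) {
  if (target %in% regulators) stopf("target must not be among regulators")
  if (!length(regulators)) return(setNames(numeric(0), character(0)))
  v <- expr$values
  if (ncol(v) < 3) stopf("need at least 3 samples for tree-ensemble inference")
  y <- v[target, ]
  if (sd(y) == 0) return(setNames(numeric(length(regulators)), regulators))
  y <- as.numeric(scale(y))
  x <- t(v[regulators, , drop = FALSE])
  colnames(x) <- regulators
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        importance = "impurity",
                        mtry = max(1L, floor(sqrt(ncol(x)))),
                        min.node.size = 2L, num.threads = 1L,
                        seed = as.integer(seed %% 2147483647L))
  imp <- fit$variable.importance[regulators]
  imp[is.na(imp) | imp < 0] <- 0
  s <- sum(imp)
  w <- if (s > 0) imp / s else imp
  setNames(as.numeric(w), regulators)
}

#' Keep the strongest edges in proportion to the transcription-factor count
#'
#' Retains the top `ceiling(trim_factor * n_tf)` edges by weight; ties at
#' the cutoff are broken lexicographically by (regulator, target).
#'
#' @param weighted_edges a `grn_network` (or data.frame of edges).
#' @param n_tf number of transcription factors behind these edges.
#' @param trim_factor edges kept per TF (default 5).
#' @return The trimmed `grn_network`.
#' @export
trim_edges <- function(weighted_edges, n_tf, trim_factor = 5) {
  net <- validate_network(weighted_edges)
  keep_n <- as.integer(ceiling(trim_factor * n_tf))
  if (nrow(net) <= keep_n) return(net)
  ord <- order(-net$weight, net$regulator, net$target)
  validate_network(net[ord[seq_len(keep_n)], , drop = FALSE])
}

#' Infer one weighted network from one clustering of one cell context
#'
#' Within each cluster, every gene is a candidate target and the
#' transcription factors of that cluster are the candidate regulators,
#' so all edges are intra-cluster and TF-rooted. Per-cluster edge lists
#' are trimmed with [trim_edges()] and pooled.
#'
#' @param expr `ExpressionMatrix` restricted to one cell context's samples
#'   (the cell's replicates plus any shared control replicates).
#' @param tf_ids character vector of transcription-factor gene ids.
#' @param clusters a `ClusterAssignment` over the genes of `expr`.
#' @param cfg an [inference_config()].
#' @param seed seed for the tree ensembles.
#' @return An unsigned weighted `grn_network`.
#' @export
infer_single_network <- function(expr, tf_ids, clusters, cfg, seed = cfg$seed) {
  stopifnot(inherits(clusters, "ClusterAssignment"))
  parts <- split(clusters$gene_id, clusters$cluster)
  out <- list()
  for (genes in parts) {
    tfs <- intersect(genes, tf_ids)
    if (!length(tfs)) next  # cluster without a TF contributes no edges
    edges <- list()
    for (ti in seq_along(genes)) {
      tg <- genes[ti]
      regs <- setdiff(tfs, tg)
      if (!length(regs)) next
      w <- importance_scores(tg, regs, expr, n_trees = cfg$n_trees,
                             seed = child_seed(seed, ti))
      keep <- w > 0
      if (any(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          regulator = names(w)[keep], target = tg, weight = as.numeric(w[keep]),
          sign = 0L, cell_type = NA_character_, support = 1,
          stringsAsFactors = FALSE)
    }
    if (!length(edges)) next
    cluster_net <- validate_network(do.call(rbind, edges))
    out[[length(out) + 1L]] <- trim_edges(cluster_net, length(tfs), cfg$trim_factor)
  }
  if (!length(out)) return(grn_network())
  validate_network(do.call(rbind, out))
}

#' Consensus network over a collection of restart networks
#'
#' An edge (regulator, target) is retained when it appears in at least
#' `maxprop` of the input networks; its support is that fraction and its
#' weight the mean weight over the networks containing it.
#'
#' @param networks list of `grn_network` objects.
#' @param maxprop minimum appearance fraction (default 1/3).
#' @return A `grn_network` with `support` filled in.
#' @export
consensus_network <- function(networks, maxprop = 1 / 3) {
  if (!length(networks)) stopf("consensus over an empty network list")
  n <- length(networks)
  tab <- new.env(parent = emptyenv())
  for (net in networks) {
    net <- validate_network(net)
    if (!nrow(net)) next
    pairs <- paste(net$regulator, net$target, sep = "\r")
    agg <- tapply(net$weight, pairs, mean)  # collapse multi-cell duplicates
    for (p in names(agg)) {
      cur <- tab[[p]] %||% c(0, 0)
      tab[[p]] <- c(cur[1] + 1, cur[2] + agg[[p]])
    }
  }
  keys <- ls(tab)
  if (!length(keys)) return(grn_network())
  counts <- vapply(keys, function(p) tab[[p]][1], numeric(1))
  wsum <- vapply(keys, function(p) tab[[p]][2], numeric(1))
  support <- counts / n
  keep <- support >= maxprop - 1e-12
  if (!any(keep)) return(grn_network())
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  out <- data.frame(regulator = vapply(parts, `[`, "", 1),
                    target = vapply(parts, `[`, "", 2),
                    weight = wsum[keep] / counts[keep],
                    sign = 0L, cell_type = NA_character_,
                    support = support[keep], stringsAsFactors = FALSE)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  validate_network(out)
}

#' Default per-cell sample contexts
#'
#' Each stem-cell context uses that cell's replicates plus the control
#' (niche-marker) replicates.
#'
#' @param expr an `ExpressionMatrix`.
#' @param control control cell type shared across contexts.
#' @return Named list mapping cell type -> character vector of sample ids.
#' @export
cell_contexts <- function(expr, control = "NSC") {
  s <- expr$samples
  cells <- setdiff(unique(s$cell_type), control)
  setNames(lapply(cells, function(ct)
    s$sample_id[s$cell_type %in% c(ct, control)]), cells)
}

#' Consensus GRN over clustering restarts, per stem cell, combined
#'
#' For every cell type, the gene universe is the set of genes enriched in
#' that cell (genes enriched in several cells enter each of their cells'
#' networks). Genes are clustered `numiter` times with seeds
#' `seed + 1 ... seed + numiter` on their cell-type mean profile; each
#' clustering yields one network inferred from that cell context's
#' replicates only; the per-cell consensus keeps edges appearing in at
#' least `maxprop` of the restarts. Per-cell networks are combined by
#' union, with each edge labeled by its cell type.
#'
#' @param expr `ExpressionMatrix` with all cells' samples.
#' @param tf_ids transcription-factor gene ids.
#' @param cfg an [inference_config()].
#' @param enrichment an `EnrichmentTable` defining per-cell gene universes.
#' @param contexts named list cell -> sample ids (default [cell_contexts()]).
#' @param control control cell type used by the default contexts.
#' @return Combined `grn_network` with per-edge `cell_type` labels.
#' @export
run_rtpstar <- function(expr, tf_ids, cfg, enrichment,
                        contexts = NULL, control = "NSC") {
  if (is.null(contexts)) contexts <- cell_contexts(expr, control)
  combined <- list()
  for (ct in names(contexts)) {
    genes <- intersect(gene_ids(expr), enriched_in(enrichment, ct))
    if (length(genes) < 2) next
    expr_ct <- subset_expression(expr, genes = genes,
                                 sample_ids = contexts[[ct]])
    profile <- mean_profile(subset_expression(expr, genes = genes))
    k <- cfg$k %||% choose_default_k(length(genes))
    nets <- vector("list", cfg$numiter)
    for (i in seq_len(cfg$numiter)) {
      it_seed <- cfg$seed + i
      cl <- cluster_genes(profile, k = k, seed = it_seed)
      nets[[i]] <- infer_single_network(expr_ct, tf_ids, cl, cfg,
                                        seed = child_seed(it_seed, 7L))
    }
    cons <- consensus_network(nets, cfg$maxprop)
    if (nrow(cons)) {
      cons$cell_type <- ct
      combined[[ct]] <- cons
    }
  }
  if (!length(combined)) return(grn_network())
  validate_network(do.call(rbind, combined))
}

#' One consensus network per time point of a time-course experiment
#'
#' Clustering uses the cell-type mean profile of the spatial (stem-cell)
#' dataset, as in [run_rtpstar()]; inference at each time point uses only
#' that time point's biological replicates. The consensus threshold
#' defaults to 0.45. Edges are labeled with every cell type in which both
#' endpoints are enriched.
#'
#' @param tc_expr `ExpressionMatrix` whose samples carry `time_hours`.
#' @param tf_ids transcription-factor gene ids.
#' @param cfg an [inference_config()]; `maxprop` should be 0.45 for
#'   time-point networks.
#' @param gene_subset genes to infer over (e.g. perturbation-responsive,
#'   stem-cell-enriched genes).
#' @param profile_expr `ExpressionMatrix` supplying the cell-type profile
#'   used for clustering (defaults to `tc_expr`, whose "cell types" are
#'   then its time points).
#' @param enrichment optional `EnrichmentTable` used to label edges with
#'   cell types.
#' @return Named list time point (hours, as character) -> `grn_network`.
#'   Time points with fewer than three replicates are skipped with a
#'   warning (tree ensembles need >= 3 samples).
#' @export
run_timepoint_networks <- function(tc_expr, tf_ids, cfg, gene_subset = NULL,
                                   profile_expr = NULL, enrichment = NULL) {
  s <- tc_expr$samples
  if (all(is.na(s$time_hours))) stopf("time-course samples need time_hours")
  genes <- gene_subset %||% gene_ids(tc_expr)
  genes <- intersect(gene_ids(tc_expr), genes)
  prof_src <- profile_expr %||% tc_expr
  profile <- mean_profile(subset_expression(prof_src,
                                            genes = intersect(genes, gene_ids(prof_src))))
  genes <- rownames(profile)
  k <- cfg$k %||% choose_default_k(length(genes))
  tps <- sort(unique(s$time_hours))
  out <- list()
  for (tp in tps) {
    ids <- s$sample_id[s$time_hours == tp]
    if (length(ids) < 3) {
      warnf("time point %s h skipped: %d replicate(s) < 3", format(tp), length(ids))
      next
    }
    expr_tp <- subset_expression(tc_expr, genes = genes, sample_ids = ids)
    nets <- vector("list", cfg$numiter)
    for (i in seq_len(cfg$numiter)) {
      it_seed <- cfg$seed + i
      cl <- cluster_genes(profile, k = k, seed = it_seed)
      nets[[i]] <- infer_single_network(expr_tp, tf_ids, cl, cfg,
                                        seed = child_seed(it_seed, 13L))
    }
    cons <- consensus_network(nets, cfg$maxprop)
    if (!is.null(enrichment) && nrow(cons))
      cons <- label_edges_by_enrichment(cons, enrichment)
    out[[format(tp)]] <- cons
  }
  out
}

# expand each edge to one row per cell type in which both endpoints are
# enriched; edges with no co-enriched cell stay unlabeled
#' @noRd
label_edges_by_enrichment <- function(net, enrichment) {
  rows <- lapply(seq_len(nrow(net)), function(i) {
    e <- net[i, , drop = FALSE]
    cells_r <- enrichment$enriched_cells[[match(e$regulator, enrichment$gene_id)]]
    cells_t <- enrichment$enriched_cells[[match(e$target, enrichment$gene_id)]]
    both <- intersect(cells_r, cells_t)
    if (!length(both)) return(e)
    do.call(rbind, lapply(both, function(ct) { e$cell_type <- ct; e }))
  })
  validate_network(do.call(rbind, rows))
}
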