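#' The five directed motif classes scored by the NMS
#'
#' feed_forward: A->B, A->C, B->C; feedback: the 3-cycle A->B->C->A;
#' diamond: A->B, A->C, B->D, C->D; bi_fan: A->C, A->D, B->C, B->D;
#' multilayer: the 4-node cascade A->B->C->D. Each pattern is a small
#' directed graph given as an integer edge matrix; the catalog can be
#' overridden with user-supplied patterns of 3-4 nodes.
#'
#' @return Named list of patterns, each `list(n, edges)` with `edges` a
#'   two-column matrix of 1-based vertex indices.
#' @export
motif_catalog <- function() {
  pat <- function(n, ...) {
    e <- matrix(c(...), ncol = 2, byrow = TRUE)
    list(n = n, edges = e)
  }
  list(
    feed_forward = pat(3, 1, 2, 1, 3, 2, 3),
    feedback     = pat(3, 1, 2, 2, 3, 3, 1),
    diamond      = pat(4, 1, 2, 1, 3, 2, 4, 3, 4),
    bi_fan       = pat(4, 1, 3, 1, 4, 2, 3, 2, 4),
    multilayer   = pat(4, 1, 2, 2, 3, 3, 4)
  )
}

#' @noRd
validate_pattern <- function(p, name = "pattern") {
  if (!is.list(p) || is.null(p$n) || is.null(p$edges))
    stopf("%s must be list(n, edges)", name)
  e <- p$edges
  if (any(e[, 1] == e[, 2])) stopf("%s has a self-loop", name)
  if (p$n < 3 || p$n > 4) stopf("%s must have 3-4 nodes", name)
  if (anyDuplicated(paste(e[, 1], e[, 2]))) stopf("%s has duplicate edges", name)
  p
}

# all permutations of 1..n (n <= 4 here)
#' @noRd
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- as.integer(append(p, n, after = pos - 1L))
  }
  out
}

# automorphisms of a pattern: permutations mapping its edge set onto itself
#' @noRd
pattern_automorphisms <- function(p) {
  ek <- sort(paste(p$edges[, 1], p$edges[, 2]))
  Filter(function(perm) {
    identical(sort(paste(perm[p$edges[, 1]], perm[p$edges[, 2]])), ek)
  }, all_perms(p$n))
}

# enumerate all subgraph monomorphisms of pattern into the directed graph,
# deduplicated modulo pattern automorphism; returns a list of integer
# image tuples (graph node indices, in pattern-vertex order)
#' @noRd
match_pattern <- function(p, n_nodes, out_adj, in_adj, edge_set) {
  auts <- pattern_automorphisms(p)
  # order pattern vertices so each new vertex touches an earlier one
  ord <- integer(0)
  remaining <- seq_len(p$n)
  ord <- 1L
  while (length(ord) < p$n) {
    nxt <- NULL
    for (v in setdiff(remaining, ord)) {
      touches <- any((p$edges[, 1] == v & p$edges[, 2] %in% ord) |
                     (p$edges[, 2] == v & p$edges[, 1] %in% ord))
      if (touches) { nxt <- v; break }
    }
    if (is.null(nxt)) nxt <- setdiff(remaining, ord)[1]
    ord <- c(ord, nxt)
  }
  found <- new.env(parent = emptyenv())
  images <- list()
  assign_map <- integer(p$n)

  constraints <- lapply(seq_along(ord), function(i) {
    v <- ord[i]
    prev <- ord[seq_len(i - 1L)]
    list(v = v,
         out_to = p$edges[p$edges[, 1] == v & p$edges[, 2] %in% prev, 2],
         in_from = p$edges[p$edges[, 2] == v & p$edges[, 1] %in% prev, 1])
  })

  recurse <- function(i) {
    if (i > p$n) {
      key_best <- NULL
      for (a in auts) {
        key <- paste(assign_map[a], collapse = ",")
        if (is.null(key_best) || key < key_best) key_best <- key
      }
      if (is.null(found[[key_best]])) {
        found[[key_best]] <- TRUE
        images[[length(images) + 1L]] <<- assign_map
      }
      return(invisible())
    }
    cs <- constraints[[i]]
    v <- cs$v
    # candidate graph nodes: constrain via one required adjacency if any
    cand <- if (length(cs$out_to)) {
      in_adj[[assign_map[cs$out_to[1]]]]
    } else if (length(cs$in_from)) {
      out_adj[[assign_map[cs$in_from[1]]]]
    } else seq_len(n_nodes)
    used <- assign_map[ord[seq_len(i - 1L)]]
    for (g in cand) {
      if (g %in% used) next
      ok <- TRUE
      for (u in cs$out_to) if (!edge_set[[paste(g, assign_map[u])]] %||% FALSE) { ok <- FALSE; break }
      if (ok) for (u in cs$in_from) if (!edge_set[[paste(assign_map[u], g)]] %||% FALSE) { ok <- FALSE; break }
      if (!ok) next
      assign_map[v] <<- g
      recurse(i + 1L)
      assign_map[v] <<- 0L
    }
  }
  recurse(1L)
  images
}

#' Count per-gene participation in each motif class
#'
#' Enumerates all matches of every catalog pattern in the network as
#' subgraph monomorphisms (extra edges among the matched nodes are
#' allowed), counted once per instance modulo the pattern's automorphisms,
#' and increments each participating gene once per instance.
#'
#' @param net a `grn_network` (parallel edges across cell types collapse
#'   to one directed edge).
#' @param catalog motif patterns (default [motif_catalog()]).
#' @param genes optional gene universe for the rows of the result.
#' @return A `MotifCountTable`: integer matrix genes x motifs, with
#'   attribute `totals` holding the per-motif instance counts.
#' @export
count_motifs <- function(net, catalog = motif_catalog(), genes = NULL) {
  net <- validate_network(net)
  pairs <- unique(net[, c("regulator", "target")])
  nodes <- sort(unique(c(pairs$regulator, pairs$target)))
  if (is.null(genes)) genes <- nodes
  counts <- matrix(0L, length(genes), length(catalog),
                   dimnames = list(genes, names(catalog)))
  totals <- setNames(integer(length(catalog)), names(catalog))
  if (nrow(pairs) && length(nodes) >= 3) {
    ri <- match(pairs$regulator, nodes)
    ti <- match(pairs$target, nodes)
    out_adj <- lapply(seq_along(nodes), function(i) ti[ri == i])
    in_adj <- lapply(seq_along(nodes), function(i) ri[ti == i])
    edge_set <- new.env(parent = emptyenv(), size = nrow(pairs) * 2L)
    for (i in seq_len(nrow(pairs))) edge_set[[paste(ri[i], ti[i])]] <- TRUE
    gi <- match(nodes, genes)
    for (mn in names(catalog)) {
      p <- validate_pattern(catalog[[mn]], mn)
      imgs <- match_pattern(p, length(nodes), out_adj, in_adj, edge_set)
      totals[[mn]] <- length(imgs)
      for (img in imgs) {
        rows <- gi[unique(img)]
        rows <- rows[!is.na(rows)]
        counts[rows, mn] <- counts[rows, mn] + 1L
      }
    }
  }
  attr(counts, "totals") <- totals
  class(counts) <- c("MotifCountTable", class(counts))
  counts
}

#' Network Motif Score per gene
#'
#' Within each motif class, per-gene counts are normalized to `[0, 1]` by
#' the maximum count over genes (0/0 maps to 0); the NMS is the sum of
#' the normalized scores over motif classes, so it ranges from 0 to the
#' number of motifs. High-NMS genes are flagged as putatively functionally
#' important.
#'
#' @param counts a `MotifCountTable` from [count_motifs()].
#' @return data.frame with `gene_id`, one normalized column per motif,
#'   and `nms`, sorted by decreasing NMS.
#' @export
nms_scores <- function(counts) {
  if (!nrow(counts)) stopf("empty motif count table")
  cm <- unclass(counts)
  attr(cm, "totals") <- NULL
  mx <- apply(cm, 2, max)
  norm <- sweep(cm, 2, ifelse(mx > 0, mx, 1), "/")
  out <- data.frame(gene_id = rownames(cm), norm, nms = rowSums(norm),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[order(-out$nms, out$gene_id), , drop = FALSE]
}

#' Motif enrichment against size-matched random networks
#'
#' The null model draws directed Erdos-Renyi G(n, m) graphs with the same
#' node and edge counts as the observed network (degree-preserving
#' rewiring available via `null`). The empirical p-value is the fraction
#' of null total counts >= the observed total.
#'
#' @param net a `grn_network` with >= 1 edge.
#' @param catalog motif patterns (default [motif_catalog()]).
#' @param n_random number of null networks (default 100; < 10 warns).
#' @param seed RNG seed for the null draws.
#' @param null `"gnm"` (default) or `"rewire"` (degree-preserving).
#' @return data.frame per motif: `motif`, `observed_total`, `null_mean`,
#'   `null_sd`, `z`, `empirical_p`. `z` is NA when the null is degenerate.
#' @export
motif_enrichment <- function(net, catalog = motif_catalog(), n_random = 100L,
                             seed = 1L, null = c("gnm", "rewire")) {
  net <- validate_network(net)
  null <- match.arg(null)
  if (!nrow(net)) stopf("motif enrichment needs >= 1 edge")
  if (n_random < 10) warnf("n_random < 10 gives unstable empirical p-values")
  pairs <- unique(net[, c("regulator", "target")])
  nodes <- sort(unique(c(pairs$regulator, pairs$target)))
  n <- length(nodes); m <- nrow(pairs)
  obs <- attr(count_motifs(net, catalog), "totals")
  g0 <- igraph::graph_from_edgelist(as.matrix(pairs), directed = TRUE)
  null_tot <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      g <- if (null == "gnm") igraph::sample_gnm(n, m, directed = TRUE)
           else igraph::rewire(g0, igraph::keeping_degseq(niter = m * 10))
      el <- igraph::as_edgelist(g, names = FALSE)
      rnet <- grn_network(paste0("n", el[, 1]), paste0("n", el[, 2]))
      attr(count_motifs(rnet, catalog), "totals")
    }, numeric(length(catalog)))
  })
  null_tot <- matrix(null_tot, nrow = length(catalog),
                     dimnames = list(names(catalog), NULL))
  mu <- rowMeans(null_tot)
  sdv <- apply(null_tot, 1, sd)
  data.frame(motif = names(catalog),
             observed_total = as.numeric(obs[names(catalog)]),
             null_mean = mu, null_sd = sdv,
             z = ifelse(sdv > 0, (obs[names(catalog)] - mu) / sdv, NA_real_),
             empirical_p = vapply(names(catalog), function(mn)
               mean(null_tot[mn, ] >= obs[[mn]]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score predicted direct targets of a focal gene against perturbation data
#'
#' Given the predicted outgoing edges of a focal regulator and a table of
#' observed differential expression in the perturbation (e.g. knockout)
#' of that regulator, computes: the fraction of predicted direct targets
#' differentially expressed in any cell type; the fraction of edges whose
#' target is DE in the edge's labeled cell type; and, among correct-cell
#' edges with a predicted sign, the fraction whose sign is consistent with
#' the observed direction under a knockout (predicted activation implies
#' the target goes down in the mutant).
#'
#' @param predicted a `grn_network`; only edges out of `focal_gene` are
#'   used.
#' @param observed_de data.frame with columns `gene_id`, `cell_type`,
#'   `is_de` (logical) and `direction` (+1 up in mutant, -1 down).
#' @param focal_gene the perturbed regulator.
#' @return list with `frac_de`, `frac_correct_cell`, `frac_correct_sign`
#'   (NA when no signed correct-cell edges exist) and `n_targets`.
#' @export
score_edge_validation <- function(predicted, observed_de, focal_gene) {
  predicted <- validate_network(predicted)
  ed <- predicted[predicted$regulator == focal_gene, , drop = FALSE]
  if (!focal_gene %in% c(predicted$regulator, predicted$target) || !nrow(ed))
    stopf("focal gene '%s' has no outgoing edges in the predicted network",
          focal_gene)
  de <- as.data.frame(observed_de, stringsAsFactors = FALSE)
  de_any <- unique(de$gene_id[de$is_de])
  targets <- unique(ed$target)
  frac_de <- mean(targets %in% de_any)
  cell_key <- paste(de$gene_id, de$cell_type)[de$is_de]
  correct_cell <- paste(ed$target, ed$cell_type) %in% cell_key
  frac_cell <- mean(correct_cell)
  signed <- correct_cell & ed$sign != 0L
  frac_sign <- if (!any(signed)) NA_real_ else {
    dir_map <- setNames(de$direction, paste(de$gene_id, de$cell_type))
    obs_dir <- dir_map[paste(ed$target, ed$cell_type)[signed]]
    mean(ed$sign[signed] == -obs_dir)  # activation => down in knockout
  }
  list(frac_de = frac_de, frac_correct_cell = frac_cell,
       frac_correct_sign = frac_sign, n_targets = length(targets))
}
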