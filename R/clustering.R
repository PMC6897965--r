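#' Mean expression profile of each gene in each cell type
#'
#' Genes are clustered on their replicate-mean expression per cell type;
#' this computes that genes-by-cell-types profile.
#'
#' @param expr an `ExpressionMatrix`.
#' @param cell_types optional subset/order of cell types to include.
#' @return genes x cell-types numeric matrix of means.
#' @export
mean_profile <- function(expr, cell_types = NULL) {
  m <- cell_means(expr)
  if (!is.null(cell_types)) {
    missing <- setdiff(cell_types, colnames(m))
    if (length(missing))
      stopf("cell type with zero samples: %s", paste(missing, collapse = ", "))
    m <- m[, cell_types, drop = FALSE]
  }
  m
}

#' Default cluster count for n genes
#'
#' `max(2, ceiling(sqrt(n/2)))`, capped at the number of genes.
#'
#' @param n_genes number of genes to be clustered.
#' @return A positive integer k.
#' @export
choose_default_k <- function(n_genes) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  min(n_genes, max(2L, as.integer(ceiling(sqrt(n_genes / 2)))))
}

#' Seeded k-means partition of genes on their cell-type profile
#'
#' Lloyd's algorithm with Euclidean distance and a single random
#' initialization per call; the restart-level randomness (different seeds)
#' is what drives consensus network inference downstream. Profiles are
#' z-scored per gene first (constant rows map to zero) so clusters group
#' expression shapes across cell types rather than magnitudes. Empty
#' clusters are re-seeded with the point farthest from its current
#' centroid, keeping k fixed.
#'
#' @param profile genes x cell-types matrix (see [mean_profile()]).
#' @param k number of clusters, `k <= nrow(profile)`.
#' @param seed integer seed; the assignment is deterministic given
#'   `(profile, k, seed)`.
#' @param standardize z-score rows before clustering (default TRUE).
#' @param max_iter,tol Lloyd iteration cap and centroid-shift convergence
#'   tolerance.
#' @return A `ClusterAssignment`: data.frame with columns `gene_id`,
#'   `cluster` (0-based index in `[0, k)`); attributes `k` and `seed`.
#' @export
cluster_genes <- function(profile, k, seed, standardize = TRUE,
                          max_iter = 300L, tol = 1e-6) {
  profile <- as.matrix(profile)
  n <- nrow(profile)
  if (k > n) stopf("k (%d) exceeds number of genes (%d)", k, n)
  if (k < 1) stopf("k must be >= 1")
  x <- if (standardize) zscore_rows(profile) else profile
  assign <- with_seed(seed, lloyd_kmeans(x, k, max_iter, tol))
  out <- data.frame(gene_id = rownames(profile), cluster = assign - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("ClusterAssignment", "data.frame")
  out
}

#' @noRd
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s[s == 0 | !is.finite(s)] <- 1
  (m - mu) / s
}

# Lloyd iterations with farthest-point re-seeding of empty clusters.
#' @noRd
lloyd_kmeans <- function(x, k, max_iter, tol) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d <- pairwise_sqdist(x, centers)
    assign <- max.col(-d, ties.method = "first")
    newc <- centers
    for (j in seq_len(k)) {
      mem <- which(assign == j)
      if (length(mem)) {
        newc[j, ] <- colMeans(x[mem, , drop = FALSE])
      } else {
        # farthest point from its own centroid re-seeds the empty cluster
        far <- which.max(d[cbind(seq_len(n), assign)])
        newc[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    shift <- max(rowSums((newc - centers)^2))
    centers <- newc
    if (shift < tol) break
  }
  d <- pairwise_sqdist(x, centers)
  max.col(-d, ties.method = "first")
}

#' @noRd
pairwise_sqdist <- function(x, c) {
  # ||x||^2 - 2 x c' + ||c||^2
  xx <- rowSums(x^2)
  cc <- rowSums(c^2)
  d <- outer(xx, cc, "+") - 2 * tcrossprod(x, c)
  d[d < 0] <- 0
  d
}

#' Write a cluster assignment as a two-column TSV
#' @param cl a `ClusterAssignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cl, path) {
  write_tsv_atomic(as.data.frame(cl), path,
                   header = output_header(attr(cl, "seed")))
}
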