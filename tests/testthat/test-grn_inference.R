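make_planted_expr <- function(n_samples, seed) {
  # target y mirrors regulator R1; R2..R5 are independent noise
  withr::with_seed(seed, {
    vals <- matrix(rlnorm(6 * n_samples, log(10), 0.4), 6,
                   dimnames = list(c("y", paste0("R", 1:5)), NULL))
    vals["y", ] <- vals["R1", ] * exp(rnorm(n_samples, 0, 0.1))
    colnames(vals) <- paste0("s", seq_len(n_samples))
    meta <- data.frame(sample_id = colnames(vals), cell_type = "QC",
                       replicate = seq_len(n_samples))
    expression_matrix(vals, meta)
  })
}

test_that("tree-ensemble importances recover a planted regulator", {
  hits <- vapply(1:30, function(s) {
    em <- make_planted_expr(20, seed = s)
    w <- importance_scores("y", paste0("R", 1:5), em, n_trees = 200, seed = s)
    names(which.max(w)) == "R1" && w[["R1"]] > max(w[-1])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  em <- make_planted_expr(10, seed = 1)
  em$values["y", ] <- 5  # constant target
  expect_equal(unname(importance_scores("y", paste0("R", 1:5), em, 100, 1)),
               rep(0, 5))
  em2 <- make_planted_expr(10, seed = 2)
  w1 <- importance_scores("y", "R1", em2, 100, 1)
  expect_equal(unname(w1), 1)
  expect_error(importance_scores("R1", c("R1", "R2"), em2), "must not")
  expect_error(importance_scores("y", "R1",
    subset_expression(em2, sample_ids = c("s1", "s2"))), "3 samples")
})

test_that("trimming keeps ceiling(trim_factor x nTF) edges with lexicographic ties", {
  net <- grn_network(rep("A", 10), paste0("T", 1:10), weight = 10:1)
  expect_equal(nrow(trim_edges(net, n_tf = 1, trim_factor = 5)), 5)
  expect_equal(trim_edges(net, 1, 5)$target, paste0("T", 1:5))
  small <- grn_network(rep("A", 3), paste0("T", 1:3), weight = 1)
  expect_equal(nrow(trim_edges(small, n_tf = 2, trim_factor = 5)), 3)
  # ties at the cutoff resolved by (regulator, target) order
  tie <- grn_network(c("B", "A", "A"), c("x", "z", "y"), weight = c(1, 1, 1))
  kept <- trim_edges(tie, n_tf = 1, trim_factor = 2)
  expect_equal(paste(kept$regulator, kept$target), c("A y", "A z"))
  # monotone in n_tf
  for (ntf in 1:5)
    expect_lte(nrow(trim_edges(net, ntf, 2)), nrow(trim_edges(net, ntf * 2, 2)))
})

test_that("consensus retains edges at or above the appearance fraction", {
  mk <- function(edges) grn_network(edges, rep("T", length(edges)))
  # edge A->T in 34/100 networks, B->T in 44/100
  nets <- lapply(1:100, function(i)
    mk(c(if (i <= 34) "A", if (i <= 44) "B", "C")))
  cons <- consensus_network(nets, maxprop = 1 / 3)
  expect_setequal(cons$regulator, c("A", "B", "C"))
  expect_equal(cons$support[cons$regulator == "A"], 0.34)
  expect_equal(cons$support[cons$regulator == "C"], 1)
  cons45 <- consensus_network(nets, maxprop = 0.45)
  expect_false("B" %in% cons45$regulator)   # 0.44 < 0.45
  expect_false("A" %in% cons45$regulator)
  # boundary: support exactly equal to maxprop is retained
  nets10 <- lapply(1:10, function(i) mk(c(if (i <= 3) "A", "C")))
  expect_true("A" %in% consensus_network(nets10, maxprop = 0.3)$regulator)
  # monotone: raising maxprop never adds edges
  rnets <- lapply(1:20, function(s) random_network(8, 0.2, seed = s))
  prev <- Inf
  for (mp in c(0.1, 0.25, 0.5, 0.75, 1)) {
    n_now <- nrow(consensus_network(rnets, mp))
    expect_lte(n_now, prev)
    prev <- n_now
  }
  expect_error(consensus_network(list()), "empty")
})

test_that("single-network inference plants edges intra-cluster from TFs only", {
  em <- make_planted_expr(12, seed = 3)
  cl <- data.frame(gene_id = rownames(em$values),
                   cluster = c(0L, 0L, 0L, 1L, 1L, 1L))
  class(cl) <- c("ClusterAssignment", "data.frame")
  attr(cl, "k") <- 2L
  cfg <- inference_config(n_trees = 200, seed = 1)
  net <- infer_single_network(em, tf_ids = c("R1", "R2"), cl, cfg)
  expect_true("R1" %in% net$regulator[net$target == "y"])
  # all edges intra-cluster and TF-rooted
  expect_true(all(net$regulator %in% c("R1", "R2")))
  expect_true(all(net$target %in% c("y", "R1", "R2")))
  # separated singleton clusters give no edges; no TFs give no edges
  cl$cluster <- 0:5
  expect_equal(nrow(infer_single_network(em, c("R1", "R2"), cl, cfg)), 0)
  cl$cluster <- c(0L, 0L, 0L, 1L, 1L, 1L)
  expect_equal(nrow(infer_single_network(em, character(0), cl, cfg)), 0)
})

test_that("the consensus pipeline is deterministic and degenerates correctly at numiter 1", {
  truth <- make_truth(n_genes = 20, n_edges = 6, seed = 41)
  ds <- expression_from_truth(truth, n_replicates = 4, seed = 42)
  cfg <- inference_config(numiter = 3, n_trees = 50, maxprop = 1 / 3, seed = 7)
  n1 <- run_rtpstar(ds$expr, truth$tf_ids, cfg, ds$enrichment)
  n2 <- run_rtpstar(ds$expr, truth$tf_ids, cfg, ds$enrichment)
  expect_identical(n1, n2)
  cfg1 <- inference_config(numiter = 1, n_trees = 50, seed = 7)
  s1 <- run_rtpstar(ds$expr, truth$tf_ids, cfg1, ds$enrichment)
  if (nrow(s1)) expect_true(all(s1$support == 1))
})

test_that("time-point networks are built per time point and labeled by co-enrichment", {
  genes <- c("A", "B", "C", "D")
  tps <- c(96, 104, 112)
  vals <- withr::with_seed(9, {
    v <- matrix(rlnorm(4 * 12, log(10), 0.3), 4, dimnames = list(genes, NULL))
    # dependence B ~ A present at every time point (stable planted edge)
    v["B", ] <- v["A", ] * exp(rnorm(12, 0, 0.05))
    v
  })
  meta <- data.frame(sample_id = paste0("t", rep(tps, each = 4), "_r", 1:4),
                     cell_type = "SCN", replicate = rep(1:4, 3),
                     time_hours = rep(tps, each = 4))
  colnames(vals) <- meta$sample_id
  em <- expression_matrix(vals, meta)
  cfg <- inference_config(numiter = 4, n_trees = 100, maxprop = 0.45, k = 2, seed = 3)
  et <- structure(data.frame(gene_id = genes, stringsAsFactors = FALSE),
                  class = c("EnrichmentTable", "data.frame"))
  et$enriched_cells <- list(c("QC", "Xyl"), c("QC", "Xyl"), "CEI", "CEI")
  nets <- run_timepoint_networks(em, tf_ids = c("A", "C"), cfg, enrichment = et)
  expect_length(nets, 3)
  expect_named(nets, c("96", "104", "112"))
  ab <- nets[["96"]][nets[["96"]]$regulator == "A" & nets[["96"]]$target == "B", ]
  expect_gte(nrow(ab), 2)                     # one row per co-enriched cell
  expect_setequal(ab$cell_type, c("QC", "Xyl"))
  # a time point with too few replicates is skipped with a warning
  em2 <- subset_expression(em, sample_ids = meta$sample_id[-(1:2)])
  expect_warning(n2 <- run_timepoint_networks(em2, c("A", "C"), cfg),
                 "skipped")
  expect_length(n2, 2)
})
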