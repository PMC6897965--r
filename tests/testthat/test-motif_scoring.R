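test_that("canonical patterns are counted once with all participants credited", {
  ffl <- grn_network(c("A", "A", "B"), c("B", "C", "C"))
  cm <- count_motifs(ffl)
  expect_equal(unname(cm[, "feed_forward"]), c(1L, 1L, 1L))
  expect_equal(sum(cm[, colnames(cm) != "feed_forward"]), 0L)
  expect_equal(attr(cm, "totals")[["feed_forward"]], 1L)

  cyc <- grn_network(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(attr(count_motifs(cyc), "totals")[["feedback"]], 1L)

  bifan <- grn_network(c("A", "A", "B", "B"), c("C", "D", "C", "D"))
  expect_equal(attr(count_motifs(bifan), "totals")[["bi_fan"]], 1L)

  empty <- count_motifs(grn_network(), genes = c("x", "y"))
  expect_true(all(empty == 0))
})

test_that("counts match brute-force enumeration on random graphs", {
  cat_pat <- motif_catalog()
  for (s in 1:12) {
    net <- random_network(n_nodes = withr::with_seed(s, sample(6:10, 1)),
                          p = 0.2, seed = 1000 + s)
    cm <- count_motifs(net)
    for (mn in names(cat_pat)) {
      oracle <- brute_motif_counts(net, cat_pat[[mn]])
      expect_equal(attr(cm, "totals")[[mn]], oracle$total,
                   info = sprintf("seed %d motif %s", s, mn))
      expect_equal(unname(cm[names(oracle$per), mn]), unname(oracle$per),
                   info = sprintf("seed %d motif %s per-gene", s, mn))
    }
  }
})

test_that("counts are relabeling-invariant and monotone under edge addition", {
  net <- random_network(9, 0.25, seed = 77)
  cm <- count_motifs(net)
  for (s in 1:5) {
    nodes <- sort(unique(c(net$regulator, net$target)))
    relab <- setNames(withr::with_seed(s, sample(sprintf("h%02d", seq_along(nodes)))),
                      nodes)
    net2 <- grn_network(unname(relab[net$regulator]), unname(relab[net$target]))
    cm2 <- count_motifs(net2)
    expect_equal(unname(cm2[relab[rownames(cm)], ]), unname(cm[, ]))
  }
  # add edges one at a time: no gene's count may decrease
  pairs <- expand.grid(r = rownames(cm), t = rownames(cm), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$t, ]
  have <- paste(net$regulator, net$target)
  new <- pairs[!paste(pairs$r, pairs$t) %in% have, ][1:5, ]
  cur <- net
  prev <- cm
  for (i in seq_len(nrow(new))) {
    cur <- as_grn_network(rbind(as.data.frame(cur),
      data.frame(regulator = new$r[i], target = new$t[i], weight = 1,
                 sign = 0L, cell_type = NA_character_, support = 1)))
    now <- count_motifs(cur)
    expect_true(all(now[rownames(prev), ] >= prev))
    prev <- now
  }
})

test_that("NMS normalizes per motif to [0,1] and sums across motifs", {
  counts <- matrix(0L, 3, 5,
                   dimnames = list(c("g1", "g2", "g3"),
                                   names(motif_catalog())))
  counts["g1", 1] <- 4L; counts["g2", 1] <- 2L
  class(counts) <- c("MotifCountTable", class(counts))
  sc <- nms_scores(counts)
  expect_equal(sc$nms[sc$gene_id == "g1"], 1.0)
  expect_equal(sc$nms[sc$gene_id == "g2"], 0.5)
  expect_equal(sc$nms[sc$gene_id == "g3"], 0)
  # gene with the max count in every motif scores the number of motifs
  counts[] <- 1L; counts["g1", ] <- 7L
  expect_equal(nms_scores(counts)$nms[1], 5)
  # scale-free per motif: scaling one motif's counts leaves its scores alone
  counts2 <- counts; counts2[, 2] <- counts2[, 2] * 13L
  expect_equal(nms_scores(counts2)[, 3], nms_scores(counts)[, 3])
})

test_that("motif enrichment compares against size-matched random graphs", {
  ffl <- grn_network(c("A", "A", "B"), c("B", "C", "C"))
  res <- motif_enrichment(ffl, n_random = 200, seed = 4)
  row <- res[res$motif == "feed_forward", ]
  expect_equal(row$observed_total, 1)
  # G(3, 3): 6 of the 20 possible arc sets form an FFL, so p is near 0.3
  expect_lt(row$empirical_p, 0.5)
  expect_gt(row$null_mean, 0.1)
  # motifs absent from observed and nulls: p = 1, z undefined
  bf <- res[res$motif == "bi_fan", ]
  expect_equal(bf$empirical_p, 1)
  expect_true(is.na(bf$z))
  expect_warning(motif_enrichment(ffl, n_random = 5, seed = 1), "unstable")
})

test_that("degree stats satisfy the handshake identity", {
  hub <- grn_network(rep("H", 5), paste0("t", 1:5))
  ds <- degree_stats(hub, genes = c("H", paste0("t", 1:5), "iso"))
  expect_equal(ds$outdegree[ds$gene_id == "H"], 5L)
  expect_equal(ds$indegree[ds$gene_id == "iso"], 0L)
  expect_equal(ds$outdegree[ds$gene_id == "iso"], 0L)
  for (s in 1:5) {
    net <- random_network(10, 0.2, seed = s)
    d <- degree_stats(net)
    m <- nrow(unique(net[, c("regulator", "target")]))
    expect_equal(sum(d$indegree), m)
    expect_equal(sum(d$outdegree), m)
  }
})

test_that("edge validation fractions follow the knockout-consistency rules", {
  pred <- grn_network(rep("TCX2", 4), paste0("t", 1:4),
                      sign = c(1L, -1L, 0L, 1L),
                      cell_type = c("QC", "QC", "Xyl", "CEI"))
  de <- data.frame(gene_id = c("t1", "t2", "t3", "t2"),
                   cell_type = c("QC", "QC", "CEI", "Xyl"),
                   is_de = TRUE,
                   direction = c(-1, -1, 1, 1))
  res <- score_edge_validation(pred, de, "TCX2")
  expect_equal(res$frac_de, 0.75)             # t1,t2,t3 DE anywhere; t4 not
  expect_equal(res$frac_correct_cell, 0.5)    # t1@QC, t2@QC
  # among correct-cell signed edges: t1 (+1, down) consistent; t2 (-1, down) not
  expect_equal(res$frac_correct_sign, 0.5)
  # no signed edges: fraction undefined
  pred0 <- pred; pred0$sign <- 0L
  expect_true(is.na(score_edge_validation(pred0, de, "TCX2")$frac_correct_sign))
  # perfect predictions
  de2 <- data.frame(gene_id = paste0("t", 1:4),
                    cell_type = c("QC", "QC", "Xyl", "CEI"),
                    is_de = TRUE, direction = c(-1, 1, -1, -1))
  expect_equal(unlist(score_edge_validation(pred, de2, "TCX2")[1:3]),
               c(frac_de = 1, frac_correct_cell = 1, frac_correct_sign = 1))
  expect_error(score_edge_validation(pred, de, "nope"), "focal gene")
})
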