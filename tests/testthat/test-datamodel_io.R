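test_that("expression matrices validate and round-trip through TSV", {
  vals <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), cell_type = c("QC", "NSC"),
                     replicate = 1L)
  em <- expression_matrix(vals, meta)
  expect_true(all(em$values == 0))

  vals[2, 1] <- -1
  expect_error(expression_matrix(vals, meta), "non-negative")

  dup <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(expression_matrix(dup, meta), "duplicate")

  expect_error(expression_matrix(matrix(1, 2, 2,
    dimnames = list(c("a", "b"), NULL)), meta[1, ]), "do not match")

  truth <- make_truth(seed = 11)
  ds <- expression_from_truth(truth, n_replicates = 3, seed = 12)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_expression(ds$expr, f1, f2)
  back <- read_expression(f1, f2)
  expect_equal(back$values, ds$expr$values, tolerance = 1e-12)
  expect_equal(back$samples$cell_type, ds$expr$samples$cell_type)
})

test_that("enrichment classification applies the q/fold-change gate and the multi-cell rule", {
  cells <- c("QC", "CEI", "CSC", "EpiLRC", "Xyl", "Phlo", "NSC")
  mk <- function(gene_means) {
    # 2 replicates per cell type, exactly at the stated means
    vals <- do.call(cbind, lapply(cells, function(ct)
      cbind(gene_means[, ct], gene_means[, ct])))
    colnames(vals) <- paste0(rep(cells, each = 2), "_r", 1:2)
    meta <- data.frame(sample_id = colnames(vals),
                       cell_type = rep(cells, each = 2),
                       replicate = rep(1:2, 7))
    expression_matrix(vals, meta)
  }
  means <- rbind(
    ubi5 = c(100, 100, 100, 100, 100, 10, 10),  # high in 5 of 6
    gated = c(100, 100, 100, 100, 100, 10, 10), # same shape, fails q gate
    equal = c(50, 50, 50, 50, 50, 50, 10),      # equally expressed everywhere
    single = c(80, 5, 5, 5, 5, 5, 10))          # one dominant cell
  colnames(means) <- cells
  rownames(means) <- c("ubi5", "gated", "equal", "single")
  de <- data.frame(gene_id = rownames(means),
                   q_value = c(0.01, 0.5, 0.01, 0.01),
                   fc_vs_control = c(3, 3, 4, 4))
  et <- classify_enrichment(mk(means), de)

  expect_equal(et$n_enriched[et$gene_id == "ubi5"], 5L)
  expect_equal(et$ubiquity_class[et$gene_id == "ubi5"], "ubiquitous")
  expect_equal(et$ubiquity_class[et$gene_id == "gated"], "not_enriched")
  expect_equal(sort(et$enriched_cells[[which(et$gene_id == "equal")]]),
               sort(setdiff(cells, "NSC")))
  expect_equal(et$enriched_cells[[which(et$gene_id == "single")]], "QC")
  expect_equal(et$ubiquity_class[et$gene_id == "single"], "specific")

  # partition is exhaustive and exclusive
  expect_true(all(et$ubiquity_class %in%
                    c("ubiquitous", "specific", "not_enriched")))
  expect_true(all((et$n_enriched >= 4) == (et$ubiquity_class == "ubiquitous")))
  expect_true(all((et$n_enriched == 0) == (et$ubiquity_class == "not_enriched")))

  # invariant to gene row order
  shuffle <- c(3, 1, 4, 2)
  et2 <- classify_enrichment(mk(means[shuffle, ]), de[shuffle, ])
  expect_equal(et2$ubiquity_class[match(et$gene_id, et2$gene_id)],
               et$ubiquity_class)

  expect_error(classify_enrichment(mk(means), de, control = "missing"),
               "control")
})

test_that("network writing round-trips (tsv) and maps signs to SIF relations", {
  f <- tempfile(fileext = ".tsv")
  write_network(grn_network(), f)
  txt <- readLines(f)
  expect_match(txt[2], "^regulator\ttarget")
  expect_length(txt, 2)  # header comment + column header only

  net <- random_network(12, 0.5, seed = 21)
  net$sign <- withr::with_seed(1, sample(c(-1L, 0L, 1L), nrow(net), TRUE))
  net$support <- round(withr::with_seed(2, runif(nrow(net))), 6)
  net$cell_type <- "QC"
  expect_gte(nrow(net), 50)
  write_network(net, f)
  back <- read_network(f)
  expect_equal(as.data.frame(back), as.data.frame(net), tolerance = 1e-9)

  sf <- tempfile(fileext = ".sif")
  write_network(grn_network("A", "B", weight = 0.7, sign = -1L,
                            cell_type = "QC", support = 0.5), sf, dialect = "sif")
  expect_equal(readLines(sf), "A represses B")

  expect_error(grn_network("A", "A"), "self-edges")
})
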