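test_that("an unregulated species follows the closed-form relaxation", {
  spec <- build_model(list(grn_network(), grn_network(), grn_network()),
                      cells = "QC",
                      species = data.frame(gene = "TCX2", cell = "QC"))
  p <- default_parameters(spec, beta = 4, delta = 0.2, x0 = 0)
  tg <- seq(96, 120, by = 0.5)
  closed <- (4 / 0.2) * (1 - exp(-0.2 * (tg - 96)))
  for (eng in c("compiled", "desolve")) {
    tr <- simulate_model(spec, p, tg, engine = eng)
    rel <- abs(tr$values[1, -1] - closed[-1]) / closed[-1]
    expect_lt(max(rel), 1e-5)
  }
  # long-run level approaches beta/delta; out-of-span grids are rejected
  tr <- simulate_model(spec, p, c(96, 120))
  expect_equal(unname(tr$values[1, 2]), 20 * (1 - exp(-0.2 * 24)),
               tolerance = 1e-5)
  expect_error(simulate_model(spec, p, c(96, 200)), "window span")
})

test_that("pure diffusion conserves mass and equilibrates to the mean", {
  mob <- data.frame(gene = "WOX5", from = c("QC", "Xyl"), to = c("Xyl", "QC"),
                    D = 0.3)
  spec <- build_model(list(grn_network()), cells = c("QC", "Xyl"),
                      windows = c(96, 144), mobility = mob,
                      species = data.frame(gene = "WOX5",
                                           cell = c("QC", "Xyl")))
  p <- default_parameters(spec, beta = 0, delta = 0, x0 = c(10, 2))
  tr <- simulate_model(spec, p, seq(96, 144, by = 2))
  expect_lt(max(abs(colSums(tr$values) - 12)), 1e-8)
  expect_equal(unname(tr$values[, ncol(tr$values)]), c(6, 6), tolerance = 1e-5)
  # mobility between non-adjacent cells is rejected
  adj <- data.frame(from = "QC", to = "CEI")
  expect_error(build_model(list(grn_network()), cells = c("QC", "Xyl", "CEI"),
                           windows = c(96, 144), adjacency = adj, mobility = mob,
                           species = data.frame(gene = "WOX5",
                                                cell = c("QC", "Xyl"))),
               "non-adjacent")
})

test_that("regulation terms behave as Hill activation/repression with window rewiring", {
  # unsigned edge acts as activation: identical to the explicitly signed model
  netu <- grn_network("A", "B", sign = 0L, cell_type = "QC")
  neta <- grn_network("A", "B", sign = 1L, cell_type = "QC")
  netr <- grn_network("A", "B", sign = -1L, cell_type = "QC")
  su <- build_model(list(netu), cells = "QC", windows = c(96, 120))
  sa <- build_model(list(neta), cells = "QC", windows = c(96, 120))
  p <- default_parameters(su, beta = c(5, 8), delta = 0.2, K = 8, x0 = c(20, 1))
  tg <- seq(96, 120, by = 1)
  expect_equal(simulate_model(su, p, tg)$values,
               simulate_model(sa, p, tg)$values, tolerance = 1e-10)

  # a saturated repressor shuts production off: target decays toward 0
  sr <- build_model(list(netr), cells = "QC", windows = c(96, 160))
  pr <- default_parameters(sr, beta = c(50, 8), delta = c(0.01, 0.3),
                           K = 0.5, h = 2, x0 = c(5000, 10))
  trr <- simulate_model(sr, pr, seq(96, 160, by = 4))
  expect_lt(trr$values["B@QC", ncol(trr$values)], 0.01)

  # production is monotone in an activator's level
  base <- simulate_model(sa, p, c(96, 96.5))$values["B@QC", 2]
  p_hi <- p; p_hi$x0["A@QC"] <- 40
  hi <- simulate_model(sa, p_hi, c(96, 96.5))$values["B@QC", 2]
  expect_gt(hi, base)

  # rewiring at a window boundary changes the dynamics but not the state:
  # with A settling near 4 and K = 2, activation holds B high and the
  # repression window pulls it down
  s2 <- build_model(list(neta, netr), cells = "QC", windows = c(96, 108, 120))
  p2 <- default_parameters(s2, beta = c(2, 4), delta = 0.5, K = 2,
                           x0 = c(10, 1))
  tg2 <- sort(c(seq(96, 120, by = 0.25), 108.01))
  tr2 <- simulate_model(s2, p2, tg2)
  b <- tr2$values["B@QC", ]
  i_bound <- which(tg2 == 108)
  expect_lt(abs(b[i_bound + 1] - b[i_bound]), 0.05)       # continuity at 108
  expect_gt(b[i_bound], b[length(b)])                     # repression window falls
  # engines agree across windows
  tr2d <- simulate_model(s2, p2, tg2, engine = "desolve")
  expect_lt(max(abs(tr2$values - tr2d$values)), 1e-3)
})

test_that("the residual is the sum of squared differences at observed times", {
  fx <- fit_fixture()
  obs <- list(time = fx$t_grid, values = fx$clean)
  expect_equal(model_residual(fx$truth, fx$spec, obs), 0, tolerance = 1e-8)
  obs$values[2, 5] <- obs$values[2, 5] + 2
  expect_equal(model_residual(fx$truth, fx$spec, obs), 4, tolerance = 1e-5)
  for (s in 1:3) {
    noisy <- noisy_obs(fx, 0.2, seed = s)
    sim <- simulate_model(fx$spec, fx$truth, fx$t_grid)$values
    expect_equal(model_residual(fx$truth, fx$spec, noisy),
                 sum((sim[rownames(noisy$values), ] - noisy$values)^2),
                 tolerance = 1e-8)
  }
  expect_error(model_residual(fx$truth, fx$spec,
    list(time = 96, values = matrix(1, 1, 1, dimnames = list("zz", NULL)))),
    "not in the model")
})

test_that("parameter vectorization round-trips and validates", {
  fx <- fit_fixture()
  v <- params_to_vector(fx$truth)
  p2 <- vector_to_params(v, default_parameters(fx$spec))
  expect_equal(params_to_vector(p2), v)
  expect_error(vector_to_params(c(beta.nope = 1), fx$truth), "unknown")
  expect_error(default_parameters(fx$spec, delta = -1), "delta")
})

test_that("division-timing calls follow the 1.5-fold rule on window boundaries", {
  tr <- structure(list(
    time = c(96, 104, 112, 120),
    values = matrix(c(10, 10, 16, 16,    # 1.6x increase mid-course
                      10, 10, 10, 4,     # 2.5x terminal drop
                      10, 9, 10, 8,      # at most 1.4x changes
                      10, 10, 10, 10),   # constant
                    4, 4, byrow = TRUE,
                    dimnames = list(paste0("X@", c("QC", "Xyl", "CEI", "CSC")),
                                    NULL)),
    species = paste0("X@", c("QC", "Xyl", "CEI", "CSC"))),
    class = "Trajectory")
  calls <- classify_division(tr, "X", windows = c(96, 104, 112, 120))
  expect_equal(calls$call[calls$cell == "QC"], "increase")
  expect_equal(calls$call[calls$cell == "Xyl"], "division")
  expect_equal(calls$call[calls$cell == "CEI"], "quiescent")
  expect_equal(calls$call[calls$cell == "CSC"], "quiescent")
  expect_equal(calls$last_fc[calls$cell == "Xyl"], 2.5)
  expect_error(classify_division(tr, "nope", c(96, 104, 112, 120)), "absent")
})

test_that("fitting degenerates to scored LHS initials at budget 0 and is seeded", {
  fx <- fit_fixture()
  obs <- noisy_obs(fx, 0.1, seed = 5)
  f0a <- fit_model(fx$spec, obs, fx$bounds, fx$truth, n_starts = 12,
                   budget = 0, seed = 9)
  f0b <- fit_model(fx$spec, obs, fx$bounds, fx$truth, n_starts = 12,
                   budget = 0, seed = 9)
  expect_identical(f0a, f0b)
  # budget 0: finals are the LHS initials, so best = mean of the 10 best
  inits <- withr::with_seed(9, lhs::randomLHS(12, length(fx$free)))
  lo <- vapply(fx$bounds, `[`, 0, 1); hi <- vapply(fx$bounds, `[`, 0, 2)
  inits <- sweep(sweep(inits, 2, hi - lo, "*"), 2, lo, "+")
  errs <- apply(inits, 1, function(v)
    model_residual(vector_to_params(setNames(v, fx$free), fx$truth),
                   fx$spec, obs))
  top <- order(errs)[1:10]
  expect_equal(unname(f0a$best_parameters),
               unname(colMeans(inits[top, ])), tolerance = 1e-10)
  expect_error(fit_model(fx$spec, obs, fx$bounds, fx$truth, n_starts = 5),
               "average the top")
  f1 <- fit_model(fx$spec, obs, fx$bounds, fx$truth, n_starts = 10,
                  budget = 40, seed = 3)
  f2 <- fit_model(fx$spec, obs, fx$bounds, fx$truth, n_starts = 10,
                  budget = 40, seed = 3)
  expect_identical(f1, f2)
})
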