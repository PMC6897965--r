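# Independent oracles used across tests. These deliberately share no code
# with the implementation paths they check.

# all permutations of a vector (tiny n only)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms_of(v[-i]), function(p) c(v[i], p))))
}

# brute-force motif counting: enumerate every ordered node tuple, check all
# pattern edges, and divide by the pattern's automorphism count
brute_motif_counts <- function(net, pat) {
  pairs <- unique(net[, c("regulator", "target")])
  nodes <- sort(unique(c(pairs$regulator, pairs$target)))
  es <- paste(pairs$regulator, pairs$target)
  k <- pat$n
  per <- setNames(rep(0, length(nodes)), nodes)
  if (length(nodes) < k) return(list(total = 0, per = per))
  pk <- paste(pat$edges[, 1], pat$edges[, 2])
  aut <- sum(vapply(perms_of(seq_len(k)), function(pm)
    setequal(paste(pm[pat$edges[, 1]], pm[pat$edges[, 2]]), pk), logical(1)))
  total <- 0
  for (cs in combn(nodes, k, simplify = FALSE)) {
    for (pm in perms_of(cs)) {
      if (all(paste(pm[pat$edges[, 1]], pm[pat$edges[, 2]]) %in% es)) {
        total <- total + 1
        per[cs] <- per[cs] + 1
      }
    }
  }
  list(total = total / aut, per = per / aut)
}

# average precision of a ranked edge list against a set of true edges
ap_score <- function(ranked_keys, truth_keys) {
  if (!length(ranked_keys)) return(0)
  hit <- ranked_keys %in% truth_keys
  sum(cumsum(hit) / seq_along(hit) * hit) / length(truth_keys)
}

# rank the (regulator, target) pairs of a combined consensus network by
# support then weight, collapsing per-cell duplicates
rank_consensus_pairs <- function(net) {
  if (!nrow(net)) return(character(0))
  df <- unique(as.data.frame(net)[, c("regulator", "target", "weight", "support")])
  agg <- aggregate(cbind(weight, support) ~ regulator + target, df, max)
  agg <- agg[order(-agg$support, -agg$weight, agg$regulator, agg$target), ]
  paste(agg$regulator, agg$target)
}

# random directed network for property tests
random_network <- function(n_nodes, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(runif(n_nodes^2) < p, n_nodes)
    diag(adj) <- FALSE
    idx <- which(adj, arr.ind = TRUE)
    nm <- sprintf("g%02d", seq_len(n_nodes))
    grn_network(nm[idx[, 1]], nm[idx[, 2]],
                weight = runif(nrow(idx)))
  })
}

# the three-gene cascade used in the fitting and sensitivity tests:
# G1 -> G2 (activation), G2 -| G3 (repression), one cell, three windows
fit_fixture <- function() {
  net <- grn_network(c("G1", "G2"), c("G2", "G3"), sign = c(1L, -1L),
                     cell_type = "QC")
  spec <- build_model(list(net, net, net), cells = "QC")
  truth <- default_parameters(spec, beta = c(6, 8, 5),
                              delta = c(0.15, 0.25, 0.2),
                              K = c(25, 10), h = 2, x0 = c(20, 2, 1))
  free <- c(paste0("beta.", spec$species$species_id),
            paste0("delta.", spec$species$species_id))
  bounds <- c(rep(list(c(0.5, 30)), 3), rep(list(c(0.05, 0.8)), 3))
  names(bounds) <- free
  t_grid <- seq(96, 120, by = 1)
  clean <- simulate_model(spec, truth, t_grid)$values
  list(spec = spec, truth = truth, free = free, bounds = bounds,
       t_grid = t_grid, clean = clean,
       truth_vec = params_to_vector(truth)[free])
}

# multiplicative log-normal observation noise, mean one
noisy_obs <- function(fx, sd, seed) {
  vals <- fx$clean * withr::with_seed(seed,
    exp(matrix(rnorm(length(fx$clean), -sd^2 / 2, sd), nrow(fx$clean))))
  list(time = fx$t_grid, values = vals)
}
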