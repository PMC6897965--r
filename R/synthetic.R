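#' Default synthetic stem-cell system layout
#' @return Character vector of the six stem-cell types.
#' @export
default_cells <- function() c("QC", "CEI", "CSC", "EpiLRC", "Xyl", "Phlo")

#' Plant a ground-truth signed network with known enrichment and kinetics
#'
#' Generates a TF-rooted signed directed network over `n_genes` genes,
#' optionally seeding known counts of motif instances, assigns every gene
#' to one or more of six stem-cell types (plus a non-stem control), and
#' draws kinetic parameters for the dynamics generators. Deterministic
#' given `seed`.
#'
#' @param n_genes number of genes (default 50).
#' @param tf_frac fraction of genes annotated as transcription factors
#'   (default 0.2).
#' @param n_edges number of planted edges, `<= tf_count * (n_genes - 1)`
#'   (default 15).
#' @param motif_seeding optional named integer vector (names from
#'   [motif_catalog()]) of motif instances to plant on dedicated genes;
#'   their edges count toward `n_edges`.
#' @param seed RNG seed.
#' @param cells stem-cell type names (default [default_cells()]).
#' @param control control cell-type name.
#' @return A `SyntheticTruth`: list with `network` (signed
#'   `grn_network`), `tf_ids`, `cells`, `control`, `enrichment_plan`
#'   (named list gene -> enriched cells), `base_mean`, kinetic parameters
#'   (`delta`, `beta`, per-edge `K`, `h`) and `seed`.
#' @export
make_truth <- function(n_genes = 50L, tf_frac = 0.2, n_edges = 15L,
                       motif_seeding = NULL, seed = 1L,
                       cells = default_cells(), control = "NSC") {
  n_tf <- max(1L, round(tf_frac * n_genes))
  if (n_edges > n_tf * (n_genes - 1L))
    stopf("n_edges (%d) exceeds tf_count x (n_genes - 1) = %d",
          n_edges, n_tf * (n_genes - 1L))
  genes <- sprintf("G%03d", seq_len(n_genes))
  tfs <- genes[seq_len(n_tf)]
  with_seed(seed, {
    edges <- data.frame(regulator = character(0), target = character(0),
                        stringsAsFactors = FALSE)
    used_for_motifs <- character(0)
    if (!is.null(motif_seeding)) {
      cat_pat <- motif_catalog()
      bad <- setdiff(names(motif_seeding), names(cat_pat))
      if (length(bad)) stopf("unknown motif(s): %s", paste(bad, collapse = ", "))
      free_tf <- tfs
      free_other <- setdiff(genes, tfs)
      for (mn in names(motif_seeding)) {
        p <- cat_pat[[mn]]
        sources <- sort(unique(p$edges[, 1]))  # roles with outgoing edges
        sinks <- setdiff(seq_len(p$n), sources)
        for (inst in seq_len(motif_seeding[[mn]])) {
          if (length(free_tf) < length(sources) ||
              length(free_other) + length(free_tf) - length(sources) < length(sinks))
            stopf("not enough genes to plant the requested motifs")
          node_map <- integer(p$n)
          node_map[sources] <- match(free_tf[seq_along(sources)], genes)
          free_tf <- free_tf[-seq_along(sources)]
          pool <- c(free_other, free_tf)
          node_map[sinks] <- match(pool[seq_along(sinks)], genes)
          free_other <- setdiff(free_other, pool[seq_along(sinks)])
          free_tf <- setdiff(free_tf, pool[seq_along(sinks)])
          edges <- rbind(edges, data.frame(
            regulator = genes[node_map[p$edges[, 1]]],
            target = genes[node_map[p$edges[, 2]]],
            stringsAsFactors = FALSE))
          used_for_motifs <- c(used_for_motifs, genes[node_map])
        }
      }
    }
    if (anyDuplicated(paste(edges$regulator, edges$target)))
      edges <- unique(edges)
    n_extra <- n_edges - nrow(edges)
    if (n_extra < 0) n_extra <- 0L
    all_pairs <- expand.grid(regulator = tfs, target = genes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$regulator != all_pairs$target, ]
    key <- paste(all_pairs$regulator, all_pairs$target)
    key_used <- paste(edges$regulator, edges$target)
    avail <- all_pairs[!key %in% key_used, ]
    # avoid wiring extra random edges into the motif-planted genes so the
    # constructed instance counts stay exact
    pref <- avail[!(avail$regulator %in% used_for_motifs |
                    avail$target %in% used_for_motifs), ]
    if (nrow(pref) >= n_extra) avail <- pref
    if (n_extra > 0) {
      # draw targets without replacement where possible, so random edges
      # regulate distinct genes (multi-regulation comes from motif seeding)
      pick <- avail[sample.int(nrow(avail)), ]
      first <- !duplicated(pick$target) & !pick$target %in% edges$target
      pick <- rbind(pick[first, ], pick[!first, ])[seq_len(n_extra), ]
      edges <- rbind(edges, pick)
    }
    net <- grn_network(edges$regulator, edges$target, weight = 1,
                       sign = sample(c(-1L, 1L), nrow(edges), replace = TRUE))

    # enrichment plan: sizes mixing specific (1-3) and ubiquitous (4-6)
    sizes <- sample(1:6, n_genes, replace = TRUE,
                    prob = c(0.35, 0.15, 0.12, 0.14, 0.12, 0.12))
    plan <- lapply(sizes, function(s) sample(cells, s))
    names(plan) <- genes
    # a target inherits its regulator's enrichment pattern: regulatory pairs
    # are co-expressed across cell types (which also guarantees the shared
    # enriched cell every planted edge needs)
    for (i in seq_len(nrow(net))) {
      r <- net$regulator[i]; t <- net$target[i]
      plan[[t]] <- plan[[r]]
    }
    base_mean <- setNames(rlnorm(n_genes, log(8), 0.4), genes)
    delta <- setNames(runif(n_genes, 0.12, 0.3), genes)
    beta <- delta * 2 * base_mean
    ekey <- paste0(net$regulator, ">", net$target)
    K <- setNames(base_mean[net$regulator], ekey)
    h <- setNames(rep(2, nrow(net)), ekey)
    structure(list(network = net, tf_ids = tfs, cells = cells,
                   control = control, enrichment_plan = plan,
                   base_mean = base_mean, delta = delta, beta = beta,
                   K = K, h = h, enriched_multiplier = 4,
                   noise_sd = 0.25, seed = as.integer(seed)),
              class = "SyntheticTruth")
  })
}

#' Replicate expression data realizing a planted truth
#'
#' Per cell type, a gene's mean is its baseline times the enrichment
#' multiplier in its planted cells; the control cell stays at baseline.
#' Regulator-target dependencies are embedded by propagating each
#' regulator's replicate-level multiplicative fluctuation into its targets
#' (raised to the power of the edge sign), and multiplicative log-normal noise
#' (mean-one) is applied throughout, emulating positive, heteroskedastic
#' FPKM data.
#'
#' @param truth a `SyntheticTruth`.
#' @param n_replicates replicates per cell type (default 4).
#' @param noise_sd standard deviation of log-normal noise on the log scale
#'   (default: the truth's 0.25).
#' @param seed RNG seed.
#' @return list with `expr` (an `ExpressionMatrix` over all stem cells
#'   plus the control), `de` (per-gene q-value and fold-change vs control)
#'   and `enrichment` (the [classify_enrichment()] table of the generated
#'   data).
#' @export
expression_from_truth <- function(truth, n_replicates = 4L,
                                  noise_sd = truth$noise_sd, seed = 1L) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  genes <- names(truth$base_mean)
  all_cells <- c(truth$cells, truth$control)
  mult <- truth$enriched_multiplier
  means <- vapply(all_cells, function(ct) {
    enr <- vapply(truth$enrichment_plan[genes], function(s) ct %in% s, logical(1))
    truth$base_mean * ifelse(enr & ct != truth$control, mult, 1)
  }, numeric(length(genes)))
  rownames(means) <- genes

  samples <- expand.grid(replicate = seq_len(n_replicates), cell_type = all_cells,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample_id <- paste0(samples$cell_type, "_r", samples$replicate)
  samples$time_hours <- NA_real_
  vals <- with_seed(seed, {
    lnoise <- function(n) exp(rnorm(n, -noise_sd^2 / 2, noise_sd))
    f_own <- matrix(lnoise(length(genes) * nrow(samples)),
                    length(genes), nrow(samples), dimnames = list(genes, NULL))
    f <- f_own
    net <- truth$network
    for (i in seq_len(nrow(net))) {   # one-level propagation of regulator noise
      r <- net$regulator[i]; t <- net$target[i]
      s_i <- net$sign[i]
      f[t, ] <- f[t, ] * f_own[r, ]^s_i * exp(noise_sd^2 * (s_i - 1) / 2)
    }
    v <- means[, samples$cell_type, drop = FALSE] * f
    colnames(v) <- samples$sample_id
    v
  })
  expr <- expression_matrix(vals, samples[, c("sample_id", "cell_type",
                                              "replicate", "time_hours")])
  de <- data.frame(gene_id = genes, q_value = 0.001,
                   fc_vs_control = mult, stringsAsFactors = FALSE)
  et <- classify_enrichment(expr, de, control = truth$control)
  list(expr = expr, de = de, enrichment = et)
}

#' Time course realizing a planted truth's kinetics
#'
#' Source genes (no incoming planted edge) follow smooth seeded log
#' random-walk trajectories; regulated genes integrate Hill kinetics at
#' the truth's parameters, driven by those sources, so planted signs
#' manifest as lag-1 dependencies. Sampled every 8 h from 4 to 6 days by
#' default, with mean-one multiplicative log-normal replicate noise.
#'
#' @param truth a `SyntheticTruth`.
#' @param t_points sampling times in hours (default `seq(96, 144, by 8)`,
#'   seven points).
#' @param n_replicates biological replicates (default 3).
#' @param noise_sd log-scale noise sd (default 0.1; 0 = noiseless).
#' @param seed RNG seed.
#' @return A [time_course()] whose `values` are replicate means and whose
#'   `replicates` array holds the individual replicates.
#' @export
timecourse_from_truth <- function(truth, t_points = seq(96, 144, by = 8),
                                  n_replicates = 3L, noise_sd = 0.1, seed = 1L) {
  genes <- names(truth$base_mean)
  net <- truth$network
  targets <- unique(net$target)
  sources <- setdiff(genes, targets)
  with_seed(seed, {
    # smooth driven paths for source genes: mean-reverting walk on the log
    # scale, so regulators keep crossing their half-saturation level and
    # downstream Hill terms stay responsive
    knot_t <- seq(min(t_points) - 8, max(t_points) + 8, by = 8)
    src_paths <- lapply(sources, function(g) {
      mu <- log(truth$base_mean[g])
      lv <- numeric(length(knot_t))
      lv[1] <- mu + rnorm(1, 0, 0.35)
      for (i in seq_along(knot_t)[-1])
        lv[i] <- lv[i - 1] + 0.2 * (mu - lv[i - 1]) + rnorm(1, 0, 0.35)
      approxfun(knot_t, exp(lv), rule = 2)
    })
    names(src_paths) <- sources

    if (length(targets)) {
      ed <- net[net$target %in% targets, , drop = FALSE]
      tg_idx <- match(ed$target, targets)
      reg_is_src <- ed$regulator %in% sources
      reg_tg_idx <- match(ed$regulator, targets)
      ekey <- paste0(ed$regulator, ">", ed$target)
      K <- as.numeric(truth$K[ekey]); h <- as.numeric(truth$h[ekey])
      beta <- as.numeric(truth$beta[targets])
      delta <- as.numeric(truth$delta[targets])
      rhs <- function(t, y, parms) {
        y <- pmax(y, 0)
        xr <- numeric(nrow(ed))
        xr[reg_is_src] <- vapply(which(reg_is_src),
                                 function(i) src_paths[[ed$regulator[i]]](t), 0)
        xr[!reg_is_src] <- y[reg_tg_idx[!reg_is_src]]
        term <- ifelse(ed$sign >= 0, xr^h / (K^h + xr^h), K^h / (K^h + xr^h))
        prod <- rep(1, length(y))
        for (i in seq_along(term)) prod[tg_idx[i]] <- prod[tg_idx[i]] * term[i]
        list(beta * prod - delta * y)
      }
      y0 <- pmax(truth$base_mean[targets], 1e-3)
      sol <- deSolve::ode(y = as.numeric(y0),
                          times = unique(c(min(t_points) - 8, t_points)),
                          func = rhs, parms = NULL, method = "lsoda",
                          rtol = 1e-6, atol = 1e-9)
      tgt_vals <- t(sol[match(t_points, sol[, 1]), -1, drop = FALSE])
      rownames(tgt_vals) <- targets
    } else tgt_vals <- NULL

    src_vals <- t(vapply(sources, function(g)
      vapply(t_points, src_paths[[g]], 0), numeric(length(t_points))))
    clean <- rbind(src_vals, tgt_vals)[genes, , drop = FALSE]
    clean <- pmax(clean, 0)

    reps <- array(NA_real_, c(length(genes), length(t_points), n_replicates),
                  dimnames = list(genes, NULL, NULL))
    for (r in seq_len(n_replicates)) {
      noise <- if (noise_sd > 0)
        exp(matrix(rnorm(length(clean), -noise_sd^2 / 2, noise_sd), nrow(clean)))
      else 1
      reps[, , r] <- clean * noise
    }
    time_course(reps, t_points)
  })
}
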