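#' Total-order Sobol indices of a scalar function
#'
#' Saltelli-scheme estimation with the Jansen total-order estimator:
#' two base matrices A and B of `n` Latin-hypercube rows each, plus one
#' hybrid matrix AB_i per factor; `S_T_i = mean((f(A) - f(AB_i))^2) /
#' (2 Var(f))`. An inert control factor that never enters `fn` is appended
#' so downstream significance testing can compare every factor against
#' pure estimation noise. Replicate estimates (>= 30) are computed on
#' disjoint row blocks of the design, giving independent draws of each
#' index's sampling distribution.
#'
#' @param fn vectorized scalar function: takes a numeric matrix with one
#'   column per factor (named as `ranges`) and returns one value per row.
#' @param ranges named list mapping factor name to `c(lower, upper)`.
#' @param n base sample size (rows of A and B); must be >= 8.
#' @param seed RNG seed.
#' @param n_rep number of block-replicate estimates (default 32).
#' @param control_name name of the appended inert factor.
#' @return A `SobolResult`: list with `S_T` (named, includes the control),
#'   `replicates` (n_rep x factors matrix), `n`, `control`.
#' @export
sobol_indices <- function(fn, ranges, n = 1024L, seed = 1L, n_rep = 32L,
                          control_name = "control") {
  if (n < 8) stopf("base sample size must be >= 8")
  if (n_rep < 30) stopf("need >= 30 replicate estimates")
  k <- length(ranges)
  if (control_name %in% names(ranges)) stopf("'%s' collides with a factor name",
                                             control_name)
  lo <- vapply(ranges, `[`, 0, 1); hi <- vapply(ranges, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi))) stopf("ranges must be finite")
  kk <- k + 1L  # + control column
  scale_mat <- function(u) {
    x <- sweep(sweep(u[, seq_len(k), drop = FALSE], 2, hi - lo, "*"), 2, lo, "+")
    colnames(x) <- names(ranges)
    x
  }
  AB <- with_seed(seed, list(A = lhs::randomLHS(n, kk), B = lhs::randomLHS(n, kk)))
  evals <- matrix(NA_real_, n, kk + 2L)  # fA, fB, fAB_1..fAB_kk
  evals[, 1] <- fn(scale_mat(AB$A))
  evals[, 2] <- fn(scale_mat(AB$B))
  for (i in seq_len(kk)) {
    M <- AB$A
    M[, i] <- AB$B[, i]
    evals[, 2L + i] <- fn(scale_mat(M))
  }
  fac_names <- c(names(ranges), control_name)
  est <- function(rows) {
    v <- var(c(evals[rows, 1], evals[rows, 2]))
    if (v <= 0) return(setNames(rep(0, kk), fac_names))
    setNames(vapply(seq_len(kk), function(i)
      mean((evals[rows, 1] - evals[rows, 2L + i])^2) / (2 * v), 0), fac_names)
  }
  S_T <- est(seq_len(n))
  blocks <- split(seq_len(n), cut(seq_len(n), n_rep, labels = FALSE))
  reps <- t(vapply(blocks, est, numeric(kk)))
  structure(list(S_T = S_T, replicates = reps, n = n, control = control_name,
                 ranges = ranges),
            class = "SobolResult")
}

#' Total-order Sobol sensitivity of the ODE model
#'
#' Wraps [sobol_indices()] around the model: each factor is a vectorized
#' parameter name (see [params_to_vector()]), the scalar output is either
#' the residual against observations or a named species' value at the end
#' of the time span.
#'
#' @param spec an `OdeModelSpec`.
#' @param param_ranges named list parameter name -> `c(lower, upper)`.
#' @param base_sample_n base sample size (>= 8).
#' @param seed RNG seed.
#' @param base_params `ParameterSet` for parameters not varied.
#' @param output `"residual"` (needs `observed`) or `"species_end"`
#'   (needs `species`).
#' @param observed observations as in [model_residual()].
#' @param species species id whose end-time value is the output.
#' @param t_end end time (default: last window boundary).
#' @param n_rep replicate estimates (default 32).
#' @param engine integration engine.
#' @return A `SobolResult` including the inert control factor.
#' @export
sobol_total <- function(spec, param_ranges, base_sample_n = 1024L, seed = 1L,
                        base_params = default_parameters(spec),
                        output = c("residual", "species_end"),
                        observed = NULL, species = NULL, t_end = NULL,
                        n_rep = 32L, engine = "compiled") {
  output <- match.arg(output)
  if (output == "residual" && is.null(observed))
    stopf("output 'residual' needs observations")
  if (output == "species_end" && is.null(species))
    stopf("output 'species_end' needs a species id")
  t_end <- t_end %||% spec$windows[length(spec$windows)]
  fn <- function(X) {
    vapply(seq_len(nrow(X)), function(r) {
      p <- vector_to_params(setNames(as.numeric(X[r, ]), colnames(X)), base_params)
      if (output == "residual") model_residual(p, spec, observed, engine = engine)
      else simulate_model(spec, p, t_end, engine = engine)$values[species, 1]
    }, numeric(1))
  }
  sobol_indices(fn, param_ranges, n = base_sample_n, seed = seed, n_rep = n_rep)
}

#' Parameters with total Sobol index significantly above the control
#'
#' Each factor's replicate total-index estimates are compared with the
#' inert control's by a one-sided two-sample Wilcoxon rank test, with Holm
#' correction across factors (a conservative stand-in for the Steel-Dwass
#' many-to-one procedure).
#'
#' @param res a `SobolResult`.
#' @param alpha familywise significance level (default 0.05).
#' @return Character vector of significant factor names; attribute
#'   `table` holds the per-factor statistics.
#' @export
sensitivity_significance <- function(res, alpha = 0.05) {
  if (!inherits(res, "SobolResult")) stopf("need a SobolResult")
  if (is.null(res$control) || !res$control %in% colnames(res$replicates))
    stopf("control factor missing from the Sobol result")
  ctrl <- res$replicates[, res$control]
  params <- setdiff(colnames(res$replicates), res$control)
  p <- vapply(params, function(nm) {
    x <- res$replicates[, nm]
    if (all(x == ctrl)) return(1)
    pv <- suppressWarnings(
      wilcox.test(x, ctrl, alternative = "greater", exact = FALSE)$p.value)
    if (!is.finite(pv)) 1 else pv
  }, numeric(1))
  p_adj <- p.adjust(p, method = "holm")
  tab <- data.frame(parameter = params, S_T = res$S_T[params],
                    p_value = p, p_holm = p_adj,
                    significant = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(params[p_adj < alpha], table = tab)
}
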