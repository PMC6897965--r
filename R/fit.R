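#' Fit free model parameters by LHS multistart + simulated annealing
#'
#' Latin hypercube sampling draws `n_starts` initial vectors over the
#' bounds; each start is refined by simulated annealing under a fixed
#' objective-evaluation budget (geometric cooling; proposals perturb all
#' coordinates with a step that shrinks with the temperature, reflected
#' into the bounds). The returned best parameters are the elementwise mean
#' of the 10 lowest-error finals, following the multistart-averaging
#' protocol. Deterministic given `seed`.
#'
#' @param spec an `OdeModelSpec`.
#' @param observed observations as in [model_residual()].
#' @param bounds named list mapping vectorized parameter names (see
#'   [params_to_vector()]) to `c(lower, upper)`; only these parameters are
#'   searched, everything else stays at `base_params`.
#' @param base_params `ParameterSet` supplying the fixed parameters
#'   (measured diffusion coefficients, oligomeric states, ...).
#' @param n_starts number of LHS starts (default 50; must be >= 10 so the
#'   top 10 can be averaged).
#' @param budget objective evaluations per start spent in annealing
#'   (default 2000; 0 skips annealing and scores the initials only).
#' @param seed RNG seed.
#' @param top_n finals averaged (default 10).
#' @param engine integration engine.
#' @return A `FitResult`: list with `best_parameters` (named vector),
#'   `best_params_set` (full `ParameterSet`), `per_start` data.frame
#'   (start, seed, error, one column per free parameter) sorted by error,
#'   and `residual_definition`.
#' @export
fit_model <- function(spec, observed, bounds, base_params,
                      n_starts = 50L, budget = 2000L, seed = 1L,
                      top_n = 10L, engine = "compiled") {
  if (n_starts < top_n)
    stopf("n_starts (%d) must be >= %d to average the top %d",
          n_starts, top_n, top_n)
  free <- names(bounds)
  lo <- vapply(bounds, `[`, 0, 1)
  hi <- vapply(bounds, `[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stopf("bounds must be finite with upper > lower")
  objective <- function(v) {
    model_residual(vector_to_params(setNames(v, free), base_params),
                   spec, observed, engine = engine)
  }
  inits <- with_seed(seed, lhs::randomLHS(n_starts, length(free)))
  inits <- sweep(sweep(inits, 2, hi - lo, "*"), 2, lo, "+")

  finals <- matrix(NA_real_, n_starts, length(free),
                   dimnames = list(NULL, free))
  errors <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    res <- with_seed(child_seed(seed, s),
                     anneal(objective, inits[s, ], lo, hi, budget))
    finals[s, ] <- res$par
    errors[s] <- res$value
  }
  ord <- order(errors)
  top <- ord[seq_len(top_n)]
  best <- colMeans(finals[top, , drop = FALSE])
  per_start <- data.frame(start = ord, seed = child_seed(seed, ord),
                          error = errors[ord], finals[ord, , drop = FALSE],
                          check.names = FALSE)
  structure(list(
    best_parameters = best,
    best_params_set = vector_to_params(best, base_params),
    per_start = per_start,
    residual_definition = "sum of squared simulated-minus-observed differences at observed times"),
    class = "FitResult")
}

# bounded simulated annealing with geometric cooling and an evaluation
# budget, followed by a greedy polish phase; returns the best point seen.
# Moves perturb one random coordinate at a time (anisotropic residual
# surfaces are the norm for kinetic parameters).
#' @noRd
anneal <- function(objective, init, lo, hi, budget) {
  cur <- init
  f_cur <- objective(cur)
  best <- cur; f_best <- f_cur
  if (budget < 1) return(list(par = best, value = f_best))
  span <- hi - lo
  k_dim <- length(cur)
  n_sa <- floor(0.7 * budget)
  n_polish <- budget - n_sa
  # moves are proportional to the current coordinate value (rate constants
  # live on relative scales), with a floor tied to the box width
  move_sd <- function(x, j, scale) max(abs(x[j]), 0.02 * span[j]) * scale
  if (n_sa > 0) {
    t0 <- max(abs(f_cur) * 0.2, 1e-12)
    cool <- (1e-6)^(1 / n_sa)
    temp <- t0
    shrink <- (0.02 / 0.5)^(1 / n_sa)
    scale <- 0.5
    for (k in seq_len(n_sa)) {
      j <- sample.int(k_dim, 1L)
      prop <- cur
      prop[j] <- prop[j] + rnorm(1, 0, move_sd(cur, j, scale))
      if (prop[j] < lo[j]) prop[j] <- 2 * lo[j] - prop[j]
      if (prop[j] > hi[j]) prop[j] <- 2 * hi[j] - prop[j]
      prop[j] <- min(max(prop[j], lo[j]), hi[j])
      f_prop <- objective(prop)
      if (f_prop <= f_cur || runif(1) < exp(-(f_prop - f_cur) / temp)) {
        cur <- prop; f_cur <- f_prop
        if (f_cur < f_best) { best <- cur; f_best <- f_cur }
      }
      temp <- temp * cool
      scale <- scale * shrink
    }
  }
  # greedy polish around the best point with shrinking one-coordinate steps
  cur <- best; f_cur <- f_best
  if (n_polish > 0) {
    shrink <- (0.001 / 0.1)^(1 / n_polish)
    scale <- 0.1
    for (k in seq_len(n_polish)) {
      j <- sample.int(k_dim, 1L)
      prop <- cur
      prop[j] <- prop[j] + rnorm(1, 0, move_sd(cur, j, scale))
      prop[j] <- min(max(prop[j], lo[j]), hi[j])
      f_prop <- objective(prop)
      if (f_prop < f_cur) {
        cur <- prop; f_cur <- f_prop
        if (f_cur < f_best) { best <- cur; f_best <- f_cur }
      }
      scale <- scale * shrink
    }
  }
  list(par = best, value = f_best)
}
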