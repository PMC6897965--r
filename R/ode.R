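#' Build a piecewise-in-time multicellular gene-circuit model
#'
#' One state variable is created per (gene, cell) pair appearing in the
#' window networks (or given explicitly). Within each time window the
#' production of a target is its basal rate times a product of Hill terms,
#' one per incoming edge in that window's network for that cell:
#' activation `x^h / (K^h + x^h)`, repression `K^h / (K^h + x^h)`; edges
#' without a predicted sign are treated as activating. Degradation is
#' linear. Proteins listed in the mobility table move between adjacent
#' cells with rate `D * (x_src^n - x_dst^n)` added to the destination
#' cell's equation, where n is the protein's oligomeric state in the
#' source cell. The regulatory terms are rewired at each window boundary
#' while the state stays continuous.
#'
#' @param window_networks named list mapping window start (hours) to a
#'   `grn_network` whose `cell_type` labels place each edge in a cell.
#' @param cells character vector of cell types in the model.
#' @param windows strictly increasing window boundaries in hours; defaults
#'   to `c(96, 104, 112, 120)` (4 days to 5 days, every 8 h). There must
#'   be `length(windows) - 1` window networks, in order.
#' @param adjacency data.frame (`from`, `to`) of cell pairs allowed to
#'   exchange proteins; default: all pairs adjacent.
#' @param mobility data.frame (`gene`, `from`, `to`, `D`) of moving
#'   proteins with default diffusion coefficients (h^-1).
#' @param oligomer data.frame (`gene`, `cell`, `n`) of oligomeric states;
#'   unlisted pairs are monomers (n = 1).
#' @param species optional data.frame (`gene`, `cell`) of state variables;
#'   default: every (gene, cell) seen in the window networks plus mobility
#'   endpoints.
#' @return An `OdeModelSpec` list: `species` (with ids `gene@cell`),
#'   `windows`, per-window edge tables resolved to species indices,
#'   `mobility`, `edge_keys` (unique edge identities across windows) and
#'   `cells`.
#' @export
build_model <- function(window_networks, cells, windows = c(96, 104, 112, 120),
                        adjacency = NULL, mobility = NULL, oligomer = NULL,
                        species = NULL) {
  windows <- as.numeric(windows)
  if (any(diff(windows) <= 0)) stopf("window boundaries must be strictly increasing")
  n_win <- length(windows) - 1L
  if (length(window_networks) != n_win)
    stopf("need %d window networks for %d boundaries", n_win, length(windows))
  window_networks <- lapply(window_networks, validate_network)
  for (net in window_networks) {
    lab <- unique(net$cell_type[!is.na(net$cell_type)])
    if (length(setdiff(lab, cells)))
      stopf("network cell labels outside the model cells: %s",
            paste(setdiff(lab, cells), collapse = ", "))
  }

  if (is.null(species)) {
    sp <- do.call(rbind, lapply(window_networks, function(net) {
      if (!nrow(net)) return(NULL)
      ct <- ifelse(is.na(net$cell_type),
                   if (length(cells) == 1) cells else NA_character_,
                   net$cell_type)
      if (anyNA(ct)) stopf("edges need cell_type labels in a multicellular model")
      rbind(data.frame(gene = net$regulator, cell = ct, stringsAsFactors = FALSE),
            data.frame(gene = net$target, cell = ct, stringsAsFactors = FALSE))
    }))
    if (!is.null(mobility))
      sp <- rbind(sp,
                  data.frame(gene = mobility$gene, cell = mobility$from,
                             stringsAsFactors = FALSE),
                  data.frame(gene = mobility$gene, cell = mobility$to,
                             stringsAsFactors = FALSE))
    if (is.null(sp) || !nrow(sp)) stopf("model has no species")
    species <- unique(sp)
  }
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  species$species_id <- paste0(species$gene, "@", species$cell)
  species <- unique(species[, c("gene", "cell", "species_id")])
  rownames(species) <- NULL
  sp_index <- setNames(seq_len(nrow(species)), species$species_id)

  resolve <- function(net) {
    if (!nrow(net)) return(data.frame(tgt = integer(0), reg = integer(0),
                                      sign = integer(0), key = character(0)))
    ct <- ifelse(is.na(net$cell_type),
                 if (length(cells) == 1) cells else NA_character_, net$cell_type)
    tgt <- sp_index[paste0(net$target, "@", ct)]
    reg <- sp_index[paste0(net$regulator, "@", ct)]
    if (anyNA(tgt) || anyNA(reg))
      stopf("edge endpoints missing from the species list")
    data.frame(tgt = as.integer(tgt), reg = as.integer(reg),
               sign = ifelse(net$sign < 0, -1L, 1L),  # unsigned => activation
               key = paste0(net$regulator, "@", ct, ">", net$target, "@", ct),
               stringsAsFactors = FALSE)
  }
  win_edges <- lapply(window_networks, resolve)
  edge_keys <- unique(unlist(lapply(win_edges, `[[`, "key")))

  if (!is.null(mobility)) {
    mobility <- as.data.frame(mobility, stringsAsFactors = FALSE)
    if (!"D" %in% names(mobility)) mobility$D <- 0
    if (is.null(adjacency)) {
      adj_ok <- rep(TRUE, nrow(mobility))
    } else {
      akey <- c(paste(adjacency$from, adjacency$to),
                paste(adjacency$to, adjacency$from))
      adj_ok <- paste(mobility$from, mobility$to) %in% akey
    }
    if (!all(adj_ok))
      stopf("mobility between non-adjacent cells: %s",
            paste(paste(mobility$from[!adj_ok], mobility$to[!adj_ok]), collapse = ", "))
    src <- sp_index[paste0(mobility$gene, "@", mobility$from)]
    dst <- sp_index[paste0(mobility$gene, "@", mobility$to)]
    if (anyNA(src) || anyNA(dst)) stopf("mobility endpoints missing from species")
    n_ol <- rep(1, nrow(mobility))
    if (!is.null(oligomer)) {
      ok <- match(paste(mobility$gene, mobility$from),
                  paste(oligomer$gene, oligomer$cell))
      n_ol[!is.na(ok)] <- oligomer$n[ok[!is.na(ok)]]
    }
    mobility$src_idx <- as.integer(src)
    mobility$dst_idx <- as.integer(dst)
    mobility$n <- n_ol
    mobility$mob_id <- paste0(mobility$gene, ":", mobility$from, ">", mobility$to)
  } else {
    mobility <- data.frame(gene = character(0), from = character(0),
                           to = character(0), D = numeric(0),
                           src_idx = integer(0), dst_idx = integer(0),
                           n = numeric(0), mob_id = character(0),
                           stringsAsFactors = FALSE)
  }
  structure(list(species = species, cells = cells, windows = windows,
                 win_edges = win_edges, edge_keys = edge_keys,
                 mobility = mobility),
            class = "OdeModelSpec")
}

#' @export
print.OdeModelSpec <- function(x, ...) {
  cat(sprintf("OdeModelSpec: %d species (%d cells), %d windows, %d mobile links\n",
              nrow(x$species), length(x$cells), length(x$windows) - 1L,
              nrow(x$mobility)))
  invisible(x)
}

#' Default parameter set for a model
#'
#' Parameters: per species a production rate `beta` (FPKM h^-1),
#' degradation rate `delta` (h^-1, zero allowed to switch degradation
#' off) and initial condition `x0` (FPKM); per
#' unique edge a half-saturation constant `K` (FPKM) and Hill coefficient
#' `h`; per mobility row a diffusion coefficient `D` (h^-1). The
#' vectorized order (see [params_to_vector()]) is beta, delta, K, h, D,
#' x0, each block in its table's order.
#'
#' @param spec an `OdeModelSpec`.
#' @param beta,delta,K,h scalar defaults recycled over species/edges.
#' @param x0 initial conditions; default `beta/delta`.
#' @param D diffusion coefficients; default from the spec's mobility table.
#' @return A `ParameterSet` list of named numeric vectors.
#' @export
default_parameters <- function(spec, beta = 5, delta = 0.1, K = 10, h = 2,
                               x0 = NULL, D = NULL) {
  ids <- spec$species$species_id
  p <- list(
    beta = setNames(rep_len(beta, length(ids)), ids),
    delta = setNames(rep_len(delta, length(ids)), ids),
    K = setNames(rep_len(K, length(spec$edge_keys)), spec$edge_keys),
    h = setNames(rep_len(h, length(spec$edge_keys)), spec$edge_keys),
    D = setNames(D %||% spec$mobility$D, spec$mobility$mob_id),
    x0 = NULL)
  p$x0 <- if (is.null(x0)) p$beta / p$delta else setNames(rep_len(x0, length(ids)), ids)
  validate_parameters(p)
  structure(p, class = "ParameterSet")
}

#' @noRd
validate_parameters <- function(p) {
  if (any(p$beta < 0)) stopf("beta must be >= 0")
  if (any(p$delta < 0)) stopf("delta must be >= 0")
  if (any(p$K <= 0)) stopf("K must be > 0")
  if (any(p$h < 1)) stopf("Hill coefficients must be >= 1")
  if (length(p$D) && any(p$D < 0)) stopf("D must be >= 0")
  if (any(p$x0 < 0)) stopf("initial conditions must be >= 0")
  invisible(p)
}

#' Flatten a ParameterSet to a named vector (documented block order)
#' @param p a `ParameterSet`.
#' @return Named numeric vector: `beta.<sp>`, `delta.<sp>`, `K.<edge>`,
#'   `h.<edge>`, `D.<mob>`, `x0.<sp>`.
#' @export
params_to_vector <- function(p) {
  unlist(p[c("beta", "delta", "K", "h", "D", "x0")])
}

#' Rebuild a ParameterSet from a (possibly partial) named vector
#' @param v named numeric vector in [params_to_vector()] naming.
#' @param template a `ParameterSet` supplying values absent from `v`.
#' @return A `ParameterSet`.
#' @export
vector_to_params <- function(v, template) {
  p <- template
  for (block in c("beta", "delta", "K", "h", "D", "x0")) {
    pref <- paste0(block, ".")
    hit <- startsWith(names(v), pref)
    if (!any(hit)) next
    nm <- substring(names(v)[hit], nchar(pref) + 1L)
    bad <- setdiff(nm, names(p[[block]]))
    if (length(bad)) stopf("unknown parameter(s): %s",
                           paste(paste0(block, ".", bad), collapse = ", "))
    p[[block]][nm] <- as.numeric(v[hit])
  }
  validate_parameters(p)
  structure(p, class = "ParameterSet")
}

#' Simulate the model over a time grid
#'
#' Integrates window by window, carrying the state across boundaries, with
#' the compiled adaptive Runge-Kutta (Cash-Karp 4/5) engine by default or
#' `deSolve::ode` (lsoda) as a reference engine. States are clamped at
#' zero.
#'
#' @param spec an `OdeModelSpec`.
#' @param params a `ParameterSet` (see [default_parameters()]).
#' @param t_grid output times in hours, within the window span.
#' @param engine `"compiled"` (default) or `"desolve"`.
#' @param rtol,atol integration tolerances (defaults 1e-6, 1e-9).
#' @return A `Trajectory`: list with `time` and `values`
#'   (species x time matrix, rownames = species ids).
#' @export
simulate_model <- function(spec, params, t_grid = NULL,
                           engine = c("compiled", "desolve"),
                           rtol = 1e-6, atol = 1e-9) {
  engine <- match.arg(engine)
  w <- spec$windows
  if (is.null(t_grid)) t_grid <- seq(w[1], w[length(w)], length.out = 49L)
  t_grid <- sort(as.numeric(t_grid))
  if (t_grid[1] < w[1] - 1e-9 || t_grid[length(t_grid)] > w[length(w)] + 1e-9)
    stopf("t_grid must lie within the window span [%g, %g]", w[1], w[length(w)])
  ids <- spec$species$species_id
  ns <- length(ids)
  out <- matrix(NA_real_, ns, length(t_grid), dimnames = list(ids, NULL))
  state <- as.numeric(params$x0[ids])
  t_now <- w[1]
  done <- t_grid <= t_now + 1e-12
  out[, done] <- state
  for (j in seq_len(length(w) - 1L)) {
    if (all(done)) break
    t_end <- w[j + 1L]
    sel <- !done & t_grid <= t_end + 1e-12
    times <- c(t_grid[sel], t_end)   # always integrate to the boundary
    res <- integrate_window(spec, params, j, state, t_now, times, engine, rtol, atol)
    if (any(sel)) out[, which(sel)] <- res[, seq_len(sum(sel)), drop = FALSE]
    state <- res[, ncol(res)]
    t_now <- t_end
    done <- done | sel
  }
  out[out < 0] <- 0
  structure(list(time = t_grid, values = out, species = ids),
            class = "Trajectory")
}

#' @noRd
integrate_window <- function(spec, params, win, state, t0, times, engine,
                             rtol, atol) {
  ed <- spec$win_edges[[win]]
  mob <- spec$mobility
  beta <- as.numeric(params$beta)
  delta <- as.numeric(params$delta)
  K <- as.numeric(params$K[ed$key]); h <- as.numeric(params$h[ed$key])
  D <- if (nrow(mob)) as.numeric(params$D[mob$mob_id]) else numeric(0)
  if (engine == "compiled") {
    .ode_window_cpp(state, t0, times, beta, delta,
                    ed$tgt - 1L, ed$reg - 1L, as.integer(ed$sign), K, h,
                    mob$dst_idx - 1L, mob$src_idx - 1L, D, as.numeric(mob$n),
                    rtol, atol)
  } else {
    f <- function(t, y, parms) {
      y <- pmax(y, 0)
      prod <- rep(1, length(y))
      if (nrow(ed)) {
        Kh <- K^h
        xh <- y[ed$reg]^h
        term <- ifelse(ed$sign >= 0, xh / (Kh + xh), Kh / (Kh + xh))
        for (i in seq_len(nrow(ed))) prod[ed$tgt[i]] <- prod[ed$tgt[i]] * term[i]
      }
      dy <- beta * prod - delta * y
      if (nrow(mob)) {
        flux <- D * (y[mob$src_idx]^mob$n - y[mob$dst_idx]^mob$n)
        for (i in seq_len(nrow(mob)))
          dy[mob$dst_idx[i]] <- dy[mob$dst_idx[i]] + flux[i]
      }
      list(dy)
    }
    sol <- deSolve::ode(y = state, times = unique(c(t0, times)), func = f,
                        parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
    sol <- sol[match(times, sol[, 1]), -1, drop = FALSE]
    t(pmax(sol, 0))
  }
}

#' Sum-of-squares residual between simulation and observations
#'
#' @param params a `ParameterSet`.
#' @param spec an `OdeModelSpec`.
#' @param observed list with `time` (hours) and `values` (matrix observed
#'   species x time, rownames = species ids; NAs are skipped).
#' @param engine integration engine (see [simulate_model()]).
#' @return Non-negative sum of squared differences.
#' @export
model_residual <- function(params, spec, observed, engine = "compiled") {
  traj <- simulate_model(spec, params, observed$time, engine = engine)
  obs <- as.matrix(observed$values)
  miss <- setdiff(rownames(obs), spec$species$species_id)
  if (length(miss)) stopf("observed species not in the model: %s",
                          paste(miss, collapse = ", "))
  sim <- traj$values[rownames(obs), , drop = FALSE]
  sum((sim - obs)^2, na.rm = TRUE)
}

#' Call division timing from modeled expression of a focal gene
#'
#' For each cell carrying the focal gene, expression is read at every
#' window boundary and fold-changes are computed between consecutive
#' boundaries. A fold-change above `fc_threshold` in either direction is a
#' significant change; a significant decrease over the final interval is
#' called a division, otherwise any significant increase is reported as
#' `increase`, and cells with no significant change are `quiescent`
#' (stable expression).
#'
#' @param traj a `Trajectory` from [simulate_model()].
#' @param focal_gene gene whose dynamics time the division.
#' @param windows window boundaries in hours (default: the trajectory's
#'   span split as in the model, supply the spec's `windows`).
#' @param fc_threshold significance threshold on the fold-change
#'   (default 1.5).
#' @param pseudocount added when a boundary value is zero (logged).
#' @return data.frame per cell: `cell`, `call`, `max_increase_fc`,
#'   `last_fc` (final-interval fold-change, > 1 means decrease).
#' @export
classify_division <- function(traj, focal_gene, windows, fc_threshold = 1.5,
                              pseudocount = 1e-3) {
  ids <- traj$species
  hit <- startsWith(ids, paste0(focal_gene, "@"))
  if (!any(hit)) stopf("focal gene '%s' absent from the trajectory", focal_gene)
  cells <- sub(".*@", "", ids[hit])
  bounds <- windows[windows >= min(traj$time) - 1e-9 &
                    windows <= max(traj$time) + 1e-9]
  if (length(bounds) < 2) stopf("need >= 2 window boundaries inside the trajectory")
  out <- lapply(seq_along(cells), function(ci) {
    sp <- ids[hit][ci]
    v <- approx(traj$time, traj$values[sp, ], xout = bounds)$y
    if (any(v == 0)) {
      message(sprintf("classify_division: zero boundary value for %s, pseudocount %g applied",
                      sp, pseudocount))
      v <- v + pseudocount
    }
    fc <- v[-1] / v[-length(v)]
    sig_inc <- fc > fc_threshold
    sig_dec <- (1 / fc) > fc_threshold
    last <- length(fc)
    call <- if (sig_dec[last]) "division"
            else if (any(sig_inc)) "increase"
            else "quiescent"
    data.frame(cell = cells[ci], call = call,
               max_increase_fc = max(fc),
               last_fc = 1 / fc[last],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
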