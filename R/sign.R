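#' Construct a validated time course
#'
#' @param values genes x time-points matrix of non-negative expression,
#'   or a 3-d array genes x time-points x replicates.
#' @param time_points strictly increasing times in hours (>= 2 points).
#' @return A `TimeCourse`: list with `values` (replicate-mean matrix),
#'   `replicates` (the array, if given) and `time_points`.
#' @export
time_course <- function(values, time_points) {
  time_points <- as.numeric(time_points)
  if (length(time_points) < 2) stopf("a time course needs >= 2 time points")
  if (any(diff(time_points) <= 0)) stopf("time points must be strictly increasing")
  reps <- NULL
  if (length(dim(values)) == 3) {
    reps <- values
    values <- apply(values, c(1, 2), mean)
    if (!is.null(dimnames(reps)[[1]])) rownames(values) <- dimnames(reps)[[1]]
  }
  values <- as.matrix(values)
  if (ncol(values) != length(time_points))
    stopf("value columns (%d) do not match time points (%d)",
          ncol(values), length(time_points))
  if (any(values < 0)) stopf("time-course values must be non-negative")
  colnames(values) <- paste0("t", format(time_points, trim = TRUE))
  structure(list(values = values, replicates = reps, time_points = time_points),
            class = "TimeCourse")
}

#' Sign of a regulation from lagged correlation of two series
#'
#' First-order Markov reading of a time course: the Pearson correlation r
#' between the regulator at time t and the target at time t+1 over
#' consecutive pairs. Returns +1 (activation) when r > tau, -1
#' (repression) when r < -tau, 0 otherwise; zero-variance series give 0.
#'
#' @param regulator_series,target_series numeric vectors aligned on the
#'   same >= 2 time points.
#' @param tau dead-band half-width on the correlation (default 0.1).
#' @return An integer sign in `{-1, 0, 1}`.
#' @export
infer_edge_sign <- function(regulator_series, target_series, tau = 0.1) {
  n <- length(regulator_series)
  if (length(target_series) != n) stopf("series length mismatch")
  if (n < 2) stopf("need >= 2 time points")
  x <- regulator_series[-n]
  y <- target_series[-1]
  if (sd(x) == 0 || sd(y) == 0) return(0L)
  r <- cor(x, y)
  if (is.na(r)) return(0L)
  if (r > tau) 1L else if (r < -tau) -1L else 0L
}

#' Assign signs to every edge of a network from a time course
#'
#' Each edge's sign is set by [infer_edge_sign()] on the replicate-mean
#' series of its regulator and target; weights and support are untouched.
#' Edges whose endpoints are missing from the time course keep sign 0.
#'
#' @param net a `grn_network`.
#' @param tc a [time_course()].
#' @param tau dead-band passed to [infer_edge_sign()].
#' @return The network with the `sign` column filled in.
#' @export
sign_network <- function(net, tc, tau = 0.1) {
  net <- validate_network(net)
  if (!nrow(net)) return(net)
  stopifnot(inherits(tc, "TimeCourse"))
  v <- tc$values
  present <- rownames(v)
  missing <- setdiff(unique(c(net$regulator, net$target)), present)
  if (length(missing))
    message(sprintf("sign_network: %d gene(s) absent from the time course keep sign 0",
                    length(missing)))
  for (i in seq_len(nrow(net))) {
    r <- net$regulator[i]; t <- net$target[i]
    if (r %in% present && t %in% present)
      net$sign[i] <- infer_edge_sign(v[r, ], v[t, ], tau = tau)
  }
  net
}
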