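# Delay embeddings: the state of a series at time t is its d most recent
# values [x(t-d+1), ..., x(t)]; states at time t predict targets at t+1.
# With T samples this yields n = T - d usable regression rows, for
# t = d, ..., T-1 (1-based).

.embed_series <- function(x, d) {
  T <- length(x)
  n <- T - d
  if (n < 1L) stop("insufficient-data error: embedding dimension d = ", d,
                   " needs more than d + 1 = ", d + 1L, " time points, got ", T)
  idx <- outer(seq_len(n), 0:(d - 1L), `+`) # row i: x[i..i+d-1], state at t=i+d-1...
  matrix(x[idx], nrow = n, ncol = d)
}

#' Build the delay embedding of one series
#'
#' Constructs the source phase space: row k holds
#' `[x_s(t-d+1), ..., x_s(t)]` for `t = d + k - 1`, so that each state
#' precedes the one-step-ahead prediction target `x_r(t+1)`.
#'
#' @param ensemble A [ts_ensemble] or numeric matrix (series in rows).
#' @param s Source series index.
#' @param d Embedding dimension (number of lags), `1 <= d < T`.
#' @return A list of class `delay_embedding`: `states` (n x d matrix with
#'   n = T - d), `time_index` (the times t of each state row, 1-based),
#'   `source_index`, `d`, and `target_offset` (always 1).
#' @export
build_delay_embedding <- function(ensemble, s, d) {
  e <- as_ensemble(ensemble)
  stopifnot(s >= 1L, s <= nrow(e))
  d <- as.integer(d)
  if (d < 1L) stop("embedding dimension must be >= 1")
  if (d >= ncol(e)) stop("insufficient-data error: d = ", d,
                         " >= T = ", ncol(e))
  st <- .embed_series(e[s, ], d)
  structure(list(states = st,
                 time_index = seq.int(d, ncol(e) - 1L),
                 source_index = s, d = d, target_offset = 1L),
            class = "delay_embedding")
}

#' Build the conditional embedding (all series except the source)
#'
#' Stacks the delay embeddings of every series except `s`, in ascending
#' series order, into one state matrix of width `(N-1)*d`. It contains no
#' value from series `s`, and its rows are time-aligned with the paired
#' [build_delay_embedding] states.
#'
#' @inheritParams build_delay_embedding
#' @return A list of class `conditional_embedding`: `states`
#'   (n x (N-1)d), `time_index`, `excluded_index`, `d`.
#' @export
build_conditional_embedding <- function(ensemble, s, d) {
  e <- as_ensemble(ensemble)
  N <- nrow(e)
  stopifnot(N >= 2L, s >= 1L, s <= N)
  d <- as.integer(d)
  if (d < 1L) stop("embedding dimension must be >= 1")
  if (d >= ncol(e)) stop("insufficient-data error: d = ", d,
                         " >= T = ", ncol(e))
  others <- setdiff(seq_len(N), s)
  blocks <- lapply(others, function(j) .embed_series(e[j, ], d))
  structure(list(states = do.call(cbind, blocks),
                 time_index = seq.int(d, ncol(e) - 1L),
                 excluded_index = s, d = d),
            class = "conditional_embedding")
}

# One-step-ahead targets aligned with the embedding rows: x_r(t+1) for
# t in time_index.
embedding_targets <- function(ensemble, r, embedding) {
  e <- as_ensemble(ensemble)
  e[r, embedding$time_index + 1L]
}

# Cao's E(d) statistics for d = 1..d_upper: mean expansion ratio of
# nearest-neighbor distances when going from a d- to a (d+1)-dimensional
# embedding. Windows share their start times (the classical convention:
# dimension d+1 appends the next later sample), and squared distances are
# grown incrementally, one coordinate at a time. Nearest neighbors use the
# Euclidean metric with self-matches and zero-distance matches excluded,
# ties broken by lowest index.
.cao_E_curve <- function(x, d_upper) {
  T <- length(x)
  starts <- 1L:(T - d_upper - 1L) # window start times shared by all dims
  m <- length(starts)
  D2 <- matrix(0, m, m)
  E <- numeric(d_upper)
  nn_idx <- NULL; nn_d2 <- NULL
  for (d in seq_len(d_upper + 1L)) {
    v <- x[starts + (d - 1L)]
    D2 <- D2 + outer(v, v, `-`)^2
    if (d >= 2L) {
      # D2 is now at dimension d; expand the dim-(d-1) neighbor pairs
      ratios <- sqrt(D2[cbind(seq_len(m), nn_idx)] / nn_d2)
      ratios <- ratios[is.finite(ratios) & is.finite(nn_d2)]
      if (length(ratios) == 0L)
        stop("degenerate-input error: all nearest-neighbor distances are zero (constant series?)")
      E[d - 1L] <- mean(ratios)
    }
    if (d <= d_upper) {
      W <- D2
      diag(W) <- Inf
      W[W == 0] <- Inf # need strictly positive denominators
      nn_idx <- max.col(-W, ties.method = "first")
      nn_d2 <- W[cbind(seq_len(m), nn_idx)]
    }
  }
  E
}

#' Choose an embedding dimension with Cao's method
#'
#' Computes Cao's E1(d) = E(d+1)/E(d), where E(d) is the average one-step
#' expansion of nearest-neighbor distances between embeddings of dimension
#' d and d+1, and returns the smallest d at which E1 saturates: either
#' `|E1(d) - 1| < threshold` or `|E1(d+1) - E1(d)| < threshold`. If no
#' saturation occurs up to `d_max`, `d_max` is returned with a warning.
#'
#' @param series Numeric vector (one time series).
#' @param d_max Largest dimension considered (default 10).
#' @param threshold Saturation tolerance on E1 (default 0.05).
#' @param full If `TRUE`, return a list with the E1 curve as well.
#' @return The selected dimension (integer), or if `full = TRUE` a list
#'   with elements `d`, `E1` (length `d_max`), and `saturated`.
#' @export
cao_embedding_dimension <- function(series, d_max = 10L, threshold = 0.05,
                                    full = FALSE) {
  series <- as.numeric(series)
  d_max <- as.integer(d_max)
  if (d_max < 2L) stop("d_max must be >= 2")
  if (length(series) < d_max + 4L)
    stop("insufficient-data error: need T > d_max + 2; got T = ",
         length(series))
  if (diff(range(series)) == 0)
    stop("degenerate-input error: constant series")
  E <- .cao_E_curve(series, d_max + 1L) # E(d) for d = 1..d_max+1
  E1 <- E[-1L] / E[-length(E)] # E1(d) = E(d+1)/E(d), d = 1..d_max
  sat <- abs(E1 - 1) < threshold |
    c(abs(diff(E1)), Inf) < threshold
  d_sel <- if (any(sat)) which(sat)[1L] else {
    warning("Cao's E1 did not saturate below d_max = ", d_max,
            "; using d_max")
    d_max
  }
  if (full) list(d = as.integer(d_sel), E1 = E1, saturated = any(sat))
  else as.integer(d_sel)
}

#' Choose one global embedding dimension for an ensemble
#'
#' Runs Cao's method on each series and takes the median across series,
#' rounded up, so one d serves the whole ensemble.
#'
#' @inheritParams build_delay_embedding
#' @inheritParams cao_embedding_dimension
#' @return Integer embedding dimension.
#' @export
choose_embedding_dimension <- function(ensemble, d_max = 10L,
                                       threshold = 0.05) {
  e <- as_ensemble(ensemble)
  d_max <- min(as.integer(d_max), ncol(e) - 3L)
  if (d_max < 2L) d_max <- 2L
  ds <- vapply(seq_len(nrow(e)), function(s)
    cao_embedding_dimension(e[s, ], d_max = d_max, threshold = threshold),
    integer(1))
  as.integer(ceiling(stats::median(ds)))
}
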