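# Benchmark generators with known ground-truth directed graphs. Every
# simulator returns list(ensemble = ts_ensemble, truth = N x N binary
# matrix with truth[s, r] = 1 iff series s drives series r). Trajectories
# that leave their valid range are re-initialized from a derived seed
# (re-draw rather than clip, so the invariant distribution is untouched).

.retry_sim <- function(seed, max_attempts, stepfun) {
  for (attempt in seq_len(max_attempts)) {
    out <- withr::with_seed(as.integer(seed) + (attempt - 1L) * 7919L,
                            stepfun())
    if (!is.null(out)) return(out)
  }
  stop("simulation failed to stay in bounds after ", max_attempts,
       " re-initializations")
}

#' Simulate the two-species coupled logistic map
#'
#' Iterates
#' `x1(t+1) = x1(t) [r1 - r1 x1(t) - gamma12 x2(t)]`,
#' `x2(t+1) = x2(t) [r2 - r2 x2(t) - gamma21 x1(t)]`
#' from Uniform(0, 1) initial conditions, discarding the burn-in. The
#' defaults (`gamma21 = 0.32`, `gamma12 = 0`) give the unidirectional
#' system where species 1 drives species 2.
#'
#' @param r1,r2 Logistic growth rates (defaults 3.7 and 3.8).
#' @param gamma12 Coupling of x2 into x1's equation (default 0).
#' @param gamma21 Coupling of x1 into x2's equation (default 0.32).
#' @param T Emitted series length (default 500).
#' @param burn_in Initial points discarded (default 50).
#' @param seed Integer seed.
#' @param max_attempts Re-initializations allowed if the trajectory leaves
#'   \[0, 1\] or diverges (default 100).
#' @param init Optional fixed initial state (length-2 vector); `NULL`
#'   (default) draws Uniform(0, 1) initial conditions.
#' @return List: `ensemble` (2 x T [ts_ensemble]), `truth` (2 x 2 binary,
#'   `truth[s, r] = 1` iff s drives r), `config`.
#' @export
simulate_two_logistic <- function(r1 = 3.7, r2 = 3.8,
                                  gamma12 = 0, gamma21 = 0.32,
                                  T = 500L, burn_in = 50L, seed = 1L,
                                  max_attempts = 100L, init = NULL) {
  total <- T + burn_in
  sim <- .retry_sim(seed, max_attempts, function() {
    x <- matrix(NA_real_, 2L, total)
    x[, 1L] <- if (is.null(init)) stats::runif(2L) else init
    for (t in seq_len(total - 1L)) {
      x[1L, t + 1L] <- x[1L, t] * (r1 - r1 * x[1L, t] - gamma12 * x[2L, t])
      x[2L, t + 1L] <- x[2L, t] * (r2 - r2 * x[2L, t] - gamma21 * x[1L, t])
      if (!all(is.finite(x[, t + 1L])) || any(x[, t + 1L] < 0) ||
          any(x[, t + 1L] > 1)) return(NULL)
    }
    x
  })
  truth <- matrix(0L, 2L, 2L)
  if (gamma21 != 0) truth[1L, 2L] <- 1L
  if (gamma12 != 0) truth[2L, 1L] <- 1L
  list(ensemble = ts_ensemble(sim[, (burn_in + 1L):total, drop = FALSE]),
       truth = truth,
       config = list(r1 = r1, r2 = r2, gamma12 = gamma12,
                     gamma21 = gamma21, T = T, burn_in = burn_in,
                     seed = seed))
}

#' Simulate a three-node fan-out or fan-in logistic-map motif
#'
#' Extends the two-species coupling template to three nodes: every node j
#' updates as `x_j(t+1) = x_j(t) [r_j - r_j x_j(t) - sum_k gamma x_k(t)]`
#' over its incoming true edges, with per-node rates (3.7, 3.8, 3.85) and
#' coupling 0.32 on true edges. Fan-out: node 1 drives nodes 2 and 3
#' (confounder motif). Fan-in: nodes 1 and 2 both drive node 3 (collider,
#' v-structure). The exact published motif equations are not available;
#' this is a documented reconstruction built from the same coupled-map
#' template as the two-species system.
#'
#' @param kind `"out"` or `"in"`.
#' @param coupling Coupling strength on true edges (default 0.32).
#' @param rates Per-node logistic rates.
#' @inheritParams simulate_two_logistic
#' @return List: `ensemble` (3 x T), `truth` (3 x 3), `config`.
#' @export
simulate_fan_motif <- function(kind = c("out", "in"), T = 500L,
                               coupling = 0.32,
                               rates = c(3.7, 3.8, 3.85),
                               burn_in = 50L, seed = 1L,
                               max_attempts = 100L, init = NULL) {
  kind <- match.arg(kind)
  truth <- matrix(0L, 3L, 3L)
  if (kind == "out") truth[1L, c(2L, 3L)] <- 1L else truth[c(1L, 2L), 3L] <- 1L
  G <- coupling * t(truth) # G[j, k]: weight of x_k in x_j's update
  total <- T + burn_in
  sim <- .retry_sim(seed, max_attempts, function() {
    x <- matrix(NA_real_, 3L, total)
    x[, 1L] <- if (is.null(init)) stats::runif(3L) else init
    for (t in seq_len(total - 1L)) {
      drive <- drop(G %*% x[, t])
      x[, t + 1L] <- x[, t] * (rates - rates * x[, t] - drive)
      if (!all(is.finite(x[, t + 1L])) || any(x[, t + 1L] < 0) ||
          any(x[, t + 1L] > 1)) return(NULL)
    }
    x
  })
  list(ensemble = ts_ensemble(sim[, (burn_in + 1L):total, drop = FALSE]),
       truth = truth,
       config = list(kind = kind, coupling = coupling, rates = rates,
                     T = T, burn_in = burn_in, seed = seed))
}

#' Simulate the five-node autoregressive benchmark
#'
#' The canonical five-node system of the kernel-Granger benchmark suite:
#' a damped stochastic oscillator `x1` drives `x2`, `x3` and `x4` at lags
#' 2-3, and `x4`/`x5` are mutually coupled, with unit-variance Gaussian
#' innovations:
#' \preformatted{
#' x1(t) = 0.95*sqrt(2) x1(t-1) - 0.9025 x1(t-2) + w1
#' x2(t) = 0.5 x1(t-2)                           + w2
#' x3(t) = -0.4 x1(t-3)                          + w3
#' x4(t) = -0.5 x1(t-2) + 0.25*sqrt(2) (x4(t-1) + x5(t-1)) + w4
#' x5(t) = -0.25*sqrt(2) x4(t-1) + 0.25*sqrt(2) x5(t-1)    + w5
#' }
#' The nonlinear variant replaces the drive of `x1` into `x4` by its
#' square. Ground truth: edges 1->2, 1->3, 1->4, 4->5, 5->4. This is a
#' documented reconstruction of the benchmark (its published source is the
#' kernel-Granger toolbox); all coefficients are exposed in `config`.
#'
#' @param kind `"linear"` or `"nonlinear"`.
#' @inheritParams simulate_two_logistic
#' @return List: `ensemble` (5 x T), `truth` (5 x 5), `config`.
#' @export
simulate_five_node <- function(kind = c("linear", "nonlinear"), T = 500L,
                               burn_in = 50L, seed = 1L) {
  kind <- match.arg(kind)
  total <- T + burn_in + 3L
  x <- withr::with_seed(as.integer(seed), {
    w <- matrix(stats::rnorm(5L * total), 5L, total)
    x <- matrix(0, 5L, total)
    x[, 1:3] <- w[, 1:3]
    s2 <- sqrt(2)
    for (t in 4:total) {
      x[1L, t] <- 0.95 * s2 * x[1L, t - 1L] - 0.9025 * x[1L, t - 2L] + w[1L, t]
      x[2L, t] <- 0.5 * x[1L, t - 2L] + w[2L, t]
      x[3L, t] <- -0.4 * x[1L, t - 3L] + w[3L, t]
      drive <- if (kind == "linear") x[1L, t - 2L] else x[1L, t - 2L]^2
      x[4L, t] <- -0.5 * drive + 0.25 * s2 * (x[4L, t - 1L] + x[5L, t - 1L]) +
        w[4L, t]
      x[5L, t] <- -0.25 * s2 * x[4L, t - 1L] + 0.25 * s2 * x[5L, t - 1L] +
        w[5L, t]
    }
    x
  })
  if (!all(is.finite(x))) stop("five-node simulation diverged")
  truth <- matrix(0L, 5L, 5L)
  truth[1L, c(2L, 3L, 4L)] <- 1L
  truth[4L, 5L] <- 1L
  truth[5L, 4L] <- 1L
  list(ensemble = ts_ensemble(x[, (total - T + 1L):total, drop = FALSE]),
       truth = truth,
       config = list(kind = kind, T = T, burn_in = burn_in, seed = seed))
}

#' Directed or undirected Zachary coupling pattern
#'
#' Builds the 34 x 34 binary influence pattern on the karate-club skeleton:
#' the undirected variant keeps all 78 edges in both directions (156 ones);
#' the directed variant orients each edge by a fair coin flip and then
#' upgrades `n_bidirectional` distinct randomly chosen edges to run both
#' ways (78 + n ones).
#'
#' @param directed Logical.
#' @param n_bidirectional Number of edges made bidirectional in the
#'   directed variant (default 5).
#' @param seed Integer seed for the random orientation.
#' @return Binary 34 x 34 matrix `P`, `P[s, r] = 1` iff node s influences
#'   node r.
#' @export
zachary_graph <- function(directed = TRUE, n_bidirectional = 5L, seed = 1L) {
  el <- zachary_edges()
  if (n_bidirectional > nrow(el)) stop("n_bidirectional exceeds 78 edges")
  P <- matrix(0L, 34L, 34L)
  if (!directed) {
    P[el] <- 1L
    P[el[, c(2L, 1L)]] <- 1L
    return(P)
  }
  withr::with_seed(as.integer(seed), {
    flip <- stats::runif(nrow(el)) < 0.5
    oriented <- el
    oriented[flip, ] <- el[flip, c(2L, 1L)]
    P[oriented] <- 1L
    both <- sample.int(nrow(el), n_bidirectional)
    P[el[both, , drop = FALSE]] <- 1L
    P[el[both, c(2L, 1L), drop = FALSE]] <- 1L
  })
  P
}

#' Simulate the 34-node Zachary coupled-map network
#'
#' Iterates the noisy coupled quadratic map
#' `x_i(t) = (1 - sum_j c_ij)(1 - a x_i(t-1)^2) +
#'   sum_j c_ij (1 - a x_j(t-1)^2) + s tau_i(t)`
#' on a given influence pattern, with `c_ij = c` wherever node j influences
#' node i, standard Gaussian `tau`, Uniform(-1, 1) initial conditions and a
#' discarded burn-in.
#'
#' @param pattern Binary 34 x 34 influence pattern from [zachary_graph]
#'   (`pattern[s, r] = 1` iff s influences r).
#' @param a Map nonlinearity (default 1.8).
#' @param s_noise Noise scale (default 0.01).
#' @param coupling Coupling strength c: 0.05 for the directed variant,
#'   0.025 for the undirected one.
#' @param divergence_bound Re-initialize if any |x| exceeds this.
#' @inheritParams simulate_two_logistic
#' @return List: `ensemble` (34 x T), `truth` (= `pattern`), `config`.
#' @export
simulate_zachary <- function(pattern, a = 1.8, s_noise = 0.01,
                             coupling = 0.05, T = 500L, burn_in = 50L,
                             seed = 1L, divergence_bound = 1e6,
                             max_attempts = 100L, init = NULL) {
  stopifnot(is.matrix(pattern), all(dim(pattern) == 34L))
  C <- coupling * t(pattern) # C[i, j]: influence of j on i
  budget <- 1 - rowSums(C)
  if (any(budget <= 0))
    stop("row coupling budget non-positive: reduce the coupling strength")
  n_nodes <- 34L
  total <- T + burn_in
  sim <- .retry_sim(seed, max_attempts, function() {
    x <- matrix(NA_real_, n_nodes, total)
    x[, 1L] <- if (is.null(init)) stats::runif(n_nodes, -1, 1) else init
    noise <- matrix(stats::rnorm(n_nodes * total), n_nodes, total)
    for (t in 2:total) {
      q <- 1 - a * x[, t - 1L]^2
      x[, t] <- budget * q + drop(C %*% q) + s_noise * noise[, t]
      if (!all(is.finite(x[, t])) || any(abs(x[, t]) > divergence_bound))
        return(NULL)
    }
    x
  })
  list(ensemble = ts_ensemble(sim[, (burn_in + 1L):total, drop = FALSE]),
       truth = pattern,
       config = list(a = a, s_noise = s_noise, coupling = coupling,
                     T = T, burn_in = burn_in, seed = seed))
}

.benchmark_names <- c("2-logistic", "3-fan-out", "3-fan-in",
                      "5-linear", "5-nonlinear",
                      "34-Zachary1", "34-Zachary2")

#' Generate a benchmark suite of independently seeded realizations
#'
#' Produces `n_sets` realizations of one named benchmark, each `T` points
#' long, with its ground-truth directed adjacency. For `"34-Zachary2"` the
#' random edge orientation is regenerated per set, so each realization has
#' its own ground truth; all other benchmarks share one truth.
#'
#' @param name One of `"2-logistic"`, `"3-fan-out"`, `"3-fan-in"`,
#'   `"5-linear"`, `"5-nonlinear"`, `"34-Zachary1"`, `"34-Zachary2"`.
#' @param n_sets Number of realizations (default 50).
#' @param T Series length (default 500).
#' @param seed Master seed; per-set seeds are derived from it.
#' @return List of class `lsngc_benchmark`: `name`, `ensembles` (list of
#'   [ts_ensemble]), `truths` (list of adjacency matrices, one per set),
#'   `n_sets`, `T`, `seed`.
#' @export
benchmark_suite <- function(name, n_sets = 50L, T = 500L, seed = 1L) {
  if (!name %in% .benchmark_names)
    stop("unknown benchmark '", name, "'; valid names: ",
         paste(.benchmark_names, collapse = ", "))
  seeds <- as.integer(seed) + 1000L * seq_len(n_sets)
  one <- function(si) {
    switch(name,
      "2-logistic" = simulate_two_logistic(T = T, seed = si),
      "3-fan-out" = simulate_fan_motif("out", T = T, seed = si),
      "3-fan-in" = simulate_fan_motif("in", T = T, seed = si),
      "5-linear" = simulate_five_node("linear", T = T, seed = si),
      "5-nonlinear" = simulate_five_node("nonlinear", T = T, seed = si),
      "34-Zachary1" = {
        p <- zachary_graph(directed = FALSE)
        simulate_zachary(p, coupling = 0.025, T = T, seed = si)
      },
      "34-Zachary2" = {
        p <- zachary_graph(directed = TRUE, seed = si)
        simulate_zachary(p, coupling = 0.05, T = T, seed = si)
      })
  }
  runs <- lapply(seeds, one)
  structure(list(name = name,
                 ensembles = lapply(runs, `[[`, "ensemble"),
                 truths = lapply(runs, `[[`, "truth"),
                 n_sets = as.integer(n_sets), T = as.integer(T),
                 seed = as.integer(seed)),
            class = "lsngc_benchmark")
}

#' @export
print.lsngc_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark suite '%s': %d sets of %d x %d\n", x$name,
              x$n_sets, nrow(x$ensembles[[1L]]), x$T))
  invisible(x)
}
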