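# Nested-regression machinery: restricted vs unrestricted linear readouts
# on GRBF activations, compared with an F-test. Both activation blocks are
# partitions of unity, so the constant vector lies in each design's span
# and the combined design is rank-deficient by construction; least squares
# therefore uses the minimum-norm solution, whose residual sum of squares
# is unique and keeps the F-statistic well defined.

#' Least squares with minimum-norm solution
#'
#' Solves `design %*% beta ~ target` by SVD. For rank-deficient designs the
#' minimum-norm coefficient vector is returned; the residual sum of squares
#' is the (unique) minimum.
#'
#' @param design Numeric matrix (n x p).
#' @param target Numeric vector of length n.
#' @return List with `coefficients`, `rss`, `rank`, `fitted`.
#' @export
least_squares_rss <- function(design, target) {
  if (!is.matrix(design)) design <- as.matrix(design)
  if (nrow(design) == 0L || ncol(design) == 0L) stop("empty design matrix")
  stopifnot(nrow(design) == length(target))
  sv <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  uty <- crossprod(sv$u[, pos, drop = FALSE], target)
  beta <- sv$v[, pos, drop = FALSE] %*% (uty / sv$d[pos])
  fitted <- drop(design %*% beta)
  list(coefficients = drop(beta),
       rss = sum((target - fitted)^2),
       rank = sum(pos),
       fitted = fitted)
}

# Orthonormal basis of a design's column space; used to get RSS for many
# targets from one factorization: rss(y) = ||y||^2 - ||Q'y||^2.
.col_basis <- function(design) {
  sv <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(sv$d, 0)
  sv$u[, sv$d > tol, drop = FALSE]
}

.rss_from_basis <- function(Q, y) {
  max(sum(y^2) - sum(crossprod(Q, y)^2), 0)
}

#' Nested-regression F-statistic
#'
#' `F = ((rss_r - rss_u) / (p_u - p_r)) / (rss_u / (n - p_u - 1))`, the
#' explanatory gain of the unrestricted model per extra parameter, relative
#' to its residual variance. A (numerically) negative numerator is clamped
#' to zero.
#'
#' @param rss_r,rss_u Residual sums of squares of the restricted and
#'   unrestricted model.
#' @param p_r,p_u Parameter counts (`p_u > p_r`).
#' @param n Regression sample count.
#' @return The F value (scalar, >= 0).
#' @export
f_statistic <- function(rss_r, rss_u, p_r, p_u, n) {
  if (p_u <= p_r) stop("p_u must exceed p_r")
  df2 <- n - p_u - 1L
  if (df2 <= 0L)
    stop("insufficient-samples error: n - p_u - 1 = ", df2,
         " <= 0; need at least n = ", p_u + 2L,
         " regression rows (increase T or reduce c_f/c_g/d)")
  if (rss_u <= 0) rss_u <- .Machine$double.eps
  num <- max(rss_r - rss_u, 0) / (p_u - p_r)
  num / (rss_u / df2)
}

#' Benjamini-Hochberg thresholded adjacency
#'
#' Applies the BH step-up procedure to the `N(N-1)` off-diagonal p-values
#' jointly and returns the binary adjacency of significant directed edges.
#'
#' @param p_values N x N matrix of p-values (diagonal ignored).
#' @param q FDR level (default 0.05).
#' @return Integer N x N matrix; `adjacency[s, r] = 1` iff the edge s -> r
#'   survives FDR control at level `q`. Diagonal is 0.
#' @export
fdr_adjacency <- function(p_values, q = 0.05) {
  stopifnot(is.matrix(p_values), nrow(p_values) == ncol(p_values))
  N <- nrow(p_values)
  off <- row(p_values) != col(p_values)
  p <- p_values[off]
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  adj <- matrix(0L, N, N, dimnames = dimnames(p_values))
  adj[off] <- as.integer(stats::p.adjust(p, method = "BH") <= q)
  adj
}

#' Score one directed pair with the nested-regression test
#'
#' Builds the source embedding `W_s` and conditional embedding `Z_s`, their
#' GRBF activations `g(W_s)` (c_g centers) and `f(Z_s)` (c_f centers), fits
#' the unrestricted readout on `[f(Z_s) | g(W_s)]` and the restricted one on
#' `f(Z_s)` alone for the one-step-ahead target `x_r(t+1)`, and returns both
#' fits with the F-statistic for the influence of series s on series r.
#'
#' @inheritParams build_delay_embedding
#' @param r Target series index (`r != s`).
#' @param c_f,c_g Number of GRBF centers for the conditional and source
#'   transforms (defaults 25 and 5).
#' @param seed Integer seed for center selection.
#' @return List of class `lsngc_pair`: `f_stat`, `p_value`, `rss_u`,
#'   `rss_r`, `p_u`, `p_r`, `n`, `df1`, `df2`, and the two coefficient
#'   vectors.
#' @export
pairwise_score <- function(ensemble, s, r, d, c_f = 25L, c_g = 5L,
                           seed = 1L) {
  e <- as_ensemble(ensemble)
  if (s == r) stop("source and target must differ")
  W <- build_delay_embedding(e, s, d)
  Z <- build_conditional_embedding(e, s, d)
  tf <- fit_centers(Z$states, c_f, seed = .derive_seed(seed, e[s, ], 1L))
  tg <- fit_centers(W$states, c_g, seed = .derive_seed(seed, e[s, ], 2L))
  Fz <- activations(tf, Z$states)
  Gw <- activations(tg, W$states)
  y <- embedding_targets(e, r, W)
  fit_u <- least_squares_rss(cbind(Fz, Gw), y)
  fit_r <- least_squares_rss(Fz, y)
  p_u <- tf$k + tg$k
  p_r <- tf$k
  n <- length(y)
  f <- f_statistic(fit_r$rss, fit_u$rss, p_r, p_u, n)
  df1 <- p_u - p_r
  df2 <- n - p_u - 1L
  structure(list(f_stat = f,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 rss_u = fit_u$rss, rss_r = fit_r$rss,
                 p_u = p_u, p_r = p_r, n = n, df1 = df1, df2 = df2,
                 coef_unrestricted = fit_u$coefficients,
                 coef_restricted = fit_r$coefficients),
            class = "lsngc_pair")
}

# Deterministic per-source seed derivation from one master seed. The
# source is identified by its data, not its row index, so relabeling or
# permuting series permutes the affinity matrix exactly (k-means and the
# activations depend on the states only through distances, which are
# invariant under the column reordering a permutation induces).
.derive_seed <- function(seed, source_values, which) {
  h <- as.integer(floor(sum(abs(source_values)) * 1e3) %% 65521)
  (as.integer(seed) %% 30011L) * 65536L + h * 2L + as.integer(which)
}
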