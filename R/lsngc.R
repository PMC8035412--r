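#' Large-scale nonlinear Granger causality
#'
#' Fits the lsNGC estimator to an ensemble of N time series: for every
#' ordered pair (s, r) it asks whether the delay-embedded past of series s
#' improves one-step-ahead prediction of series r beyond what the
#' (GRBF-transformed) past of all other series already achieves. The
#' answer is an F-statistic from the nested regression of `x_r(t+1)` on
#' `[f(Z_s) | g(W_s)]` versus `f(Z_s)` alone, stored at position (s, r) of
#' the affinity matrix.
#'
#' Per source s the conditional embedding `Z_s`, the source embedding
#' `W_s`, their k-means centers and activations are computed once and
#' reused for all N-1 targets, so N clusterings are run in total, not N^2.
#'
#' @param x A [ts_ensemble] or numeric N x T matrix (series in rows).
#' @param d Embedding dimension: a positive integer, or `"auto"` (default)
#'   to select it with Cao's method per series and take the median
#'   (rounded up) across series.
#' @param c_f Number of GRBF centers for the conditional transform
#'   (default 25).
#' @param c_g Number of GRBF centers for the source transform (default 5).
#' @param q FDR level for the Benjamini-Hochberg thresholded adjacency
#'   (default 0.05).
#' @param seed Master seed; all clustering randomness derives from it.
#' @param d_max,cao_threshold Parameters of Cao's method when `d = "auto"`.
#' @return An object of class `lsngc` with components:
#'   \describe{
#'     \item{f_stats}{N x N matrix of F-statistics, `[s, r]` = influence of
#'       s on r; diagonal `NaN`.}
#'     \item{p_values}{upper-tail F-test p-values, same layout.}
#'     \item{adjacency}{binary matrix of FDR-significant edges at level `q`.}
#'     \item{sources}{per-source data frame of the fitted center counts and
#'       degrees of freedom actually used.}
#'     \item{d, c_f, c_g, q, seed, n, labels}{the resolved configuration.}
#'   }
#' @examples
#' sim <- simulate_two_logistic(T = 300, seed = 7)
#' fit <- lsngc(sim$ensemble, seed = 7)
#' fit$f_stats
#' summary(fit)
#' @export
lsngc <- function(x, d = "auto", c_f = 25L, c_g = 5L, q = 0.05,
                  seed = 1L, d_max = 10L, cao_threshold = 0.05) {
  e <- as_ensemble(x)
  N <- nrow(e); T <- ncol(e)
  if (identical(d, "auto")) {
    d <- choose_embedding_dimension(e, d_max = d_max,
                                    threshold = cao_threshold)
  }
  d <- as.integer(d)
  if (d < 1L || d >= T) stop("invalid embedding dimension d = ", d)
  labels <- rownames(e)
  fs <- matrix(NaN, N, N, dimnames = list(labels, labels))
  pv <- fs
  src <- vector("list", N)
  n <- T - d
  for (s in seq_len(N)) {
    res <- tryCatch(
      .lsngc_source(e, s, d, c_f, c_g, seed),
      error = function(err)
        stop("series pair diagnostics (source s = ", s, "): ",
             conditionMessage(err), call. = FALSE))
    fs[s, res$targets] <- res$f_stats
    pv[s, res$targets] <- res$p_values
    src[[s]] <- data.frame(source = s, c_f = res$p_r,
                           c_g = res$p_u - res$p_r,
                           df1 = res$df1, df2 = res$df2, n = res$n)
  }
  structure(list(f_stats = fs,
                 p_values = pv,
                 adjacency = fdr_adjacency(pv, q = q),
                 sources = do.call(rbind, src),
                 d = d, c_f = as.integer(c_f), c_g = as.integer(c_g),
                 q = q, seed = as.integer(seed), n = n,
                 labels = labels),
            class = "lsngc")
}

# all N-1 tests that share source s: one clustering of Z_s and W_s, one
# orthonormal basis per design, then cheap per-target projections
.lsngc_source <- function(e, s, d, c_f, c_g, seed) {
  N <- nrow(e)
  W <- build_delay_embedding(e, s, d)
  Z <- build_conditional_embedding(e, s, d)
  tf <- fit_centers(Z$states, c_f, seed = .derive_seed(seed, e[s, ], 1L))
  tg <- fit_centers(W$states, c_g, seed = .derive_seed(seed, e[s, ], 2L))
  Fz <- activations(tf, Z$states)
  Gw <- activations(tg, W$states)
  p_u <- tf$k + tg$k
  p_r <- tf$k
  n <- nrow(Fz)
  df2 <- n - p_u - 1L
  if (df2 <= 0L)
    stop("insufficient-samples error: n - p_U - 1 = ", df2,
         " <= 0 at d = ", d, ", c_f = ", tf$k, ", c_g = ", tg$k,
         "; need T >= ", d + p_u + 2L)
  Qr <- .col_basis(Fz)
  Qu <- .col_basis(cbind(Fz, Gw))
  targets <- setdiff(seq_len(N), s)
  fvals <- numeric(length(targets))
  for (i in seq_along(targets)) {
    y <- embedding_targets(e, targets[i], W)
    rss_r <- .rss_from_basis(Qr, y)
    rss_u <- .rss_from_basis(Qu, y)
    fvals[i] <- f_statistic(rss_r, rss_u, p_r, p_u, n)
  }
  df1 <- p_u - p_r
  list(targets = targets, f_stats = fvals,
       p_values = stats::pf(fvals, df1, df2, lower.tail = FALSE),
       p_u = p_u, p_r = p_r, n = n, df1 = df1, df2 = df2)
}

#' @export
print.lsngc <- function(x, ...) {
  cat("lsNGC fit:", length(x$labels), "series,", x$n,
      "regression samples per test\n")
  cat(sprintf("  d = %d, c_f = %d, c_g = %d, FDR q = %g, seed = %d\n",
              x$d, x$c_f, x$c_g, x$q, x$seed))
  cat("  significant directed edges:", sum(x$adjacency), "of",
      length(x$labels) * (length(x$labels) - 1L), "\n")
  invisible(x)
}

#' @export
summary.lsngc <- function(object, ...) {
  N <- length(object$labels)
  off <- which(row(object$f_stats) != col(object$f_stats), arr.ind = TRUE)
  edges <- data.frame(
    source = object$labels[off[, 1L]],
    target = object$labels[off[, 2L]],
    f_stat = object$f_stats[off],
    p_value = object$p_values[off],
    significant = object$adjacency[off] == 1L)
  edges <- edges[order(edges$p_value, -edges$f_stat), ]
  rownames(edges) <- NULL
  structure(list(fit = object, edges = edges), class = "summary.lsngc")
}

#' @export
print.summary.lsngc <- function(x, n_show = 10L, ...) {
  print(x$fit)
  cat("\nStrongest directed edges:\n")
  print(utils::head(x$edges, n_show), digits = 4L)
  invisible(x)
}

#' Extract the affinity matrix of F-statistics
#' @param object An `lsngc` fit.
#' @param ... Unused.
#' @return The N x N matrix of F-statistics (diagonal `NaN`).
#' @export
coef.lsngc <- function(object, ...) object$f_stats

#' Plot an lsNGC affinity matrix
#'
#' Displays the log-transformed affinity matrix as an image, sources on the
#' vertical axis, targets on the horizontal.
#'
#' @param x An `lsngc` fit.
#' @param log If `TRUE` (default) show `log(F + 1e-12)`.
#' @param ... Passed on to [graphics::image].
#' @export
plot.lsngc <- function(x, log = TRUE, ...) {
  m <- x$f_stats
  if (log) m <- log_transform_scores(m)
  N <- nrow(m)
  m[!is.finite(m)] <- min(m[is.finite(m)])
  # image() draws row 1 at the bottom; flip so source 1 is at the top
  graphics::image(seq_len(N), seq_len(N), t(m[N:1, , drop = FALSE]),
                  axes = FALSE, xlab = "target", ylab = "source", ...)
  graphics::axis(1L, at = seq_len(N), labels = x$labels, las = 2L)
  graphics::axis(2L, at = seq_len(N), labels = rev(x$labels), las = 2L)
  graphics::box()
  invisible(x)
}

#' Write lsNGC results to disk
#'
#' Writes `f_stats.csv`, `p_values.csv` and `adjacency.csv` (labelled N x N
#' matrices) plus a `manifest.json` sidecar recording the resolved
#' configuration, into `dir`.
#'
#' @param fit An `lsngc` fit.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_lsngc <- function(fit, dir) {
  stopifnot(inherits(fit, "lsngc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("f_stats.csv", "p_values.csv",
                            "adjacency.csv", "manifest.json"))
  utils::write.csv(fit$f_stats, paths[1L])
  utils::write.csv(fit$p_values, paths[2L])
  utils::write.csv(fit$adjacency, paths[3L])
  manifest <- list(
    d = fit$d, c_f = fit$c_f, c_g = fit$c_g, q = fit$q,
    seed = fit$seed, n = fit$n, labels = fit$labels,
    sources = fit$sources,
    software = paste0("lsngc ", as.character(utils::packageVersion("lsngc"))))
  jsonlite::write_json(manifest, paths[4L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
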