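# Normalized (generalized) radial-basis-function transform. Cluster
# centers summarize the state space; the activation of a state is a
# Gaussian kernel around each center, normalized across centers so that
# every activation row is a partition of unity.

# squared Euclidean cross-distances, rows of A vs rows of B
.sqdist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- .sqdist(X, X[idx[1L], , drop = FALSE])[, 1L]
    for (j in 2:k) {
      if (all(d2 == 0)) idx[j] <- sample.int(n, 1L)
      else idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, .sqdist(X, X[idx[j], , drop = FALSE])[, 1L])
    }
  }
  X[idx, , drop = FALSE]
}

#' Fit GRBF centers by k-means and set the kernel width
#'
#' Clusters the state rows with seeded k-means (Lloyd iterations,
#' k-means++ initialization, 10 restarts) and sets the kernel width sigma
#' to the average spacing between the resulting centers (mean
#' nearest-neighbor distance; see [kernel_width]). If the states contain
#' fewer distinct rows than `k`, or fewer rows than `k`, the number of
#' centers is reduced with a warning and the reduced count is what enters
#' downstream degrees of freedom.
#'
#' @param states Numeric state matrix (rows are states).
#' @param k Requested number of centers (hidden neurons).
#' @param seed Integer seed for the clustering restarts.
#' @param width_method `"nearest"` (default) for mean nearest-neighbor
#'   spacing, `"allpairs"` for the mean over all center pairs.
#' @return A list of class `grbf`: `centers` (k' x width), `sigma`, `k`
#'   (the fitted, possibly reduced count), `seed`.
#' @export
fit_centers <- function(states, k, seed = 1L,
                        width_method = c("nearest", "allpairs")) {
  width_method <- match.arg(width_method)
  if (!is.matrix(states)) states <- as.matrix(states)
  if (nrow(states) < 1L) stop("empty state matrix")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nrow(states) < k) {
    k_new <- max(2L, nrow(states) %/% 2L)
    warning("fewer state rows (", nrow(states), ") than centers requested (",
            k, "); reducing k to ", k_new)
    k <- k_new
  }
  m <- nrow(unique(states))
  if (m < k) {
    warning("only ", m, " distinct state rows; reducing k from ", k, " to ", m)
    k <- m
  }
  centers <- withr::with_seed(as.integer(seed), {
    if (k == 1L) {
      matrix(colMeans(states), nrow = 1L)
    } else if (k == m) {
      # exact solution: the centers are the m distinct rows (zero inertia)
      unique(states)
    } else {
      best <- NULL
      for (r in 1:10) {
        init <- .kmeanspp_init(states, k)
        if (nrow(unique(init)) < k) next
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(states, centers = init,
                                         iter.max = 300L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$tot.withinss < best$tot.withinss))
          best <- fit
      }
      if (is.null(best))
        best <- suppressWarnings(stats::kmeans(states, centers = k,
                                               nstart = 10L, iter.max = 300L,
                                               algorithm = "Lloyd"))
      best$centers
    }
  })
  centers <- unname(as.matrix(centers))
  # merge duplicate centers before computing the width
  centers <- centers[!duplicated(round(centers, 12L)), , drop = FALSE]
  sigma <- if (nrow(centers) >= 2L) {
    kernel_width(centers, method = width_method)
  } else {
    s <- mean(sqrt(.sqdist(states, centers)[, 1L]))
    if (s <= 0) stop("degenerate-width error: all states coincide with the single center")
    s
  }
  structure(list(centers = centers, sigma = sigma,
                 k = nrow(centers), seed = as.integer(seed)),
            class = "grbf")
}

#' Kernel width from center spacing
#'
#' The width sigma is the average spacing between centers: by default the
#' mean, over centers, of the distance to the nearest other center (the
#' standard RBF-width heuristic); `method = "allpairs"` uses the mean of
#' all pairwise distances instead.
#'
#' @param centers Numeric matrix of distinct center rows (>= 2).
#' @param method `"nearest"` or `"allpairs"`.
#' @return Positive scalar sigma.
#' @export
kernel_width <- function(centers, method = c("nearest", "allpairs")) {
  method <- match.arg(method)
  if (!is.matrix(centers)) centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("need at least 2 centers")
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  sigma <- if (method == "nearest") mean(apply(D, 1L, min))
           else mean(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0)
    stop("degenerate-width error: duplicate-only centers")
  sigma
}

#' Normalized GRBF activations
#'
#' For each state row w and center v_i computes
#' `exp(-||w - v_i||^2 / sigma^2)` and normalizes across centers, so every
#' row is a partition of unity (sums to 1). The log-sum-exp max-subtraction
#' trick keeps rows well-defined even for states far outside the training
#' region.
#'
#' @param transform A `grbf` object from [fit_centers].
#' @param states State matrix whose width matches the centers.
#' @return Matrix of activations, `nrow(states)` x `k`.
#' @export
activations <- function(transform, states) {
  stopifnot(inherits(transform, "grbf"))
  if (!is.matrix(states)) states <- matrix(states, nrow = 1L)
  if (ncol(states) != ncol(transform$centers))
    stop("shape error: state width ", ncol(states),
         " does not match center width ", ncol(transform$centers))
  E <- -.sqdist(states, transform$centers) / transform$sigma^2
  E <- E - apply(E, 1L, max)
  A <- exp(E)
  A / rowSums(A)
}
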