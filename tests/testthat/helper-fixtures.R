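# Small in-code fixtures shared across test files.

random_ensemble <- function(N = 3L, T = 60L, seed = 1L) {
  withr::with_seed(seed, ts_ensemble(matrix(rnorm(N * T), N, T)))
}

logistic_series <- function(T = 500L, r = 3.7, seed = 1L, burn = 100L) {
  withr::with_seed(seed, {
    v <- numeric(T + burn)
    v[1L] <- runif(1L)
    for (t in seq_len(T + burn - 1L)) v[t + 1L] <- r * v[t] * (1 - v[t])
    v[(burn + 1L):(burn + T)]
  })
}

# brute-force AUC: enumerate all (positive, negative) score pairs,
# ties count 1/2
auc_bruteforce <- function(scores, truth) {
  off <- row(scores) != col(scores)
  s <- scores[off]; y <- truth[off]
  pos <- s[y == 1L]; neg <- s[y == 0L]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# classical nested-model F-test via explicit normal equations, for
# full-rank designs only
f_test_normal_equations <- function(X_r, X_u, y) {
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  rss_r <- rss(X_r); rss_u <- rss(X_u)
  p_r <- ncol(X_r); p_u <- ncol(X_u); n <- length(y)
  ((rss_r - rss_u) / (p_u - p_r)) / (rss_u / (n - p_u - 1))
}
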