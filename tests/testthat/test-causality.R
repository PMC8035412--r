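test_that("minimum-norm least squares reproduces classical solutions", {
  # full-rank square design: exact interpolation
  X <- diag(6)
  y <- withr::with_seed(1, rnorm(6))
  expect_equal(least_squares_rss(X, y)$rss, 0)

  # target orthogonal to the design's column space
  X2 <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  y2 <- c(0, 0, 2, 3)
  expect_equal(least_squares_rss(X2, y2)$rss, sum(y2^2))

  # seeded 40 x 6 design against explicit normal equations
  withr::with_seed(20, {
    X3 <- matrix(rnorm(240), 40, 6)
    y3 <- rnorm(40)
  })
  beta_ne <- solve(crossprod(X3), crossprod(X3, y3))
  fit <- least_squares_rss(X3, y3)
  expect_equal(fit$rss, sum((y3 - X3 %*% beta_ne)^2), tolerance = 1e-10)
  expect_equal(fit$coefficients, drop(beta_ne), tolerance = 1e-8)

  # rank-deficient design still yields the unique minimal RSS
  X4 <- cbind(X3, X3[, 1] + X3[, 2])
  expect_equal(least_squares_rss(X4, y3)$rss, fit$rss, tolerance = 1e-10)
})

test_that("the F-statistic follows its closed form", {
  expect_equal(f_statistic(2.0, 1.0, 25, 30, 100), (1 / 5) / (1 / 69))
  expect_equal(f_statistic(1.0, 1.0, 25, 30, 100), 0) # no explanatory gain
  expect_equal(f_statistic(0.9, 1.0, 25, 30, 100), 0) # clamp numerical noise
  expect_error(f_statistic(2, 1, 25, 30, 31), "insufficient-samples")
  expect_error(f_statistic(2, 1, 30, 25, 100), "p_u must exceed p_r")
})

test_that("BH thresholding follows the step-up rule", {
  p <- matrix(1, 3, 3)
  p[row(p) != col(p)] <- c(0.001, 0.02, 0.04, 0.9, 1, 1)
  # sorted cutoffs k*q/6: only p=0.001 survives step-up at q=0.05
  adj <- fdr_adjacency(p, q = 0.05)
  expect_identical(sum(adj), 1L)
  expect_identical(adj[p == 0.001], 1L)
  expect_identical(diag(adj), rep(0L, 3))

  expect_identical(sum(fdr_adjacency(matrix(1, 4, 4))), 0L)
  p0 <- matrix(0, 4, 4)
  expect_identical(sum(fdr_adjacency(p0)), 12L) # all off-diagonals
  expect_error(fdr_adjacency(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("pairwise score detects a planted nonlinear influence", {
  withr::with_seed(42, {
    x_s <- runif(203)
    x_r <- numeric(203)
    x_r[1] <- runif(1)
    for (t in 1:202) x_r[t + 1] <- 3.9 * x_s[t] * (1 - x_s[t]) + 0.01 * rnorm(1)
    x_o <- rnorm(203) # independent bystander
  })
  e <- ts_ensemble(rbind(x_s, x_r, x_o), labels = c("s", "r", "o"))
  res <- pairwise_score(e, s = 1, r = 2, d = 2, c_f = 10, c_g = 5, seed = 1)
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$df1, res$p_u - res$p_r)
  expect_lte(res$rss_u, res$rss_r + 1e-9)

  # determinism: same seed, same statistic
  res2 <- pairwise_score(e, s = 1, r = 2, d = 2, c_f = 10, c_g = 5, seed = 1)
  expect_identical(res$f_stat, res2$f_stat)
})

test_that("with default center counts the numerator dof equals c_g", {
  e <- random_ensemble(N = 3, T = 200, seed = 31)
  res <- pairwise_score(e, s = 1, r = 2, d = 2, seed = 1)
  expect_identical(res$df1, 5L)
  expect_identical(res$p_u, 30L)
  expect_identical(res$p_r, 25L)
})

test_that("null pairs are calibrated: uncorrected p-values near uniform", {
  pvals <- vapply(1:60, function(i) {
    e <- random_ensemble(N = 3, T = 120, seed = 500 + i)
    pairwise_score(e, s = 1, r = 2, d = 2, c_f = 10, c_g = 4,
                   seed = 500 + i)$p_value
  }, numeric(1))
  # rejection rate at alpha within binomial error; the data-driven centers
  # make the test mildly conservative, never anti-conservative
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / 60) + 0.02)
  expect_lt(abs(mean(pvals < 0.1) - 0.1), 2 * sqrt(0.1 * 0.9 / 60) + 0.02)
  expect_lte(mean(pvals < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})

test_that("the affinity matrix is permutation-equivariant and cached per source", {
  sim <- simulate_fan_motif("out", T = 150, seed = 5)
  fit <- lsngc(sim$ensemble, d = 2, c_f = 8, c_g = 3, seed = 7)
  perm <- c(3, 1, 2)
  ep <- ts_ensemble(unclass(sim$ensemble)[perm, ],
                    labels = rownames(sim$ensemble)[perm])
  fitp <- lsngc(ep, d = 2, c_f = 8, c_g = 3, seed = 7)
  # distances are permutation-invariant, so the statistics agree up to
  # floating-point summation order
  expect_equal(unname(fitp$f_stats), unname(fit$f_stats[perm, perm]),
               tolerance = 1e-9)
  expect_identical(unname(fitp$adjacency), unname(fit$adjacency[perm, perm]))

  expect_true(all(is.nan(diag(fit$f_stats))))
  off <- row(fit$p_values) != col(fit$p_values)
  expect_true(all(fit$p_values[off] >= 0 & fit$p_values[off] <= 1))
  expect_true(all(fit$f_stats[off] >= 0))
})

test_that("rescaling one series keeps the recovered direction", {
  sim <- simulate_two_logistic(T = 300, seed = 6)
  fit <- lsngc(sim$ensemble, d = 2, c_f = 8, c_g = 3, seed = 2)
  e2 <- unclass(sim$ensemble)
  e2[1, ] <- 10 * e2[1, ]
  fit2 <- lsngc(ts_ensemble(e2), d = 2, c_f = 8, c_g = 3, seed = 2)
  # centers and sigma are refit, so the dominant edge is preserved
  expect_gt(fit$f_stats[1, 2], fit$f_stats[2, 1])
  expect_gt(fit2$f_stats[1, 2], fit2$f_stats[2, 1])
})
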