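test_that("two-species logistic map follows its one-step update", {
  # x1 <- 0.5 * (3.7 - 3.7*0.5) = 0.925 when uncoupled
  s1 <- simulate_two_logistic(gamma21 = 0, T = 2, burn_in = 0,
                              init = c(0.5, 0.5), seed = 1)
  expect_equal(unname(s1$ensemble[1, 2]), 0.925)
  # x2 <- 0.5 * (3.8 - 3.8*0.5 - 0.32*0.5) = 0.87 under coupling
  s2 <- simulate_two_logistic(T = 2, burn_in = 0, init = c(0.5, 0.5),
                              seed = 1)
  expect_equal(unname(s2$ensemble[2, 2]), 0.87)
  expect_identical(s2$truth, rbind(c(0L, 1L), c(0L, 0L)))
})

test_that("default logistic trajectories stay in [0,1] after burn-in", {
  for (sd in 1:5) {
    s <- simulate_two_logistic(T = 500, seed = sd)
    expect_true(all(s$ensemble >= 0 & s$ensemble <= 1))
    expect_identical(dim(unclass(s$ensemble)), c(2L, 500L))
  }
})

test_that("fan motifs carry the right ground truth and stay bounded", {
  fo <- simulate_fan_motif("out", T = 300, seed = 2)
  expect_identical(sum(fo$truth), 2L)
  expect_identical(fo$truth[1, 2] + fo$truth[1, 3], 2L)
  expect_identical(fo$truth[2, 3] + fo$truth[3, 2], 0L)

  fi <- simulate_fan_motif("in", T = 300, seed = 2)
  expect_identical(sum(fi$truth), 2L)
  expect_identical(fi$truth[1, 3] + fi$truth[2, 3], 2L)

  expect_true(all(fo$ensemble >= 0 & fo$ensemble <= 1))
  expect_true(all(fi$ensemble >= 0 & fi$ensemble <= 1))
})

test_that("five-node system has the canonical edge set and coefficients", {
  s <- simulate_five_node("linear", T = 300, seed = 3)
  truth <- matrix(0L, 5, 5)
  truth[1, 2:4] <- 1L; truth[4, 5] <- 1L; truth[5, 4] <- 1L
  expect_identical(s$truth, truth)
  expect_identical(dim(unclass(s$ensemble)), c(5L, 300L))

  # refit the generating AR(2) of x1 at large T: coefficients recovered
  big <- simulate_five_node("linear", T = 5000, seed = 4)
  x1 <- unclass(big$ensemble)[1, ]
  n <- length(x1)
  fit <- lm(x1[3:n] ~ 0 + x1[2:(n - 1)] + x1[1:(n - 2)])
  est <- coef(summary(fit))
  expect_lt(abs(est[1, 1] - 0.95 * sqrt(2)), 2 * est[1, 2])
  expect_lt(abs(est[2, 1] + 0.9025), 2 * est[2, 2])
  # innovation variance close to 1
  expect_lt(abs(summary(fit)$sigma - 1), 0.05)

  # nonlinear variant differs only through the squared drive into x4
  nl <- simulate_five_node("nonlinear", T = 300, seed = 3)
  expect_identical(nl$truth, truth)
  expect_false(isTRUE(all.equal(unclass(nl$ensemble)[4, ],
                                unclass(s$ensemble)[4, ])))
  expect_equal(unclass(nl$ensemble)[1, ], unclass(s$ensemble)[1, ])
})

test_that("the karate-club skeleton matches the published graph", {
  el <- zachary_edges()
  expect_identical(dim(el), c(78L, 2L))
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = 34)
  expect_identical(max(deg), 17L)
  expect_identical(sum(deg), 156L)

  skip_if_not_installed("igraph")
  g <- igraph::make_graph("Zachary")
  expect_identical(sort(deg), sort(as.integer(igraph::degree(g))))
  ref <- igraph::as_edgelist(g)
  norm <- function(m) m[order(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])), ]
  expect_equal(norm(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))),
               norm(cbind(pmin(ref[, 1], ref[, 2]), pmax(ref[, 1], ref[, 2]))),
               ignore_attr = TRUE)
})

test_that("Zachary coupling patterns have the prescribed edge counts", {
  und <- zachary_graph(directed = FALSE)
  expect_identical(sum(und), 156L)
  expect_identical(und, t(und))
  expect_identical(diag(und), rep(0L, 34))

  for (sd in 1:5) {
    dir <- zachary_graph(directed = TRUE, seed = sd)
    expect_identical(sum(dir), 83L) # 78 oriented + 5 upgraded
    sym_pairs <- sum(dir == 1L & t(dir) == 1L) / 2
    expect_identical(sym_pairs, 5)
  }
})

test_that("Zachary map dynamics satisfy the origin identity and bounds", {
  p <- zachary_graph(directed = TRUE, seed = 1)
  # from x = 0 with no noise the couplings cancel: every node lands on 1
  s0 <- simulate_zachary(p, s_noise = 0, T = 2, burn_in = 0,
                         init = rep(0, 34), seed = 1)
  expect_equal(unname(s0$ensemble[, 2]), rep(1, 34))

  s <- simulate_zachary(p, T = 200, seed = 2)
  expect_true(all(abs(s$ensemble) < 2))
  expect_identical(s$truth, p)

  over <- matrix(1L, 34, 34); diag(over) <- 0L
  expect_error(simulate_zachary(over, coupling = 0.05), "coupling budget")
})

test_that("benchmark suites are reproducible and correctly shaped", {
  a <- benchmark_suite("2-logistic", n_sets = 3, T = 120, seed = 9)
  b <- benchmark_suite("2-logistic", n_sets = 3, T = 120, seed = 9)
  expect_identical(a, b)
  expect_identical(length(a$ensembles), 3L)
  expect_identical(dim(unclass(a$ensembles[[2]])), c(2L, 120L))

  z <- benchmark_suite("34-Zachary2", n_sets = 3, T = 60, seed = 1)
  expect_identical(vapply(z$truths, sum, integer(1)), rep(83L, 3))
  expect_false(identical(z$truths[[1]], z$truths[[2]])) # per-set orientation

  expect_error(benchmark_suite("no-such-net"), "2-logistic")
})
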