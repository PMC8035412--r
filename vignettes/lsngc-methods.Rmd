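---
title: "Large-scale nonlinear Granger causality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Large-scale nonlinear Granger causality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lsngc)
```

## The problem

Given an ensemble of $N$ simultaneously recorded time series
$x_1, \dots, x_N$ of length $T$, we want the *directed* network of
influences among them: which series help predict which other series,
beyond what the rest of the system already explains. Granger's
operational definition — $x_s$ causes $x_r$ if the past of $x_s$
improves prediction of $x_r$ given the past of everything else — is the
right framing, but the classical linear vector-autoregressive
implementation fails on nonlinear dynamics, and fully nonparametric
conditional estimators do not scale to dozens of series with only a few
hundred samples each.

`lsngc()` implements a middle path: each conditioning set is compressed
through a fixed, small nonlinear basis before the linear prediction
step, so the nested-regression machinery (and its F-test) survives
intact while the features themselves capture nonlinear structure.

## The estimator

For a candidate source $s$ and embedding dimension $d$:

1. **Delay embedding of the source.** The state of $x_s$ at time $t$ is
   the window $w_s(t) = (x_s(t-d+1), \dots, x_s(t))$. Stacking all
   windows gives the $n \times d$ matrix $W_s$ with $n = T - d$ usable
   rows, each aligned with a one-step-ahead target at $t+1$
   (`build_delay_embedding()`).

2. **Conditional embedding of everything else.** The same windows for
   all series *except* $s$, concatenated into an
   $n \times (N-1)d$ matrix $Z_s$ (`build_conditional_embedding()`).

3. **Normalized GRBF transforms.** Both state matrices are mapped
   through normalized Gaussian radial basis functions: with centers
   $v_1, \dots, v_k$ from k-means clustering of the states, the $i$-th
   activation at state $u$ is
   $$\phi_i(u) = \frac{\exp(-\lVert u - v_i\rVert^2/\sigma^2)}
                      {\sum_{j=1}^{k}\exp(-\lVert u - v_j\rVert^2/\sigma^2)}.$$
   The rows sum to one by construction (a partition of unity), so the
   transform is a soft, smooth quantization of the state space. The
   source states get $c_g$ centers (default 5), the much
   higher-dimensional conditional states get $c_f$ centers (default
   25). The kernel width $\sigma$ is the mean nearest-neighbor distance
   among the fitted centers (`fit_centers()`, `kernel_width()`,
   `activations()`).

4. **Nested regressions and F-test.** For each target $r \neq s$, two
   linear least-squares models predict $x_r(t+1)$: the *restricted*
   model from the conditional activations $f(Z_s)$ alone
   ($p_R = c_f$ regressors), and the *unrestricted* model from
   $[\,f(Z_s) \mid g(W_s)\,]$ ($p_U = c_f + c_g$). The affinity score is
   $$F_{s \to r} =
     \frac{(\mathrm{RSS}_R - \mathrm{RSS}_U)/(p_U - p_R)}
          {\mathrm{RSS}_U/(n - p_U - 1)},$$
   with a p-value from the upper tail of
   $F(p_U - p_R,\; n - p_U - 1)$.

5. **Multiple-testing control.** The $N(N-1)$ off-diagonal p-values are
   Benjamini–Hochberg adjusted and thresholded at $q$ (default 0.05) to
   give a binary adjacency matrix (`fdr_adjacency()`).

The result is an S3 object of class `"lsngc"` carrying the F-statistic
affinity matrix, the p-values, the adjacency, and the fit
configuration, with `print()`, `summary()`, `coef()`, and `plot()`
methods.

## Choosing the embedding dimension

With `d = "auto"` (the default) the embedding dimension comes from
Cao's method (`cao_embedding_dimension()`): for each trial dimension
$d$, find every state's nearest neighbor in the $d$-dimensional
embedding and measure how much their distance grows when one more
coordinate is appended. The mean growth factor $E(d)$ stabilizes once
$d$ suffices to unfold the dynamics; the method reports the first $d$
where the ratio $E1(d) = E(d{+}1)/E(d)$ is within 0.05 of 1 *or*
changes by less than 0.05 from the previous ratio. If no $d \le
d_{\max}$ (default 10) satisfies this, $d_{\max}$ is returned with a
warning. The ensemble-level dimension is the rounded-up median of the
per-series values (`choose_embedding_dimension()`). Deterministic
low-dimensional signals (logistic maps, sinusoids) yield $d \le 3$;
white noise drifts to large $d$ because no embedding ever unfolds it.

## Numerical choices

**No intercept, and deliberate rank deficiency.** Because the GRBF
activations are a partition of unity, each block already contains the
constant vector in its column span, so no intercept column is added —
and the combined design $[f \mid g]$ is rank-deficient *by
construction* (both blocks sum rowwise to one). The residual sum of
squares is still unique; `least_squares_rss()` computes the
minimum-norm solution through the singular value decomposition, with
small singular values truncated at a relative tolerance. The degrees
of freedom in the F-test use the nominal column counts $p_R = c_f$ and
$p_U = c_f + c_g$, matching the standard formulation of the method.

**One clustering per source.** The transforms of $W_s$ and $Z_s$
depend on the source only, so `lsngc()` fits both cluster sets once
per source and reuses orthonormal bases of the two design matrices for
all $N-1$ targets. The whole fit costs $2N$ k-means runs and $O(N^2)$
cheap projections, not $O(N^2)$ clusterings.

**k-means.** Centers come from Lloyd's algorithm (`stats::kmeans`,
`iter.max = 300`) with k-means++ initialization and 10 restarts,
keeping the lowest within-cluster sum of squares. If the states have
fewer rows (or fewer distinct rows) than requested centers, $k$ is
reduced with a warning; duplicate converged centers are merged. All
randomness is derived deterministically from the `seed` argument and
the source series' values, so fits are reproducible and permuting the
series permutes the result.

**Conservative null behavior.** The centers are estimated from the
same data used in the regressions, so the F-statistic's null
distribution is slightly stochastically smaller than the reference
$F$ distribution. Empirically (see the package tests) the rejection
rate at level $\alpha$ sits at or just below $\alpha$ — the safe
direction: the FDR-controlled adjacency is conservative, never
anti-conservative.

## The benchmark simulators

The package ships the synthetic systems used to validate the
estimator; all have known ground-truth graphs, and their defaults are
the study conditions (500 retained time points after burn-in, ensembles
of 50 realizations via `benchmark_suite()`):

- `simulate_two_logistic()`: two chaotic logistic maps with
  unidirectional coupling $x_1 \to x_2$ (rates 3.7 and 3.8, coupling
  0.32). The minimal nonlinear test of directionality.
- `simulate_fan_motif()`: three logistic maps in a fan-out
  ($1 \to 2$, $1 \to 3$) or fan-in ($1 \to 3$, $2 \to 3$)
  configuration. Fan-out probes the common-driver confound: an
  unconditioned pairwise method sees a spurious $2 \leftrightarrow 3$
  association; conditioning should remove it.
- `simulate_five_node()`: the classic five-node autoregressive
  oscillator system (linear, and a nonlinear variant where one drive
  enters squared), truth $\{1\to2, 1\to3, 1\to4, 4\to5, 5\to4\}$.
- `simulate_zachary()` with `zachary_graph()`: 34 noisy quadratic maps
  coupled along the Zachary karate-club network, either undirected
  (all edges bidirectional, coupling 0.025) or directed (random
  orientation plus five bidirectional edges, coupling 0.05). This is
  the "large-scale" regime: 1122 ordered pairs from 500 samples per
  series.

These systems emulate the properties that make real recordings (e.g.
neuroimaging or gene-expression series) hard — chaotic or oscillatory
dynamics, weak coupling, observation noise, short length, confounders —
while keeping the true graph exactly known. They are *not* calibrated
to any particular measurement modality.

## Evaluation harness

`run_benchmark()` fits `lsngc()` to every realization in a suite, at
one or more truncated lengths, and scores the log-transformed affinity
matrices against the ground truth: threshold-free ranking quality via
`roc_auc()` (rank-based, ties counted half), and the FDR-thresholded
operating point via `sensitivity_specificity()` (reported alongside
balanced accuracy by default, or Youden's J). The natural-log
transform `log_transform_scores()` compresses the heavy right tail of
the F-statistics for plotting; it is monotone, so ranking metrics are
unchanged by it — a property the tests verify directly.

## Limitations

- The method tests *one-step-ahead, single-lag-block* prediction with
  a shared embedding dimension for all series; strongly heterogeneous
  time scales may need manual `d`.
- F-test p-values are asymptotic and assume homoscedastic residuals;
  with data-driven centers they are conservative rather than exact.
- $c_f = 25$ conditional centers compress $(N-1)d$ dimensions very
  aggressively when $N$ is large; this is what makes 34 nodes feasible
  at $T = 500$, but residual confounding through the compression is
  possible.
- Hidden (unrecorded) common drivers remain outside Granger's
  framework entirely; no conditioning can remove them.
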