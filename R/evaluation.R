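# Scoring recovered networks against ground truth: rank-based AUC on the
# (log-transformed) score matrix, sensitivity/specificity on the
# FDR-thresholded adjacency, and the median-over-runs benchmarking
# protocol with a time-series-length sweep.

#' Log-transform a score matrix
#'
#' `log(x + epsilon)` entrywise, used to reduce the skew of F-statistic
#' scores before display or AUC computation (AUC itself is rank-based and
#' unaffected). The diagonal is left as is.
#'
#' @param f_stats Square matrix of non-negative scores (diagonal may be
#'   `NaN`).
#' @param epsilon Offset guarding `log(0)` (default 1e-12).
#' @return Transformed matrix.
#' @export
log_transform_scores <- function(f_stats, epsilon = 1e-12) {
  off <- row(f_stats) != col(f_stats)
  if (any(f_stats[off] < 0, na.rm = TRUE))
    stop("negative scores: F-statistics cannot be negative")
  out <- f_stats
  out[off] <- log(f_stats[off] + epsilon)
  out
}

#' ROC AUC for directed-network recovery
#'
#' Area under the ROC curve over the N(N-1) off-diagonal (score, label)
#' pairs, computed with the rank (Mann-Whitney) formulation; tied scores
#' contribute 1/2.
#'
#' @param scores Square score matrix (higher = more confident edge).
#' @param truth Square binary matrix of true directed edges.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(all(dim(scores) == dim(truth)))
  off <- row(scores) != col(scores)
  s <- scores[off]; y <- truth[off]
  keep <- is.finite(s)
  s <- s[keep]; y <- y[keep]
  P <- sum(y == 1L); Ng <- sum(y == 0L)
  if (P == 0L || Ng == 0L)
    stop("undefined-AUC error: truth needs at least one edge and one non-edge")
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1L]) - P * (P + 1) / 2) / (P * Ng)
}

#' Sensitivity and specificity of a thresholded adjacency
#'
#' Counts off-diagonal true/false positives/negatives of a binary
#' predicted adjacency against the ground truth and returns sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and a combined score: balanced
#' accuracy `(sens + spec)/2` (default) or Youden's J `sens + spec - 1`.
#'
#' @param adjacency Binary predicted matrix.
#' @param truth Binary ground-truth matrix of the same shape.
#' @param combine `"balanced"` or `"youden"`.
#' @return Named numeric vector: `sensitivity`, `specificity`, `combined`.
#' @export
sensitivity_specificity <- function(adjacency, truth,
                                    combine = c("balanced", "youden")) {
  combine <- match.arg(combine)
  stopifnot(all(dim(adjacency) == dim(truth)))
  off <- row(truth) != col(truth)
  pred <- adjacency[off] == 1L
  pos <- truth[off] == 1L
  if (!any(pos)) stop("sensitivity undefined: truth has no positive edges")
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  fp <- sum(pred & !pos); tn <- sum(!pred & !pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  comb <- if (combine == "balanced") (sens + spec) / 2 else sens + spec - 1
  c(sensitivity = sens, specificity = spec, combined = comb)
}

#' Run the benchmarking protocol on a simulated suite
#'
#' For each requested series length T' (taking the leading T' points of
#' every realization, so lengths are nested) and each realization: fit
#' [lsngc], compute the AUC of the log-transformed affinity matrix against
#' the realization's ground truth, threshold by FDR at level `q` and
#' compute sensitivity/specificity. Lengths whose regression sample count
#' is too small for the F-test are skipped with a warning.
#'
#' @param suite An `lsngc_benchmark` from [benchmark_suite].
#' @param lengths Series lengths to evaluate (default: the full length).
#' @param d,c_f,c_g,q,seed Passed to [lsngc]; seeds are derived per run.
#' @param combine Combined sens/spec statistic, see
#'   [sensitivity_specificity].
#' @return List of class `lsngc_eval`, one element per evaluated length:
#'   `per_run` (data frame of auc, sensitivity, specificity, combined) and
#'   `medians`/`iqr` summaries, plus the configuration echo.
#' @export
run_benchmark <- function(suite, lengths = NULL, d = "auto", c_f = 25L,
                          c_g = 5L, q = 0.05, seed = 1L,
                          combine = c("balanced", "youden")) {
  combine <- match.arg(combine)
  stopifnot(inherits(suite, "lsngc_benchmark"))
  if (is.null(lengths)) lengths <- suite$T
  if (any(lengths > suite$T))
    stop("requested length exceeds the generated series length ", suite$T)
  out <- list()
  for (len in sort(lengths, decreasing = TRUE)) {
    rows <- vector("list", suite$n_sets)
    failed <- FALSE
    for (i in seq_len(suite$n_sets)) {
      e <- suite$ensembles[[i]][, seq_len(len), drop = FALSE]
      truth <- suite$truths[[i]]
      fit <- tryCatch(
        lsngc(e, d = d, c_f = c_f, c_g = c_g, q = q,
              seed = as.integer(seed) + 37L * i),
        error = function(err) err)
      if (inherits(fit, "error")) {
        warning("skipping length ", len, ": ", conditionMessage(fit))
        failed <- TRUE
        break
      }
      auc <- roc_auc(log_transform_scores(fit$f_stats), truth)
      ss <- sensitivity_specificity(fit$adjacency, truth, combine = combine)
      rows[[i]] <- data.frame(set = i, length = len, auc = auc,
                              sensitivity = ss[["sensitivity"]],
                              specificity = ss[["specificity"]],
                              combined = ss[["combined"]])
    }
    if (failed) next
    per_run <- do.call(rbind, rows)
    met <- per_run[, c("auc", "sensitivity", "specificity", "combined")]
    out[[as.character(len)]] <- list(
      length = len,
      per_run = per_run,
      medians = vapply(met, stats::median, numeric(1)),
      iqr = vapply(met, stats::IQR, numeric(1)),
      config = list(benchmark = suite$name, n_sets = suite$n_sets,
                    d = d, c_f = c_f, c_g = c_g, q = q, seed = seed,
                    combine = combine))
  }
  structure(out, class = "lsngc_eval")
}

#' @export
print.lsngc_eval <- function(x, ...) {
  cat("lsNGC benchmark evaluation\n")
  for (len in names(x)) {
    m <- x[[len]]$medians
    cat(sprintf(
      "  T = %4s: median AUC %.3f, sens %.3f, spec %.3f, combined %.3f (%d runs)\n",
      len, m[["auc"]], m[["sensitivity"]], m[["specificity"]],
      m[["combined"]], nrow(x[[len]]$per_run)))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the per-run metrics as a tidy CSV and the median/IQR summaries as
#' JSON.
#'
#' @param report An `lsngc_eval` from [run_benchmark].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(report, dir) {
  stopifnot(inherits(report, "lsngc_eval"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_run <- do.call(rbind, lapply(report, `[[`, "per_run"))
  p1 <- file.path(dir, "per_run_metrics.csv")
  p2 <- file.path(dir, "summary.json")
  utils::write.csv(per_run, p1, row.names = FALSE)
  summ <- lapply(report, function(el)
    list(length = el$length, medians = as.list(el$medians),
         iqr = as.list(el$iqr), config = el$config))
  jsonlite::write_json(summ, p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
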