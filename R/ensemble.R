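#' Time-series ensemble container
#'
#' Validates and wraps an N x T matrix of N series observed at T time points.
#' Rows are series, columns are time points. All entries must be finite.
#'
#' @param values Numeric matrix, N series x T time points (N >= 2, T >= 2).
#' @param labels Character vector of N unique series labels, or `NULL` to
#'   auto-generate `x1..xN`.
#' @return An object of class `ts_ensemble`: the validated matrix with
#'   row names set to the labels.
#' @export
ts_ensemble <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (series in rows)")
  N <- nrow(values); T <- ncol(values)
  if (N < 2L) stop("input-format error: need at least 2 series, got ", N)
  if (T < 2L) stop("input-format error: need at least 2 time points, got ", T)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("input-format error: non-finite value at series %d, time point %d",
                 bad[1L, 1L], bad[1L, 2L]))
  if (is.null(labels)) labels <- paste0("x", seq_len(N))
  labels <- as.character(labels)
  if (length(labels) != N) stop("labels length (", length(labels),
                                ") does not match series count (", N, ")")
  if (anyDuplicated(labels)) stop("series labels must be unique")
  rownames(values) <- labels
  colnames(values) <- NULL
  structure(values, class = c("ts_ensemble", "matrix", "array"))
}

#' @export
print.ts_ensemble <- function(x, ...) {
  cat(sprintf("Time-series ensemble: %d series x %d time points\n",
              nrow(x), ncol(x)))
  cat("Series:", paste(utils::head(rownames(x), 8L), collapse = ", "),
      if (nrow(x) > 8L) "..." else "", "\n")
  invisible(x)
}

as_ensemble <- function(x) {
  if (inherits(x, "ts_ensemble")) return(x)
  ts_ensemble(as.matrix(x), labels = rownames(x))
}

.guess_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.is_numlike <- function(tok) {
  tok <- trimws(gsub('^"|"$', "", tok))
  tok == "" | !is.na(suppressWarnings(as.numeric(tok))) |
    tok %in% c("NaN", "NA", "Inf", "-Inf")
}

#' Read a time-series ensemble from a delimited text file
#'
#' Accepts CSV or TSV matrices with an optional header line and an optional
#' leading label column (both auto-detected). The delimiter is inferred from
#' the file extension (`.tsv`/`.txt` is tab, anything else comma) unless
#' given explicitly.
#'
#' @param path Path to the delimited file.
#' @param orientation `"rows-are-series"` (default, N x T on disk) or
#'   `"columns-are-series"` (T x N on disk; the matrix is transposed on read).
#' @param delimiter Field separator; `NULL` to infer from the extension.
#' @return A [ts_ensemble].
#' @export
read_ensemble <- function(path,
                          orientation = c("rows-are-series", "columns-are-series"),
                          delimiter = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  sep <- if (is.null(delimiter)) .guess_sep(path) else delimiter
  first <- readLines(path, n = 1L)
  toks <- scan(text = first, what = character(), sep = sep, quiet = TRUE)
  # header if any token past the first is non-numeric
  has_header <- length(toks) > 1L && !all(.is_numlike(toks[-1L]))
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = has_header,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "", check.names = FALSE),
    error = function(e) stop("input-format error: ", conditionMessage(e)))
  labels <- NULL
  if (ncol(df) > 1L && (is.character(df[[1L]]) || is.factor(df[[1L]]))) {
    labels <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) & !is.na(df[[j]]))
      stop(sprintf("input-format error: non-numeric cell at row %d, column %d",
                   if (length(bad)) bad[1L] else 1L, j))
    }
  }
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (orientation == "columns-are-series") {
    m <- t(m)
    if (has_header && is.null(labels)) labels <- toks[-1L][seq_len(nrow(m))]
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("input-format error: non-finite value at row %d, column %d of %s",
                 bad[1L, 1L], bad[1L, 2L], path))
  if (!is.null(labels) && length(labels) != nrow(m)) labels <- NULL
  ts_ensemble(m, labels = labels)
}

#' Write a time-series ensemble to a delimited text file
#'
#' Writes the N x T matrix with a header line (`series,t1..tT`) and the
#' series labels in the first column, quoting labels as needed. Values are
#' printed with 17 significant digits so that a read/write round trip is
#' lossless at double precision.
#'
#' @param ensemble A [ts_ensemble] (or numeric matrix).
#' @param path Output path; the delimiter is inferred from the extension
#'   unless `delimiter` is given.
#' @param delimiter Field separator; `NULL` to infer.
#' @param digits Significant digits to print (default 17, full precision).
#' @return Invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path, delimiter = NULL, digits = 17L) {
  e <- as_ensemble(ensemble)
  sep <- if (is.null(delimiter)) .guess_sep(path) else delimiter
  vals <- matrix(formatC(e, digits = digits, format = "g"),
                 nrow = nrow(e))
  quote_label <- function(s) {
    needs <- grepl(sep, s, fixed = TRUE) | grepl('"', s, fixed = TRUE)
    s[needs] <- paste0('"', gsub('"', '""', s[needs]), '"')
    s
  }
  header <- paste(c("series", paste0("t", seq_len(ncol(e)))), collapse = sep)
  body <- apply(cbind(quote_label(rownames(e)), vals), 1L,
                paste, collapse = sep)
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(err) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write to ", path)
  invisible(path)
}

#' Min-max normalize scores to [0, 1]
#'
#' Affine rescaling used for display of causality scores. For a square
#' matrix the diagonal is excluded from the min/max statistics (self
#' influence is undefined) and left untouched.
#'
#' @param scores Numeric vector or square matrix.
#' @return Object of the same shape with (off-diagonal) entries mapped to
#'   \[0, 1\]; strictly monotone in the input.
#' @export
minmax_normalize <- function(scores) {
  is_sq <- is.matrix(scores) && nrow(scores) == ncol(scores)
  vals <- if (is_sq) scores[row(scores) != col(scores)] else scores
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L || diff(range(vals)) == 0)
    stop("degenerate-scale error: need at least two distinct finite values")
  lo <- min(vals); hi <- max(vals)
  out <- scores
  if (is_sq) {
    off <- row(scores) != col(scores)
    out[off] <- (scores[off] - lo) / (hi - lo)
  } else {
    out <- (scores - lo) / (hi - lo)
  }
  out
}
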