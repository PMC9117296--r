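# Preprocessing mirrors the standard microarray workflow: collapse duplicate
# gene rows to their mean, quantile-normalize columns, log2-transform. The
# Hy-test itself is rank-based past thresholding (per-gene thresholds on the
# pooled values), so normalization cannot change its results; it matters for
# the scale-sensitive moderated t comparator and for reporting.

#' Collapse duplicated gene rows to their mean expression
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene IDs
#'   (duplicates allowed).
#' @return Matrix with one row per unique gene ID (first-appearance order),
#'   duplicated rows replaced by their element-wise mean.
#' @export
collapse_duplicates <- function(expr) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stop_input("'expr' must be a matrix with gene rownames")
  ids <- rownames(expr)
  if (!anyDuplicated(ids)) return(expr)
  f <- factor(ids, levels = unique(ids))
  out <- rowsum(expr, f, reorder = FALSE) / as.vector(table(f))
  rownames(out) <- levels(f)
  out
}

#' Quantile normalization
#'
#' Forces every column to share the same empirical distribution: the vector
#' of row means of the column-sorted matrix (the reference order
#' statistics). Within a column, tied values receive the mean of the
#' reference values spanned by their tied ranks.
#'
#' @param expr Numeric matrix without missing values.
#' @return Matrix of the same shape; all columns have identical sorted
#'   values when the input has no within-column ties.
#' @export
quantile_normalize <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop_input("'expr' must be a numeric matrix")
  if (anyNA(expr)) stop_input("missing values are not supported")
  if (ncol(expr) == 1L) return(expr)
  ref <- rowMeans(apply(expr, 2L, sort))
  cref <- c(0, cumsum(ref))            # cref[r + 1] = sum of first r refs
  out <- expr
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    lo <- rank(x, ties.method = "min")
    hi <- rank(x, ties.method = "max")
    out[, j] <- (cref[hi + 1L] - cref[lo]) / (hi - lo + 1L)
  }
  out
}

#' Element-wise log2 transform with offset
#'
#' @param expr Numeric matrix.
#' @param offset Added before taking log2; `value + offset` must be
#'   positive everywhere. Use 1 for raw counts/intensities containing
#'   zeros, 0 for strictly positive data.
#' @return `log2(expr + offset)`.
#' @export
log2_transform <- function(expr, offset = 0) {
  if (!is.numeric(expr)) stop_input("'expr' must be numeric")
  if (any(expr + offset <= 0))
    stop_input("all values + offset must be positive for log2")
  log2(expr + offset)
}

#' Full preprocessing pipeline
#'
#' Collapse duplicate gene rows, quantile-normalize jointly across all
#' samples, then log2-transform -- in that order.
#'
#' @inheritParams collapse_duplicates
#' @inheritParams log2_transform
#' @param quantile Apply quantile normalization (jointly over all columns).
#' @param log2 Apply the log2 transform.
#' @return Preprocessed matrix.
#' @export
preprocess_expression <- function(expr, offset = 1, quantile = TRUE,
                                  log2 = TRUE) {
  expr <- collapse_duplicates(expr)
  if (quantile) expr <- quantile_normalize(expr)
  if (log2) expr <- log2_transform(expr, offset = offset)
  expr
}
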