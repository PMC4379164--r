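#' Quantile-normalize a matrix of intensities
#'
#' Forces every column to the same distribution — the across-column mean of
#' the sorted columns — while preserving within-column ranks. Tied values
#' receive the mean of their tied quantile slots, so the output of a column
#' is a function of its ranks alone. A single-column matrix is returned
#' unchanged.
#'
#' @param m numeric matrix, no missing cells.
#' @return normalized matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("quantile normalization requires no missing cells")
  if (ncol(m) <= 1L) return(m)
  ref <- rowMeans(apply(m, 2L, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(m, 2L, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Preprocess raw expression intensities
#'
#' Adds a constant offset (default 1) to enable log2 transformation, then
#' quantile-normalizes the log2 intensities to remove non-biological
#' between-array differences in intensity distribution.
#'
#' @param raw an \code{expr_matrix} with \code{state = "raw"}.
#' @param offset constant added before log2 (default 1).
#' @return an \code{expr_matrix} with \code{state = "log2_normalized"}.
#' @export
preprocess <- function(raw, offset = 1) {
  if (expr_state(raw) != "raw") stop("matrix is already preprocessed")
  v <- unclass(raw)
  attr(v, "state") <- NULL
  if (any(v < 0)) stop("raw intensities must be non-negative")
  expression_matrix(quantile_normalize(log2(v + offset)),
                    state = "log2_normalized")
}
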