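#' Normalize signals to zero mean and unit standard deviation
#'
#' Each column (one vertex's time series) is centered and scaled by its
#' population (1/t) standard deviation. Zero-variance columns cannot be
#' normalized (and their correlation-based accuracy would be undefined),
#' so they are excluded from the returned matrix with their ids recorded.
#'
#' @param X raw t x n signal matrix, or a `fold_simulation`.
#' @param vertex_ids optional ids for the columns (default `1:n`).
#' @return object of class `fold_signals`: list with `X` (normalized,
#'   retained columns only), `vertex_ids` (retained) and `excluded_ids`.
#' @examples
#' s <- normalize_signals(matrix(c(1, 2, 3, 5, 5, 5), nrow = 3))
#' s$excluded_ids  # column 2 was constant
#' @export
normalize_signals <- function(X, vertex_ids = NULL) {
  if (inherits(X, "fold_simulation")) {
    if (is.null(vertex_ids)) vertex_ids <- X$vertex_ids
    X <- X$X
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("signal matrix contains non-finite values")
  if (nrow(X) < 2) stopf("need at least 2 timepoints")
  if (is.null(vertex_ids)) vertex_ids <- seq_len(ncol(X))

  mu <- colMeans(X)
  sds <- sqrt(colMeans(X^2) - mu^2)
  keep <- sds > 1e-12
  if (!any(keep)) stopf("all columns have zero variance")
  Xn <- sweep(X[, keep, drop = FALSE], 2, mu[keep], "-")
  Xn <- sweep(Xn, 2, sds[keep], "/")
  structure(
    list(X = Xn, vertex_ids = vertex_ids[keep],
         excluded_ids = vertex_ids[!keep]),
    class = "fold_signals")
}

#' @export
print.fold_signals <- function(x, ...) {
  cat(sprintf("fold_signals: %d timepoints x %d vertices (%d excluded)\n",
              nrow(x$X), ncol(x$X), length(x$excluded_ids)))
  invisible(x)
}

signal_matrix <- function(x) {
  if (inherits(x, "fold_signals")) x$X
  else if (inherits(x, "fold_simulation")) x$X
  else as.matrix(x)
}
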