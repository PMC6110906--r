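#' Per-vertex signal representation accuracy
#'
#' For every retained vertex, the Pearson correlation between its
#' (normalized) signal and its sparse reconstruction `D alpha_v`. Vertices
#' whose reconstruction is constant (typically an all-zero code) have
#' undefined accuracy; they are recorded as NA and excluded downstream,
#' with their ids reported. Raw correlations are kept, including negative
#' values.
#'
#' @param signals a `fold_signals` (or t x n matrix).
#' @param D dictionary (t x m matrix or `fold_decomposition`; when a
#'   decomposition is given `alpha` defaults to its codes).
#' @param alpha m x n coefficient matrix.
#' @return object of class `fold_accuracy`: list with `P` (per-vertex
#'   accuracy, NA where undefined), `vertex_ids`, `undefined_ids`.
#' @export
representation_accuracy <- function(signals, D, alpha = NULL) {
  if (inherits(D, "fold_decomposition") && is.null(alpha)) alpha <- D$alpha
  X <- signal_matrix(signals)
  vertex_ids <- if (inherits(signals, "fold_signals")) signals$vertex_ids
                else seq_len(ncol(X))
  Xhat <- reconstruct(D, alpha)
  if (!all(dim(Xhat) == dim(X))) stopf("inconsistent shapes")

  cx <- sweep(X, 2, colMeans(X), "-")
  cy <- sweep(Xhat, 2, colMeans(Xhat), "-")
  sx <- sqrt(colSums(cx^2))
  sy <- sqrt(colSums(cy^2))
  ok <- sx > 1e-12 & sy > 1e-12
  if (!any(ok)) stopf("all reconstructions are constant; accuracy undefined")
  P <- rep(NA_real_, ncol(X))
  P[ok] <- colSums(cx[, ok, drop = FALSE] * cy[, ok, drop = FALSE]) /
    (sx[ok] * sy[ok])
  structure(list(P = P, vertex_ids = vertex_ids,
                 undefined_ids = vertex_ids[!ok]),
            class = "fold_accuracy")
}

#' @export
print.fold_accuracy <- function(x, ...) {
  cat(sprintf("fold_accuracy: %d vertices, mean P = %.3f (%d undefined)\n",
              length(x$vertex_ids), mean(x$P, na.rm = TRUE),
              length(x$undefined_ids)))
  invisible(x)
}

#' Collect gyral and sulcal accuracy values for one region
#'
#' Restricts an accuracy map to a region of interest, splits the region's
#' retained vertices by the gyrus/sulcus partition, and collects the two
#' accuracy multisets. Vertices with undefined accuracy are dropped with
#' a count. A region whose gyral or sulcal group comes back empty is
#' flagged; the statistics stage decides how to handle it.
#'
#' @param acc a `fold_accuracy`.
#' @param roi integer vertex ids of the region.
#' @param partition list with `gyri`/`sulci` vertex ids (see
#'   [partition_by_curvature()]).
#' @param roi_id label for the region.
#' @return list of class `fold_roi_accuracy` with `roi_id`, `V_gyri`,
#'   `V_sulci`, `P_gyri`, `P_sulci`, `n_dropped`, `flagged`.
#' @export
collect_roi_accuracy <- function(acc, roi, partition, roi_id = "roi") {
  stopifnot(inherits(acc, "fold_accuracy"))
  idx <- match(roi, acc$vertex_ids)
  present <- !is.na(idx)
  Pv <- rep(NA_real_, length(roi))
  Pv[present] <- acc$P[idx[present]]
  defined <- !is.na(Pv)
  n_dropped <- sum(!defined)

  gy <- roi %in% partition$gyri & defined
  su <- roi %in% partition$sulci & defined
  out <- list(roi_id = roi_id,
              V_gyri = roi[gy], V_sulci = roi[su],
              P_gyri = Pv[gy], P_sulci = Pv[su],
              n_dropped = n_dropped,
              flagged = !any(gy) || !any(su))
  structure(out, class = "fold_roi_accuracy")
}

#' Summarize gyral/sulcal accuracy across regions
#'
#' Per-region means, standard deviations and group sizes plus a pooled
#' row (all regions' vertices together). The pooled mean equals the
#' size-weighted average of the region means.
#'
#' @param rois list of `fold_roi_accuracy` objects.
#' @return data.frame with one row per region plus a `"pooled"` row:
#'   `roi_id`, `mean_gyri`, `mean_sulci`, `sd_gyri`, `sd_sulci`,
#'   `n_gyri`, `n_sulci`.
#' @export
summarize_network <- function(rois) {
  if (length(rois) < 1) stopf("need at least one region")
  row1 <- function(id, pg, ps) data.frame(
    roi_id = id,
    mean_gyri = if (length(pg)) mean(pg) else NA_real_,
    mean_sulci = if (length(ps)) mean(ps) else NA_real_,
    sd_gyri = if (length(pg) > 1) sd(pg) else NA_real_,
    sd_sulci = if (length(ps) > 1) sd(ps) else NA_real_,
    n_gyri = length(pg), n_sulci = length(ps))
  per <- do.call(rbind, lapply(rois, function(r)
    row1(r$roi_id, r$P_gyri, r$P_sulci)))
  pooled <- row1("pooled",
                 unlist(lapply(rois, `[[`, "P_gyri")),
                 unlist(lapply(rois, `[[`, "P_sulci")))
  rbind(per, pooled)
}
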