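# Plain-text persistence for every pipeline artifact. All vertex indices
# are 1-based. Tab-separated tables for matrices, JSON for structured
# metadata (templates, ground truth, config, reports).

#' Write / read a surface mesh as plain-text tables
#'
#' Produces `<prefix>_vertices.tsv` (x, y, z, pcurv) and
#' `<prefix>_faces.tsv` (v1, v2, v3; 1-based).
#'
#' @param mesh a `fold_mesh`.
#' @param prefix file path prefix.
#' @return `write_mesh` the prefix, invisibly; `read_mesh` a `fold_mesh`
#'   (generating parameters are not round-tripped).
#' @export
write_mesh <- function(mesh, prefix) {
  vt <- data.frame(mesh$coords, pcurv = mesh$pcurv)
  names(vt) <- c("x", "y", "z", "pcurv")
  write.table(vt, paste0(prefix, "_vertices.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ft <- as.data.frame(mesh$faces)
  names(ft) <- c("v1", "v2", "v3")
  write.table(ft, paste0(prefix, "_faces.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(prefix) {
  vt <- read.delim(paste0(prefix, "_vertices.tsv"))
  ft <- as.matrix(read.delim(paste0(prefix, "_faces.tsv")))
  colnames(ft) <- NULL
  structure(list(coords = as.matrix(vt[, c("x", "y", "z")]),
                 faces = ft, pcurv = vt$pcurv,
                 nx = NA_integer_, ny = NA_integer_,
                 fold_period = NA_real_, spacing = NA_real_),
            class = "fold_mesh")
}

#' Write / read a signal matrix as TSV with a vertex-id header row
#'
#' Columns are vertices (header = vertex id), rows are timepoints.
#'
#' @param X t x n matrix or `fold_signals`.
#' @param path output file.
#' @param vertex_ids column ids (default from the object or `1:n`).
#' @return `read_signal_matrix` returns a list with `X` and `vertex_ids`.
#' @export
write_signal_matrix <- function(X, path, vertex_ids = NULL) {
  if (inherits(X, "fold_signals")) {
    if (is.null(vertex_ids)) vertex_ids <- X$vertex_ids
    X <- X$X
  }
  if (is.null(vertex_ids)) vertex_ids <- seq_len(ncol(X))
  df <- as.data.frame(X)
  names(df) <- paste0("v", vertex_ids)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ids <- as.integer(sub("^v", "", names(df)))
  X <- as.matrix(df)
  dimnames(X) <- NULL
  list(X = X, vertex_ids = ids)
}

#' Write / read network templates as JSON vertex-index lists
#'
#' @param templates a `fold_templates`.
#' @param path output file.
#' @export
write_templates <- function(templates, path) {
  payload <- lapply(templates, function(nt)
    list(id = nt$id, rois = lapply(nt$rois, as.integer)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  nets <- lapply(payload, function(nt) {
    rois <- lapply(nt$rois, function(r) as.integer(unlist(r)))
    list(id = nt$id, vertices = sort(unique(unlist(rois))), rois = rois)
  })
  structure(nets, class = "fold_templates")
}

#' Write / read a decomposition (dictionary + codes) as TSV + JSON sidecar
#'
#' `<prefix>_D.tsv`, `<prefix>_alpha.tsv` and `<prefix>_meta.json`
#' (m, lambda, seed, learning parameters, vertex ids).
#'
#' @param decomp a `fold_decomposition`.
#' @param prefix file path prefix.
#' @export
write_decomposition <- function(decomp, prefix) {
  write.table(decomp$D, paste0(prefix, "_D.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(decomp$alpha, paste0(prefix, "_alpha.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- decomp[c("m", "lambda", "n_iter", "batch_size", "seed",
                   "vertex_ids", "objective_initial", "objective_final",
                   "objective_trace", "reseeded")]
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(prefix) {
  D <- as.matrix(read.delim(paste0(prefix, "_D.tsv"), header = FALSE))
  alpha <- as.matrix(read.delim(paste0(prefix, "_alpha.tsv"), header = FALSE))
  dimnames(D) <- dimnames(alpha) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(c(list(D = D, alpha = alpha), meta),
            class = "fold_decomposition")
}

#' Write an accuracy map as CSV
#'
#' One row per retained vertex: `vertex_id`, `pcurv`, `roi_id` (NA when
#' outside every analyzed region), `gyral` flag and accuracy `P`.
#'
#' @param acc a `fold_accuracy`.
#' @param mesh the `fold_mesh` providing curvature.
#' @param path output file.
#' @param roi_labels optional per-vertex region labels (full-mesh length).
#' @export
write_accuracy <- function(acc, mesh, path, roi_labels = NULL) {
  ids <- acc$vertex_ids
  df <- data.frame(vertex_id = ids,
                   pcurv = mesh$pcurv[ids],
                   roi_id = if (is.null(roi_labels)) NA else roi_labels[ids],
                   gyral = mesh$pcurv[ids] >= 0,
                   P = acc$P)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
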