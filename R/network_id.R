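#' Spatial maps from a coefficient matrix
#'
#' Each row of the sparse coefficient matrix, aligned back to vertex ids,
#' is one atom's spatial map: the per-vertex loading on that temporal
#' basis signal.
#'
#' @param codes a `fold_decomposition` or m x n coefficient matrix.
#' @param vertex_ids ids for the n columns (defaults to those stored in
#'   the decomposition, else `1:n`).
#' @return list of `fold_map` objects (`atom_index`, `values`,
#'   `vertex_ids`).
#' @export
extract_spatial_maps <- function(codes, vertex_ids = NULL) {
  alpha <- if (inherits(codes, "fold_decomposition")) codes$alpha
           else as.matrix(codes)
  if (is.null(vertex_ids))
    vertex_ids <- if (inherits(codes, "fold_decomposition")) codes$vertex_ids
                  else seq_len(ncol(alpha))
  lapply(seq_len(nrow(alpha)), function(k)
    structure(list(atom_index = k, values = alpha[k, ],
                   vertex_ids = vertex_ids),
              class = "fold_map"))
}

#' Binarize a spatial map into a vertex set
#'
#' Two rules are provided. `"nonzero"` (default, suited to sparse codes
#' which already zero-out irrelevant vertices): vertices with a nonzero
#' loading. `"z"` (for dense maps): vertices whose loading, z-scored over
#' the map's nonzero support, exceeds `tau`.
#'
#' @param map a `fold_map` (or a plain numeric vector).
#' @param rule `"nonzero"` or `"z"`.
#' @param tau z threshold for the `"z"` rule.
#' @return integer vector of vertex ids (possibly empty).
#' @export
binarize_map <- function(map, rule = c("nonzero", "z"), tau = 2) {
  rule <- match.arg(rule)
  if (inherits(map, "fold_map")) {
    values <- map$values; ids <- map$vertex_ids
  } else {
    values <- as.numeric(map); ids <- seq_along(values)
  }
  nz <- which(values != 0)
  if (rule == "nonzero") return(ids[nz])
  if (length(nz) < 2) return(integer(0))
  v <- values[nz]
  s <- sd(v)
  if (s < 1e-12) return(integer(0))
  ids[nz][(v - mean(v)) / s > tau]
}

#' Overlap rate between a candidate vertex set and a template
#'
#' `R(S, T) = |intersect(S, T)| / |T|`: the fraction of the template
#' covered by the candidate set. Equals 1 exactly when the template is
#' contained in the set, and is monotone under growing `S`.
#'
#' @param S candidate vertex set (integer ids).
#' @param T_set template vertex set (nonempty).
#' @return real in \[0, 1\].
#' @export
overlap_rate <- function(S, T_set) {
  if (length(T_set) == 0) stopf("template set is empty (undefined denominator)")
  length(intersect(S, T_set)) / length(unique(T_set))
}

#' Identify intrinsic networks by maximal template overlap
#'
#' For every template, binarizes each atom's spatial map and selects the
#' atom with the highest overlap rate; ties go to the lower atom index.
#' One atom may match several templates. A template for which every atom
#' scores 0 is still reported, with `flagged = TRUE`.
#'
#' @param maps list of `fold_map` (see [extract_spatial_maps()]).
#' @param templates `fold_templates` or list of template vertex sets.
#' @param rule,tau binarization rule passed to [binarize_map()].
#' @return data.frame with columns `template_id`, `atom_index`, `R`,
#'   `size_S`, `size_T`, `flagged`.
#' @export
match_networks <- function(maps, templates, rule = "nonzero", tau = 2) {
  sets <- template_sets(templates)
  if (length(sets) < 1) stopf("need at least one template")
  ids <- template_ids(templates)
  S_list <- lapply(maps, binarize_map, rule = rule, tau = tau)
  res <- lapply(seq_along(sets), function(i) {
    R <- vapply(S_list, overlap_rate, numeric(1), T_set = sets[[i]])
    cands <- which(R == max(R))
    atom_idx <- vapply(maps[cands], function(m) m$atom_index, numeric(1))
    best <- cands[which.min(atom_idx)]  # ties: lowest atom index wins
    if (R[best] == 0)
      warning(sprintf("template '%s' matched with R = 0", ids[i]))
    data.frame(template_id = ids[i],
               atom_index = maps[[best]]$atom_index,
               R = R[best],
               size_S = length(S_list[[best]]),
               size_T = length(unique(sets[[i]])),
               flagged = R[best] == 0)
  })
  do.call(rbind, res)
}

#' Map volume-space points to their nearest surface vertices
#'
#' Assigns each voxel center to the Euclidean-nearest mesh vertex (3D
#' coordinates); exact distance ties go to the lower vertex index. Used
#' to carry volume-space network membership onto the cortical surface.
#'
#' @param voxel_centers k x 3 matrix of mm coordinates (zero rows give an
#'   empty set).
#' @param mesh a `fold_mesh`.
#' @return sorted integer vector of the assigned vertices (union).
#' @export
map_volume_to_surface <- function(voxel_centers, mesh) {
  stopifnot(inherits(mesh, "fold_mesh"))
  if (n_vertices(mesh) == 0) stopf("mesh has no vertices")
  V <- as.matrix(voxel_centers)
  if (length(V) == 0) return(integer(0))
  if (ncol(V) != 3) stopf("`voxel_centers` must be k x 3")
  tco <- t(mesh$coords)
  assigned <- vapply(seq_len(nrow(V)), function(i) {
    which.min(colSums((tco - V[i, ])^2))  # first minimum = lowest index
  }, integer(1))
  sort(unique(assigned))
}
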