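#' Plant disjoint multi-region network templates on a folded sheet
#'
#' Each network is the union of `rois_per_network` disjoint circular
#' regions (balls in sheet x-y distance) around randomly seeded centers.
#' Centers are kept at least `2 * radius` apart (plus a small guard) so
#' regions never share a vertex, and every region is required to contain
#' both gyral and sulcal vertices (guaranteed geometrically whenever
#' `radius >= fold_period / 2`). Placement is by bounded rejection
#' sampling; if the sheet cannot host the requested regions an error is
#' raised.
#'
#' @param mesh a `fold_mesh`.
#' @param k number of networks (>= 1).
#' @param rois_per_network regions per network.
#' @param radius region radius in mm (> 0).
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param max_tries proposal budget for rejection sampling.
#' @return object of class `fold_templates`: a list of `k` networks, each
#'   a list with `id`, `vertices` (sorted union, 1-based) and `rois`
#'   (list of per-region vertex index vectors).
#' @export
make_network_templates <- function(mesh, k, rois_per_network = 2, radius = 4,
                                   seed = 1, max_tries = 5000) {
  stopifnot(inherits(mesh, "fold_mesh"))
  if (!is.numeric(k) || k < 1) stopf("`k` must be >= 1")
  assert_scalar_num(radius, "radius", 0, strict = TRUE)
  k <- as.integer(k); rois_per_network <- as.integer(rois_per_network)
  xy <- mesh$coords[, 1:2, drop = FALSE]
  n_total <- k * rois_per_network

  withr::with_seed(as.integer(seed), {
    # candidate centers: vertices whose ball stays inside the sheet when
    # the sheet is wide enough, otherwise any vertex
    lo <- apply(xy, 2, min); hi <- apply(xy, 2, max)
    inside <- xy[, 1] >= lo[1] + radius & xy[, 1] <= hi[1] - radius &
              xy[, 2] >= lo[2] + radius & xy[, 2] <= hi[2] - radius
    candidates <- which(if (any(inside)) inside else rep(TRUE, nrow(xy)))

    centers <- integer(0)
    tries <- 0L
    stuck <- 0L
    while (length(centers) < n_total && tries < max_tries) {
      tries <- tries + 1L
      if (stuck > 200L) {  # greedy accumulation wedged: restart placement
        centers <- integer(0)
        stuck <- 0L
      }
      cand <- sample(candidates, 1L)
      if (length(centers)) {
        d <- sqrt(colSums((t(xy[centers, , drop = FALSE]) - xy[cand, ])^2))
        if (min(d) <= 2 * radius + 1e-9) {
          stuck <- stuck + 1L
          next
        }
      }
      ball <- ball_vertices(xy, xy[cand, ], radius)
      # a ball of radius >= fold_period / 2 always spans a full half
      # period, so both phases can and must be present; smaller balls
      # (down to singletons) are accepted as-is
      need_both <- isTRUE(radius >= mesh$fold_period / 2)
      pc <- mesh$pcurv[ball]
      if (need_both && (!any(pc >= 0) || !any(pc < 0))) next
      centers <- c(centers, cand)
      stuck <- 0L
    }
    if (length(centers) < n_total)
      stopf("could not place %d disjoint regions of radius %g after %d tries",
            n_total, radius, max_tries)

    nets <- lapply(seq_len(k), function(i) {
      idx <- ((i - 1L) * rois_per_network + 1L):(i * rois_per_network)
      rois <- lapply(centers[idx], function(cv)
        sort(ball_vertices(xy, xy[cv, ], radius)))
      list(id = paste0("net", i),
           vertices = sort(unique(unlist(rois))),
           rois = rois)
    })
    structure(nets, class = "fold_templates")
  })
}

# vertices within `radius` (sheet x-y Euclidean distance) of point `center`
ball_vertices <- function(xy, center, radius) {
  which((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2 <= radius^2 + 1e-12)
}

#' @export
print.fold_templates <- function(x, ...) {
  cat(sprintf("fold_templates: %d networks\n", length(x)))
  for (nt in x)
    cat(sprintf("  %s: %d vertices in %d regions\n",
                nt$id, length(nt$vertices), length(nt$rois)))
  invisible(x)
}

# accept either fold_templates or a bare list of vertex index vectors
template_sets <- function(templates) {
  if (inherits(templates, "fold_templates"))
    lapply(templates, function(nt) nt$vertices)
  else lapply(templates, as.integer)
}

template_ids <- function(templates) {
  if (inherits(templates, "fold_templates"))
    vapply(templates, function(nt) nt$id, character(1))
  else if (!is.null(names(templates)) && all(nzchar(names(templates))))
    names(templates)
  else paste0("net", seq_along(templates))
}
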