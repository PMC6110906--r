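#' Generate a synthetic folded cortical sheet
#'
#' Builds a rectangular triangulated surface whose height (and signed
#' principal curvature) follows `sin(2*pi*x / fold_period)`, so gyral
#' crests (curvature >= 0) and sulcal fundi (curvature < 0) alternate as
#' stripes along the x axis. The curvature field is the analytic sine
#' value, not an estimate from the discrete mesh, so tests are free of
#' discretization noise.
#'
#' @param nx,ny grid dimensions (>= 4 each).
#' @param fold_period spatial period of the folding pattern in mm.
#' @param spacing vertex spacing in mm; defaults to `fold_period / 8` so
#'   both fold phases are well sampled.
#' @return An object of class `fold_mesh`: list with `coords` (n x 3
#'   matrix, mm), `faces` (triangle matrix of 1-based vertex indices),
#'   `pcurv` (signed per-vertex curvature), and the generating parameters.
#' @examples
#' mesh <- make_surface(16, 16, fold_period = 8)
#' table(mesh$pcurv >= 0)
#' @export
make_surface <- function(nx, ny, fold_period = 8, spacing = fold_period / 8) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 4 || ny < 4)
    stopf("`nx` and `ny` must be >= 4")
  assert_scalar_num(fold_period, "fold_period", 0, strict = TRUE)
  assert_scalar_num(spacing, "spacing", 0, strict = TRUE)
  nx <- as.integer(nx); ny <- as.integer(ny)

  x <- rep((seq_len(nx) - 1L) * spacing, times = ny)
  y <- rep((seq_len(ny) - 1L) * spacing, each = nx)
  z <- sin(2 * pi * x / fold_period)
  coords <- cbind(x = x, y = y, z = z)

  # two triangles per grid cell, counter-clockwise
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  colnames(faces) <- NULL

  structure(
    list(coords = coords, faces = faces, pcurv = z,
         nx = nx, ny = ny, fold_period = fold_period, spacing = spacing),
    class = "fold_mesh")
}

#' @export
print.fold_mesh <- function(x, ...) {
  cat(sprintf(
    "fold_mesh: %d vertices, %d faces, fold period %.3g mm (%d gyral / %d sulcal)\n",
    nrow(x$coords), nrow(x$faces), x$fold_period,
    sum(x$pcurv >= 0), sum(x$pcurv < 0)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$coords)

#' Partition vertices into gyral and sulcal groups by curvature sign
#'
#' Applies the curvature rule used throughout the pipeline: vertices with
#' principal curvature >= 0 are gyral (the boundary value 0 is assigned to
#' gyri), vertices with curvature < 0 are sulcal. The two groups are
#' disjoint and exhaust the input set.
#'
#' @param mesh a `fold_mesh` (or any list with a `pcurv` vector).
#' @param vertices integer vertex indices to partition; defaults to all.
#' @return list with integer vectors `gyri` and `sulci`.
#' @export
partition_by_curvature <- function(mesh, vertices = seq_along(mesh$pcurv)) {
  pc <- mesh$pcurv[vertices]
  if (anyNA(pc)) stopf("all vertices must have curvature values")
  list(gyri = vertices[pc >= 0], sulci = vertices[pc < 0])
}
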