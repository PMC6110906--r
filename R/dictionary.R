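#' L1-regularized sparse coding against a fixed dictionary
#'
#' Solves, for every column x of `x`,
#' `argmin_a 0.5 * ||x - D a||_2^2 + lambda * ||a||_1`
#' by cyclic coordinate descent on the Gram matrix (compiled kernel).
#' Solutions satisfy the lasso KKT conditions to high precision (see
#' [kkt_residual()]).
#'
#' @param x length-t signal vector or t x n matrix.
#' @param D t x m dictionary matrix (or a `fold_dictionary`).
#' @param lambda nonnegative sparsity weight.
#' @param max_sweeps,tol coordinate-descent iteration cap and convergence
#'   tolerance on the largest per-sweep coefficient change.
#' @return length-m vector (vector input) or m x n matrix of coefficients.
#' @export
sparse_code <- function(x, D, lambda, max_sweeps = 2000, tol = 1e-10) {
  D <- dict_matrix(D)
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, ncol = 1) else as.matrix(x)
  if (!all(is.finite(X))) stopf("`x` contains non-finite values")
  if (nrow(X) != nrow(D))
    stopf("dimension mismatch: x has %d rows, D has %d", nrow(X), nrow(D))
  if (lambda < 0) stopf("`lambda` must be >= 0")
  G <- crossprod(D)
  C <- crossprod(D, X)
  alpha <- cd_lasso(G, C, lambda, matrix(0, ncol(D), ncol(X)),
                    as.integer(max_sweeps), tol)
  if (vec_in) drop(alpha) else alpha
}

#' Lasso KKT residual of a sparse code
#'
#' For residual res = x - D a, active coefficients must satisfy
#' d_i'res = lambda * sign(a_i) and inactive ones |d_i'res| <= lambda.
#' Returns the largest violation across all atoms (and columns).
#'
#' @inheritParams sparse_code
#' @param alpha coefficients as returned by [sparse_code()].
#' @return nonnegative scalar.
#' @export
kkt_residual <- function(x, D, alpha, lambda) {
  D <- dict_matrix(D)
  X <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  A <- if (is.null(dim(alpha))) matrix(alpha, ncol = 1) else as.matrix(alpha)
  Dtr <- crossprod(D, X - D %*% A)
  active <- A != 0
  viol_active <- abs(Dtr[active] - lambda * sign(A[active]))
  viol_inactive <- pmax(abs(Dtr[!active]) - lambda, 0)
  max(c(0, viol_active, viol_inactive))
}

#' Online dictionary learning with sparse coding
#'
#' Factorizes `X ~ D alpha` with atoms constrained to the unit ball
#' (`||d_i||_2 <= 1`) and L1-sparse coefficients. The learner is the
#' classic online scheme: atoms are initialized from randomly chosen data
#' columns scaled to unit norm; each mini-batch is sparse coded against
#' the current dictionary; accumulated sufficient statistics
#' (`A += alpha alpha'`, `B += X alpha'`) drive a block coordinate-descent
#' atom update with projection onto the unit ball. Atoms unused for a full
#' epoch are re-seeded from the currently worst-reconstructed signal.
#' After the final epoch the whole matrix is re-coded against the finished
#' dictionary. Deterministic given `seed`.
#'
#' @param X a `fold_signals` (normalized signals) or plain t x n matrix.
#' @param m number of atoms (default 50; a whole-brain-scale analysis
#'   uses m = 400).
#' @param lambda L1 weight (default 1.5, appropriate for unit-variance
#'   signals of a few hundred timepoints).
#' @param n_iter epochs over the data.
#' @param batch_size mini-batch size.
#' @param seed integer seed (initialization and batch order).
#' @return object of class `fold_decomposition`: list with `D` (t x m,
#'   every atom norm <= 1), `alpha` (m x n), `lambda`, `vertex_ids`,
#'   `objective_initial`, `objective_final`, `objective_trace` (one
#'   subsampled objective value per epoch), `reseeded` (dead-atom reseed
#'   count) and the learning parameters.
#' @export
learn_dictionary <- function(X, m = 50, lambda = 1.5, n_iter = 10,
                             batch_size = 256, seed = 1) {
  vertex_ids <- if (inherits(X, "fold_signals")) X$vertex_ids else NULL
  Xm <- signal_matrix(X)
  if (!all(is.finite(Xm))) stopf("non-finite values in input")
  t_len <- nrow(Xm); n <- ncol(Xm)
  if (m < 2) stopf("`m` must be >= 2")
  if (is.null(vertex_ids)) vertex_ids <- seq_len(n)
  if (m > n) warning("more atoms than signals (m > n); proceeding")
  m <- as.integer(m)

  withr::with_seed(as.integer(seed), {
    # init: distinct data columns, unit norm (pad with random atoms if m > n)
    take <- sample.int(n, min(m, n))
    D <- Xm[, take, drop = FALSE]
    if (m > n)
      D <- cbind(D, matrix(rnorm(t_len * (m - n)), t_len))
    D <- normalize_atoms(D)

    obj_init <- {
      a0 <- cd_lasso(crossprod(D), crossprod(D, Xm), lambda,
                     matrix(0, m, n), 200L, 1e-7)
      objective(Xm, D, a0, lambda)
    }

    # fixed subsample for the per-epoch objective trace
    trace_cols <- sample.int(n, min(n, 500L))
    A <- matrix(0, m, m)
    B <- matrix(0, t_len, m)
    obj_trace <- numeric(n_iter)
    reseeded <- 0L

    for (epoch in seq_len(n_iter)) {
      # decay the sufficient statistics so codes computed against stale
      # dictionaries lose influence (forgetting factor, online-learning
      # standard practice)
      A <- A * 0.5
      B <- B * 0.5
      ord <- sample.int(n)
      used <- rep(FALSE, m)
      worst_col <- NULL; worst_err <- -Inf
      for (b0 in seq(1, n, by = batch_size)) {
        cols <- ord[b0:min(b0 + batch_size - 1, n)]
        Xb <- Xm[, cols, drop = FALSE]
        ab <- cd_lasso(crossprod(D), crossprod(D, Xb), lambda,
                       matrix(0, m, length(cols)), 200L, 1e-7)
        used <- used | rowSums(ab != 0) > 0
        A <- A + tcrossprod(ab)
        B <- B + tcrossprod(Xb, ab)
        D <- update_atoms(D, A, B)
        err <- colSums((Xb - D %*% ab)^2)
        if (max(err) > worst_err) {
          worst_err <- max(err)
          worst_col <- cols[which.max(err)]
        }
      }
      dead <- which(!used)
      if (length(dead) && !is.null(worst_col)) {
        for (j in dead) {
          D[, j] <- normalize_atoms(Xm[, worst_col, drop = FALSE])
          A[j, ] <- 0; A[, j] <- 0; B[, j] <- 0
        }
        reseeded <- reseeded + length(dead)
      }
      at <- cd_lasso(crossprod(D), crossprod(D, Xm[, trace_cols, drop = FALSE]),
                     lambda, matrix(0, m, length(trace_cols)), 200L, 1e-7)
      obj_trace[epoch] <- objective(Xm[, trace_cols, drop = FALSE], D, at, lambda)
    }

    alpha <- sparse_code(Xm, D, lambda)
    structure(
      list(D = D, alpha = alpha, m = m, lambda = lambda, n_iter = n_iter,
           batch_size = batch_size, seed = as.integer(seed),
           vertex_ids = vertex_ids,
           objective_initial = obj_init,
           objective_final = objective(Xm, D, alpha, lambda),
           objective_trace = obj_trace, reseeded = reseeded),
      class = "fold_decomposition")
  })
}

# block coordinate descent over atoms on sufficient statistics, with
# projection onto the unit ball
update_atoms <- function(D, A, B) {
  for (j in seq_len(ncol(D))) {
    if (A[j, j] < 1e-12) next
    u <- D[, j] + (B[, j] - D %*% A[, j]) / A[j, j]
    D[, j] <- u / max(1, sqrt(sum(u^2)))
  }
  D
}

normalize_atoms <- function(D) {
  nrm <- sqrt(colSums(D^2))
  nrm[nrm < 1e-12] <- 1
  sweep(D, 2, nrm, "/")
}

#' @export
print.fold_decomposition <- function(x, ...) {
  cat(sprintf(
    "fold_decomposition: %d atoms x %d timepoints, lambda = %g\n", x$m,
    nrow(x$D), x$lambda))
  cat(sprintf("  objective %.4g -> %.4g; mean nonzero fraction %.3f\n",
              x$objective_initial, x$objective_final,
              mean(colMeans(x$alpha != 0))))
  invisible(x)
}

dict_matrix <- function(D) {
  if (inherits(D, "fold_decomposition")) D$D else as.matrix(D)
}

#' Sparse factorization objective
#'
#' `0.5 * ||X - D alpha||_F^2 + lambda * sum(|alpha|)`.
#'
#' @inheritParams sparse_code
#' @param alpha m x n coefficient matrix.
#' @return nonnegative scalar.
#' @export
objective <- function(X, D, alpha, lambda) {
  X <- signal_matrix(X); D <- dict_matrix(D); alpha <- as.matrix(alpha)
  if (nrow(D) != nrow(X) || ncol(D) != nrow(alpha) || ncol(alpha) != ncol(X))
    stopf("inconsistent shapes in objective()")
  0.5 * sum((X - D %*% alpha)^2) + lambda * sum(abs(alpha))
}

#' Reconstruct signals from a dictionary and codes
#'
#' @inheritParams objective
#' @return t x n matrix `D %*% alpha`.
#' @export
reconstruct <- function(D, alpha) {
  if (inherits(D, "fold_decomposition") && missing(alpha)) {
    alpha <- D$alpha; D <- D$D
  }
  D <- dict_matrix(D); alpha <- as.matrix(alpha)
  if (ncol(D) != nrow(alpha)) stopf("inconsistent shapes in reconstruct()")
  D %*% alpha
}
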