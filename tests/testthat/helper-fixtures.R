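# Shared fixtures and independent oracles. Everything here is generated
# in code; no data files.

tiny_mesh <- function(nx = 16, ny = 16, fold_period = 8)
  make_surface(nx, ny, fold_period = fold_period)

# random dictionary with orthonormal columns (t >= m)
ortho_dict <- function(t_len, m) {
  qr.Q(qr(matrix(rnorm(t_len * m), t_len)))[, seq_len(m), drop = FALSE]
}

# brute-force 1-D lasso oracle on a grid (orthonormal case is separable)
grid_lasso_1d <- function(c_i, lambda, lim = 5, step = 1e-4) {
  grid <- seq(-lim, lim, by = step)
  grid[which.min(0.5 * (c_i - grid)^2 + lambda * abs(grid))]
}

# exhaustive one-sided permutation p for a gyri/sulci mean difference
exhaustive_perm_p <- function(values, labels) {
  n1 <- sum(labels)
  obs <- mean(values[labels]) - mean(values[!labels])
  combos <- utils::combn(length(values), n1)
  diffs <- apply(combos, 2, function(idx)
    mean(values[idx]) - mean(values[-idx]))
  mean(diffs >= obs - 1e-12)
}

# greedy one-to-one atom matching by maximal |correlation|; returns the
# number of true atoms recovered above `thr`
greedy_recovered <- function(Dstar, D, thr = 0.9) {
  cc <- abs(cor(Dstar, D))
  matched <- 0L
  for (k in seq_len(nrow(cc))) {
    ij <- which(cc == max(cc), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]  # lowest index
    if (cc[ij[1], ij[2]] > thr) matched <- matched + 1L
    cc[ij[1], ] <- -1
    cc[, ij[2]] <- -1
  }
  matched
}

# planted 3-sparse synthesis model for dictionary recovery experiments
planted_sparse_data <- function(seed, t_len = 50, m = 20, n = 2000,
                                k_sparse = 3, noise_sd = 0.01) {
  set.seed(seed)
  Dstar <- matrix(rnorm(t_len * m), t_len)
  Dstar <- sweep(Dstar, 2, sqrt(colSums(Dstar^2)), "/")
  supp <- replicate(n, sample.int(m, k_sparse))
  coef <- matrix(runif(k_sparse * n, 0.5, 1.5) *
                   sample(c(-1, 1), k_sparse * n, replace = TRUE), k_sparse)
  X <- vapply(seq_len(n), function(i)
    drop(Dstar[, supp[, i], drop = FALSE] %*% coef[, i]),
    numeric(t_len)) + matrix(rnorm(t_len * n, 0, noise_sd), t_len)
  list(X = X, Dstar = Dstar)
}

# desk-scale effect configuration: package defaults (delta = 0.45
# calibrated a priori for a ~0.06 gyral-sulcal accuracy gap)
effect_config <- function(seed) fold_config(seed = seed)

# scaled-down null configuration (delta = 0) used for the 200-seed
# calibration runs; smaller mesh / learner keep the suite in budget
null_config <- function(seed)
  fold_config(seed = seed, nx = 24, ny = 24, k_networks = 2,
              rois_per_network = 2, delta = 0, m = 20, n_iter = 3,
              n_perm = 200)

# small fast pipeline config for functional tests
small_config <- function(seed, ...)
  fold_config(seed = seed, nx = 24, ny = 24, k_networks = 2,
              rois_per_network = 2, m = 20, n_iter = 2, n_perm = 100, ...)
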