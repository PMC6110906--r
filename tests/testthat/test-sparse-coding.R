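test_that("normalize_signals centers, scales and excludes constants", {
  # idempotence on an already-normalized column
  x <- c(-1, 0, 1) / sqrt(2 / 3)
  out <- normalize_signals(matrix(x, ncol = 1))
  expect_equal(out$X[, 1], x, tolerance = 1e-12)

  # closed form with population sd sqrt(2/3)
  out2 <- normalize_signals(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(out2$X[, 1], c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(out2$X[, 1], c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  # constant column excluded with its id recorded
  out3 <- normalize_signals(cbind(c(1, 2, 3), c(5, 5, 5)),
                            vertex_ids = c(10L, 20L))
  expect_identical(out3$excluded_ids, 20L)
  expect_identical(out3$vertex_ids, 10L)
  expect_equal(ncol(out3$X), 1)

  # every retained column has mean 0, population sd 1
  set.seed(1)
  big <- normalize_signals(matrix(rnorm(300), 30))
  expect_true(all(abs(colMeans(big$X)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(big$X^2)) - 1) < 1e-9))

  expect_error(normalize_signals(matrix(1, 3, 2)), "zero variance")
  expect_error(normalize_signals(matrix(c(1, NA, 3), ncol = 1)),
               "non-finite")
})

test_that("sparse_code solves the lasso (closed forms and oracles)", {
  set.seed(11)
  t_len <- 12
  D <- ortho_dict(t_len, 3)
  x <- drop(D %*% c(2, 0.3, -1))

  # lambda beyond max |d' x| forces the zero vector
  expect_equal(sparse_code(x, D, lambda = 2.5), rep(0, 3))

  # orthonormal square dictionary, lambda = 0 -> exact least squares
  Dsq <- ortho_dict(6, 6)
  xs <- rnorm(6)
  expect_equal(sparse_code(xs, Dsq, 0), drop(crossprod(Dsq, xs)),
               tolerance = 1e-10)

  # soft-thresholding closed form, checked against a grid-search oracle
  a <- sparse_code(x, D, lambda = 0.5)
  expect_equal(a, c(1.5, 0, -0.5), tolerance = 1e-8)
  oracle <- vapply(c(2, 0.3, -1), grid_lasso_1d, numeric(1), lambda = 0.5)
  expect_equal(a, oracle, tolerance = 1e-3)

  expect_error(sparse_code(rnorm(5), D, 0.1), "dimension mismatch")
  expect_error(sparse_code(x, D, -1), "lambda")
})

test_that("sparse codes satisfy lasso KKT conditions on random instances", {
  set.seed(202)
  for (i in 1:25) {
    t_len <- sample(10:40, 1)
    m <- sample(5:30, 1)
    D <- matrix(rnorm(t_len * m), t_len)
    D <- sweep(D, 2, pmax(1, sqrt(colSums(D^2))), "/")  # norms <= 1
    X <- matrix(rnorm(t_len * 3), t_len)
    lam <- runif(1, 0.05, 1)
    a <- sparse_code(X, D, lam)
    expect_lt(kkt_residual(X, D, a, lam), 1e-6)
  }
})

test_that("orthonormal-limit equivalence with soft thresholding", {
  set.seed(33)
  for (i in 1:10) {
    D <- ortho_dict(20, sample(5:20, 1))
    x <- rnorm(20)
    lam <- runif(1, 0, 1.5)
    expect_equal(sparse_code(x, D, lam),
                 drop(sign(crossprod(D, x)) *
                        pmax(abs(crossprod(D, x)) - lam, 0)),
                 tolerance = 1e-8)
  }
})

test_that("doubling lambda never increases the nonzero count", {
  set.seed(44)
  for (i in 1:8) {
    D <- matrix(rnorm(30 * 15), 30)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    x <- rnorm(30)
    nnz <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                  function(l) sum(sparse_code(x, D, l) != 0), numeric(1))
    expect_true(all(diff(nnz) <= 0))
  }
})

test_that("objective and reconstruct implement the factorization forms", {
  set.seed(5)
  X <- matrix(rnorm(12), 4)
  D <- matrix(rnorm(8), 4)
  alpha <- matrix(rnorm(6), 2)
  # alpha = 0 -> 0.5 ||X||_F^2
  expect_equal(objective(X, D, matrix(0, 2, 3), 1), 0.5 * sum(X^2))
  # exact reconstruction at lambda = 0
  expect_equal(objective(D %*% alpha, D, alpha, 0), 0)
  # hand arithmetic
  expect_equal(objective(matrix(c(1, 0), 2, 1), diag(2),
                         matrix(c(0.5, 0), 2, 1), 1), 0.625)
  expect_error(objective(X, D, matrix(0, 3, 3), 1), "shapes")

  # reconstruct: zero codes, identity dictionary, independent product check
  expect_equal(reconstruct(D, matrix(0, 2, 3)), matrix(0, 4, 3))
  expect_equal(reconstruct(diag(2), alpha), alpha)
  R3 <- matrix(rnorm(6), 3); A2 <- matrix(rnorm(4), 2)
  manual <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) manual[i, j] <- sum(R3[i, ] * A2[, j])
  expect_equal(reconstruct(R3, A2), manual)
})

test_that("learn_dictionary respects the constraint set and descends", {
  set.seed(21)
  X <- matrix(rnorm(40 * 300), 40)
  X <- normalize_signals(X)
  fit <- learn_dictionary(X, m = 12, lambda = 0.8, n_iter = 4,
                          batch_size = 64, seed = 3)
  # Eq-2-style constraint: every atom inside the unit ball
  expect_true(all(colSums(fit$D^2) <= 1 + 1e-9))
  # descent vs the initial dictionary/codes
  expect_lte(fit$objective_final, fit$objective_initial)
  # running objective decreasing on average across epochs
  expect_lte(mean(diff(fit$objective_trace)), 1e-8)
  # final codes optimal for the final dictionary
  expect_lt(kkt_residual(X$X, fit$D, fit$alpha, fit$lambda), 1e-6)
  # determinism
  fit2 <- learn_dictionary(X, m = 12, lambda = 0.8, n_iter = 4,
                           batch_size = 64, seed = 3)
  expect_identical(fit$D, fit2$D)
  expect_identical(fit$alpha, fit2$alpha)

  expect_warning(learn_dictionary(matrix(rnorm(40), 10), m = 6, lambda = 0.1,
                                  n_iter = 1, seed = 1), "m > n")
  expect_error(learn_dictionary(matrix(NA_real_, 4, 8), m = 2, lambda = 1),
               "non-finite")
})

test_that("column sparsity stays below one half at the default lambda", {
  mesh <- make_surface(24, 24)
  tpl <- make_network_templates(mesh, 2, rois_per_network = 2, radius = 4,
                                seed = 1)
  sim <- simulate_signals(mesh, tpl, make_paradigm(),
                          ground_truth(tpl, seed = 2))
  sig <- normalize_signals(sim)
  fit <- learn_dictionary(sig, m = 20, lambda = 1.5, n_iter = 3, seed = 5)
  expect_lt(mean(colMeans(fit$alpha != 0)), 0.5)
})
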