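#' Bundle ground-truth parameters for signal simulation
#'
#' @param templates planted networks (`fold_templates` or list of vertex
#'   index vectors).
#' @param delta amplitude of the sulcus-specific nuisance component
#'   (>= 0). `delta = 0` makes gyral and sulcal in-network signals
#'   exchangeable.
#' @param sigma white-noise standard deviation (>= 0).
#' @param seed integer seed; all simulation randomness derives from it.
#' @param loading_range range of the per-vertex network loading `w`,
#'   drawn uniformly; use `c(w, w)` for a fixed loading.
#' @param task_weight mixing weight of the HRF-convolved task regressor in
#'   each network time course (the rest is low-pass intrinsic
#'   fluctuation, cutoff 0.1 Hz).
#' @return object of class `fold_truth`.
#' @export
ground_truth <- function(templates, delta = 0.45, sigma = 0.5, seed = 1,
                         loading_range = c(0.8, 1.2), task_weight = 0.5) {
  assert_scalar_num(delta, "delta", 0)
  assert_scalar_num(sigma, "sigma", 0)
  stopifnot(length(loading_range) == 2, loading_range[1] <= loading_range[2],
            loading_range[1] >= 0, task_weight >= 0, task_weight <= 1)
  structure(
    list(template_sets = template_sets(templates),
         template_ids = template_ids(templates),
         delta = delta, sigma = sigma, seed = as.integer(seed),
         loading_range = loading_range, task_weight = task_weight,
         atom_timecourses = NULL, network_loadings = NULL),
    class = "fold_truth")
}

# low-pass filtered standard-normal series (hard FFT cutoff), unit variance
lowpass_noise <- function(n, tr, cutoff = 0.1) {
  x <- rnorm(n)
  f <- fft(x)
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * tr)
  f[freq > cutoff] <- 0
  standardize(Re(fft(f, inverse = TRUE)) / n)
}

#' Simulate task fMRI signals on a folded sheet
#'
#' Implements the generative model the analysis assumes. Every vertex `v`
#' of planted network `k` receives
#' `x_v = w_v * a_k + s_v * eta_v + sigma * eps_v`, where `a_k` is the
#' network's shared unit-variance time course (HRF-convolved task blocks
#' mixed with low-pass intrinsic fluctuation), `eta_v` is a vertex-specific
#' standard-normal nuisance series whose amplitude `s_v` equals
#' `truth$delta` on sulcal vertices (curvature < 0) and 0 on gyral ones,
#' and `eps_v` is white noise. Background vertices receive noise only.
#' Under independence the population correlation between `x_v` and `a_k`
#' is `w / sqrt(w^2 + s^2 + sigma^2)`, which is the closed-form
#' "representability" the generator also returns.
#'
#' The nuisance series is drawn for every in-network vertex whether or not
#' its amplitude is zero, so with `delta = 0` the output is literally
#' invariant to relabeling gyri and sulci.
#'
#' @param mesh a `fold_mesh`.
#' @param templates the planted networks (must match
#'   `truth$template_sets`).
#' @param paradigm a `fold_paradigm`.
#' @param truth a `fold_truth` from [ground_truth()].
#' @return object of class `fold_simulation`: list with `X` (t x n signal
#'   matrix), `vertex_ids`, `membership` (per-vertex network id or NA),
#'   `representability` (closed-form per-vertex value, NA on background)
#'   and the completed `truth` (loadings and time courses filled in).
#' @export
simulate_signals <- function(mesh, templates, paradigm, truth) {
  stopifnot(inherits(mesh, "fold_mesh"), inherits(paradigm, "fold_paradigm"),
            inherits(truth, "fold_truth"))
  sets <- template_sets(templates)
  if (!identical(lapply(sets, as.integer), lapply(truth$template_sets, as.integer)))
    stopf("`templates` do not match `truth$template_sets`")
  if (is.null(truth$seed)) stopf("`truth$seed` must be set")
  K <- length(sets)
  n <- n_vertices(mesh)
  t_len <- paradigm$n_volumes

  membership <- rep(NA_integer_, n)
  for (k in seq_len(K)) {
    if (any(!is.na(membership[sets[[k]]])))
      stopf("template sets must be disjoint")
    membership[sets[[k]]] <- k
  }
  in_net <- which(!is.na(membership))

  withr::with_seed(truth$seed, {
    conds <- rep(c("face", "shape"), length.out = K)
    atoms <- matrix(0, t_len, K)
    for (k in seq_len(K)) {
      task <- hrf_convolve(paradigm, conds[k])
      intr <- lowpass_noise(t_len, paradigm$tr)
      a <- if (any(task != 0))
        truth$task_weight * standardize(task) + (1 - truth$task_weight) * intr
      else intr
      atoms[, k] <- standardize(a)
    }

    w <- rep(NA_real_, n)
    w[in_net] <- runif(length(in_net), truth$loading_range[1],
                       truth$loading_range[2])

    s <- rep(0, n)
    s[in_net][mesh$pcurv[in_net] < 0] <- truth$delta

    X <- truth$sigma * matrix(rnorm(t_len * n), t_len, n)
    if (length(in_net)) {
      eta <- matrix(rnorm(t_len * length(in_net)), t_len, length(in_net))
      X[, in_net] <- X[, in_net] +
        atoms[, membership[in_net], drop = FALSE] *
          rep(w[in_net], each = t_len) +
        eta * rep(s[in_net], each = t_len)
    }

    rep_v <- rep(NA_real_, n)
    denom <- sqrt(w[in_net]^2 + s[in_net]^2 + truth$sigma^2)
    rep_v[in_net] <- ifelse(denom > 0, w[in_net] / denom, NA_real_)

    truth$atom_timecourses <- atoms
    truth$network_loadings <- w
    structure(
      list(X = X, vertex_ids = seq_len(n), membership = membership,
           representability = rep_v, truth = truth),
      class = "fold_simulation")
  })
}

#' Simulate per-vertex FA-like scalars coupled to representability
#'
#' Generates a fractional-anisotropy-like value
#' `FA_v = clamp(b0 + b1 * representability_v + noise, 0, 1)`. With
#' `b1 > 0` this emulates the empirical positive coupling between
#' white-matter fiber coherence and how well a vertex's signal is carried
#' by the shared functional basis.
#'
#' @param mesh a `fold_mesh` (used only for length validation).
#' @param representability per-vertex real (NA allowed; propagated).
#' @param b0,b1 intercept and (nonnegative) slope of the coupling.
#' @param sd noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return numeric vector in \[0, 1\] (NA where representability is NA).
#' @export
simulate_fa <- function(mesh, representability, b0 = 0.3, b1 = 0.3,
                        sd = 0.05, seed = 1) {
  if (b1 < 0) stopf("`b1` must be >= 0")
  assert_scalar_num(sd, "sd", 0)
  if (length(representability) != n_vertices(mesh))
    stopf("`representability` must have one value per vertex")
  withr::with_seed(as.integer(seed), {
    fa <- b0 + b1 * representability + rnorm(length(representability), 0, sd)
    pmin(pmax(fa, 0), 1)
  })
}
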