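test_that("make_surface produces the analytic sine curvature field", {
  mesh <- make_surface(17, 8, fold_period = 8, spacing = 1)
  # crest at x = period/4, fundus at x = 3*period/4
  crest <- which(mesh$coords[, 1] == 2)
  fundus <- which(mesh$coords[, 1] == 6)
  expect_true(all(abs(mesh$pcurv[crest] - 1) < 1e-12))
  expect_true(all(abs(mesh$pcurv[fundus] + 1) < 1e-12))

  # oracle: enumerate grid x coordinates and count curvature signs
  mesh8 <- make_surface(32, 8, fold_period = 8)  # spacing = period/8
  xs <- (0:31) * 1
  frac_oracle <- mean(rep(sin(2 * pi * xs / 8), times = 8) >= 0)
  expect_equal(mean(mesh8$pcurv >= 0), frac_oracle)
  expect_true(abs(frac_oracle - 0.5) < 0.2)  # ~half plus the pcurv = 0 line

  # mesh invariants
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$coords)))
  expect_true(all(is.finite(mesh$pcurv)))
  expect_true(any(mesh$pcurv >= 0) && any(mesh$pcurv < 0))
  expect_error(make_surface(2, 8), "nx")
  expect_error(make_surface(8, 8, fold_period = -1), "fold_period")
})

test_that("make_paradigm reproduces the emotion block design", {
  p <- make_paradigm()
  expect_identical(p$n_volumes, 176L)
  expect_equal(p$tr, 0.72)
  expect_equal(p$tr * p$n_volumes, 126.72)
  # six blocks of cue (3 s) + 6 trials x 3 s = 21 s each
  cues <- p$events[p$events$condition == "cue", ]
  tasks <- p$events[p$events$condition != "cue", ]
  expect_equal(nrow(cues), 6)
  expect_equal(sum(tasks$condition == "face"), 3)
  expect_equal(sum(tasks$condition == "shape"), 3)
  expect_equal(unique(cues$duration + 18), 21)
  expect_equal(diff(cues$onset), rep(21, 5))
  expect_true(all(p$events$onset + p$events$duration <= p$tr * p$n_volumes))
})

test_that("hrf_convolve matches the closed-form gamma impulse response", {
  # empty condition -> all zeros
  p <- make_paradigm()
  p_noface <- fold_paradigm(p$tr, p$n_volumes,
                            p$events[p$events$condition != "face", ])
  expect_equal(hrf_convolve(p_noface, "face"), rep(0, 176))
  expect_error(hrf_convolve(p, "banana"), "unknown condition")

  # 1-volume impulse at t = 0, no undershoot: equals gamma density samples
  imp <- fold_paradigm(0.72, 60,
                       data.frame(onset = 0, duration = 0.72,
                                  condition = "face"))
  got <- hrf_convolve(imp, "face", undershoot_ratio = 0)
  expect_equal(got, dgamma((0:59) * 0.72, shape = 7, rate = 1),
               tolerance = 1e-12)

  # impulse response peaks at the sample nearest 6 s (volume index 8)
  full <- hrf_convolve(imp, "face")
  expect_identical(which.max(full) - 1L, as.integer(round(6 / 0.72)))
})

test_that("planted templates are disjoint multi-phase regions", {
  mesh <- tiny_mesh(24, 24)
  # radius below vertex spacing: singleton containing only the center
  tpl1 <- make_network_templates(mesh, 1, rois_per_network = 1,
                                 radius = 0.5, seed = 3)
  expect_length(tpl1[[1]]$vertices, 1)

  tpl <- make_network_templates(mesh, 2, rois_per_network = 2, radius = 4,
                                seed = 5)
  expect_length(intersect(tpl[[1]]$vertices, tpl[[2]]$vertices), 0)
  # geometric oracle: enumerate each region, check both phases present
  for (nt in tpl) for (roi in nt$rois) {
    pc <- mesh$pcurv[roi]
    expect_true(any(pc >= 0) && any(pc < 0))
    # regions really are balls: re-derive membership from coordinates
    center <- roi[which.min(
      rowSums(sweep(mesh$coords[roi, 1:2], 2,
                    colMeans(mesh$coords[roi, 1:2, drop = FALSE]))^2))]
    d2 <- (mesh$coords[, 1] - mesh$coords[center, 1])^2 +
      (mesh$coords[, 2] - mesh$coords[center, 2])^2
    expect_setequal(roi, which(d2 <= 16 + 1e-9))
  }
  expect_error(
    make_network_templates(mesh, 50, rois_per_network = 4, radius = 4,
                           seed = 1, max_tries = 50),
    "could not place")
})

test_that("simulate_signals honors the additive component model", {
  mesh <- tiny_mesh()
  par <- make_paradigm()
  tpl <- make_network_templates(mesh, 1, rois_per_network = 1, radius = 4,
                                seed = 2)

  # noise-free limit: exact scalar multiple of the network time course
  tr0 <- ground_truth(tpl, delta = 0, sigma = 0, seed = 9,
                      loading_range = c(1, 1))
  sim0 <- simulate_signals(mesh, tpl, par, tr0)
  v <- tpl[[1]]$vertices[1]
  expect_equal(sim0$X[, v], sim0$truth$atom_timecourses[, 1],
               tolerance = 1e-12)
  bg <- setdiff(seq_len(nrow(mesh$coords)), tpl[[1]]$vertices)[1]
  expect_equal(sim0$X[, bg], rep(0, par$n_volumes))

  # determinism
  sim0b <- simulate_signals(mesh, tpl, par, tr0)
  expect_identical(sim0$X, sim0b$X)

  expect_error(simulate_signals(mesh, tpl, par,
                                ground_truth(tpl, delta = -1)), "delta")
})

test_that("simulated correlations match the closed form (Monte Carlo)", {
  # long resting acquisition so the sample correlation pins down the
  # population value w / sqrt(w^2 + s^2 + sigma^2)
  mesh <- tiny_mesh()
  par_long <- fold_paradigm(0.72, 20000,
                            data.frame(onset = numeric(0),
                                       duration = numeric(0),
                                       condition = character(0)))
  tpl <- make_network_templates(mesh, 1, rois_per_network = 1, radius = 4,
                                seed = 2)
  tr1 <- ground_truth(tpl, delta = 1, sigma = 0.5, seed = 11,
                      loading_range = c(1, 1))
  sim <- simulate_signals(mesh, tpl, par_long, tr1)
  part <- partition_by_curvature(mesh, tpl[[1]]$vertices)
  a <- sim$truth$atom_timecourses[, 1]
  r_sulcal <- mean(vapply(part$sulci, function(v) cor(sim$X[, v], a),
                          numeric(1)))
  r_gyral <- mean(vapply(part$gyri, function(v) cor(sim$X[, v], a),
                         numeric(1)))
  expect_equal(r_sulcal, 1 / sqrt(2.25), tolerance = 0.02)
  expect_equal(r_gyral, 1 / sqrt(1.25), tolerance = 0.02)
  # generator's own closed-form representability agrees
  expect_equal(unique(round(sim$representability[part$sulci], 10)),
               round(1 / sqrt(2.25), 10))
})

test_that("delta = 0 output is invariant to gyrus/sulcus relabeling", {
  mesh <- tiny_mesh()
  par <- make_paradigm()
  tpl <- make_network_templates(mesh, 1, rois_per_network = 1, radius = 4,
                                seed = 2)
  tr0 <- ground_truth(tpl, delta = 0, sigma = 0.5, seed = 4)
  sim1 <- simulate_signals(mesh, tpl, par, tr0)
  mesh_flipped <- mesh
  mesh_flipped$pcurv <- -mesh$pcurv - 1e-9  # flips every label
  sim2 <- simulate_signals(mesh_flipped, tpl, par, tr0)
  expect_identical(sim1$X, sim2$X)
})

test_that("population accuracy gap is nondecreasing in delta", {
  mesh <- tiny_mesh()
  par <- make_paradigm()
  tpl <- make_network_templates(mesh, 1, rois_per_network = 1, radius = 4,
                                seed = 2)
  part <- partition_by_curvature(mesh, tpl[[1]]$vertices)
  gap_at <- function(delta) {
    gaps <- vapply(1:6, function(s) {
      tr <- ground_truth(tpl, delta = delta, sigma = 0.5, seed = 100 + s,
                         loading_range = c(1, 1))
      sim <- simulate_signals(mesh, tpl, par, tr)
      a <- sim$truth$atom_timecourses[, 1]
      mean(vapply(part$gyri, function(v) cor(sim$X[, v], a), numeric(1))) -
        mean(vapply(part$sulci, function(v) cor(sim$X[, v], a), numeric(1)))
    }, numeric(1))
    mean(gaps)
  }
  gaps <- vapply(c(0, 0.5, 1, 2), gap_at, numeric(1))
  expect_true(all(diff(gaps) > -0.02))  # nondecreasing up to MC noise
  expect_lt(abs(gaps[1]), 0.02)
  expect_gt(gaps[4], gaps[1] + 0.1)
})

test_that("simulate_fa couples FA to representability and clamps", {
  mesh <- tiny_mesh()
  n <- nrow(mesh$coords)
  rep_v <- seq(0.6, 1.0, length.out = n)

  fa_exact <- simulate_fa(mesh, rep_v, b0 = 0.1, b1 = 0.5, sd = 0, seed = 1)
  expect_equal(cor(fa_exact, rep_v), 1)

  fa_flat <- simulate_fa(mesh, rep_v, b0 = 0.5, b1 = 0, sd = 0.05, seed = 1)
  expect_lt(abs(cor(fa_flat, rep_v)), 0.2)

  fa <- simulate_fa(mesh, rep_v, b0 = 0.3, b1 = 0.3, sd = 0.05, seed = 7)
  expect_true(all(fa >= 0 & fa <= 1))
  r <- cor(fa, rep_v)
  expect_gt(r, 0.3)
  expect_lt(r, 0.9)
  # determinism
  expect_identical(fa, simulate_fa(mesh, rep_v, b0 = 0.3, b1 = 0.3,
                                   sd = 0.05, seed = 7))
  expect_error(simulate_fa(mesh, rep_v, sd = -1), "sd")
  expect_error(simulate_fa(mesh, rep_v, b1 = -0.1), "b1")
})
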