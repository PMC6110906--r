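#' Pipeline configuration
#'
#' Collects every tunable of the synthetic study in one validated object.
#' Defaults are desk-scale: they run the full pipeline in seconds while
#' preserving the structure of a whole-brain analysis (where one would
#' use `m = 400` atoms over hundreds of thousands of vertices; `lambda =
#' 1.5` and `n_perm = 1000` carry over unchanged, and the paradigm is
#' always the TR = 0.72 s / 176-volume block design).
#'
#' @param seed master integer seed; every stage derives its own stream
#'   from it.
#' @param out_dir output directory for persisted artifacts, or `NULL` for
#'   an in-memory run.
#' @param nx,ny,fold_period,spacing surface geometry (see
#'   [make_surface()]).
#' @param k_networks,rois_per_network,radius planted-network layout (see
#'   [make_network_templates()]).
#' @param delta,sigma,loading_range,task_weight generative model (see
#'   [ground_truth()]). The default `delta = 0.45` is calibrated from the
#'   closed-form correlation gap to yield a gyral-sulcal accuracy gap of
#'   about 0.06.
#' @param fa_b0,fa_b1,fa_sd FA coupling (see [simulate_fa()]).
#' @param m,lambda,n_iter,batch_size learner settings (see
#'   [learn_dictionary()]).
#' @param binarize_rule,tau map binarization (see [binarize_map()]).
#' @param n_perm,alpha_level inference settings.
#' @return object of class `fold_config`.
#' @export
fold_config <- function(seed = 1, out_dir = NULL,
                        nx = 48, ny = 40, fold_period = 8, spacing = 1,
                        k_networks = 5, rois_per_network = 2, radius = 4,
                        delta = 0.45, sigma = 0.5,
                        loading_range = c(0.8, 1.2), task_weight = 0.5,
                        fa_b0 = 0.3, fa_b1 = 0.3, fa_sd = 0.05,
                        m = 50, lambda = 1.5, n_iter = 8, batch_size = 256,
                        binarize_rule = "nonzero", tau = 2,
                        n_perm = 1000, alpha_level = 0.05) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              nx = nx, ny = ny, fold_period = fold_period, spacing = spacing,
              k_networks = k_networks, rois_per_network = rois_per_network,
              radius = radius, delta = delta, sigma = sigma,
              loading_range = loading_range, task_weight = task_weight,
              fa_b0 = fa_b0, fa_b1 = fa_b1, fa_sd = fa_sd,
              m = m, lambda = lambda, n_iter = n_iter,
              batch_size = batch_size,
              binarize_rule = binarize_rule, tau = tau,
              n_perm = n_perm, alpha_level = alpha_level)
  if (is.null(cfg$seed) || is.na(cfg$seed)) stopf("`seed` is mandatory")
  assert_scalar_num(cfg$delta, "delta", 0)
  assert_scalar_num(cfg$sigma, "sigma", 0)
  structure(cfg, class = "fold_config")
}

# derived per-stage seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) as.integer((as.numeric(seed) + k * 1009) %% 2147483647)

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Save / load a pipeline configuration as JSON
#' @param config a `fold_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(fold_config, cfg[setdiff(names(cfg), character(0))])
}

stage_done_path <- function(out_dir, stage) file.path(out_dir, paste0(stage, ".done.json"))

stage_is_done <- function(out_dir, stage, hash, files) {
  dp <- stage_done_path(out_dir, stage)
  if (is.null(out_dir) || !file.exists(dp)) return(FALSE)
  done <- jsonlite::read_json(dp, simplifyVector = TRUE)
  identical(done$config_md5, unname(hash)) &&
    all(file.exists(file.path(out_dir, files)))
}

mark_stage_done <- function(out_dir, stage, hash, files) {
  if (is.null(out_dir)) return(invisible(NULL))
  paths <- file.path(out_dir, files)
  jsonlite::write_json(
    list(stage = stage, config_md5 = unname(hash),
         files = files,
         file_md5 = unname(tools::md5sum(paths))),
    stage_done_path(out_dir, stage), auto_unbox = TRUE)
  invisible(NULL)
}

#' Run the synthetic folding-pattern study end to end
#'
#' Stages: `simulate` (surface, paradigm, planted networks, signals, FA),
#' `decompose` (normalization + online dictionary learning + final sparse
#' coding), `identify` (spatial maps, binarization, template matching),
#' `assess` (per-vertex accuracy, curvature partition, per-region
#' accuracy sets) and `stats` (per-region one-tailed t-tests with
#' Bonferroni correction, per-network permutation tests, FA-accuracy
#' correlations). With `out_dir` set, every stage persists its artifacts
#' together with the config hash and is skipped on re-runs whose config
#' hash matches.
#'
#' @param config a `fold_config`.
#' @param stages character vector of stages to run (in pipeline order).
#' @return a `fold_report`: list with the config echo, per-stage status,
#'   `matches` (template match table), `summaries` (per-network accuracy
#'   tables), `roi_tests`, `network_tests`, `fa_tests` and exclusion /
#'   degeneracy logs.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "decompose", "identify",
                                    "assess", "stats")) {
  stopifnot(inherits(config, "fold_config"))
  all_stages <- c("simulate", "decompose", "identify", "assess", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  if (!is.null(out_dir)) write_config(config, file.path(out_dir, "config.json"))
  status <- list()
  st <- new.env(parent = emptyenv())

  run_stage <- function(name, files, compute, load) {
    if (!(name %in% stages)) {
      # stage not requested: load artifacts if a later stage needs them
      if (!is.null(out_dir) && all(file.exists(file.path(out_dir, files))))
        load()
      status[[name]] <<- "not-run"
      return(invisible(NULL))
    }
    if (!is.null(out_dir) && stage_is_done(out_dir, name, hash, files)) {
      load()
      status[[name]] <<- "skipped (up to date)"
      return(invisible(NULL))
    }
    compute()
    mark_stage_done(out_dir, name, hash, files)
    status[[name]] <<- "ran"
    invisible(NULL)
  }

  ## -- simulate ------------------------------------------------------------
  sim_files <- c("mesh_vertices.tsv", "mesh_faces.tsv", "templates.json",
                 "signals.tsv", "truth.json", "fa.tsv")
  run_stage("simulate", sim_files, compute = function() {
    st$mesh <- make_surface(config$nx, config$ny, config$fold_period,
                            config$spacing)
    st$paradigm <- make_paradigm()
    st$templates <- make_network_templates(
      st$mesh, config$k_networks, config$rois_per_network, config$radius,
      seed = derive_seed(config$seed, 1))
    truth <- ground_truth(st$templates, delta = config$delta,
                          sigma = config$sigma,
                          seed = derive_seed(config$seed, 2),
                          loading_range = config$loading_range,
                          task_weight = config$task_weight)
    st$sim <- simulate_signals(st$mesh, st$templates, st$paradigm, truth)
    st$fa <- simulate_fa(st$mesh, st$sim$representability,
                         b0 = config$fa_b0, b1 = config$fa_b1,
                         sd = config$fa_sd, seed = derive_seed(config$seed, 3))
    if (!is.null(out_dir)) {
      write_mesh(st$mesh, file.path(out_dir, "mesh"))
      write_templates(st$templates, file.path(out_dir, "templates.json"))
      write_signal_matrix(st$sim$X, file.path(out_dir, "signals.tsv"))
      jsonlite::write_json(
        list(seed = st$sim$truth$seed, delta = config$delta,
             sigma = config$sigma,
             loadings = st$sim$truth$network_loadings,
             membership = st$sim$membership,
             representability = st$sim$representability),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      write.table(data.frame(vertex_id = st$sim$vertex_ids, fa = st$fa),
                  file.path(out_dir, "fa.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
  }, load = function() {
    st$mesh <- read_mesh(file.path(out_dir, "mesh"))
    st$templates <- read_templates(file.path(out_dir, "templates.json"))
    sm <- read_signal_matrix(file.path(out_dir, "signals.tsv"))
    truth <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                                 simplifyVector = TRUE)
    st$sim <- structure(
      list(X = sm$X, vertex_ids = sm$vertex_ids,
           membership = truth$membership,
           representability = truth$representability, truth = truth),
      class = "fold_simulation")
    st$fa <- read.delim(file.path(out_dir, "fa.tsv"))$fa
  })

  ## -- decompose -----------------------------------------------------------
  dec_files <- c("decomp_D.tsv", "decomp_alpha.tsv", "decomp_meta.json")
  run_stage("decompose", dec_files, compute = function() {
    st$signals <- normalize_signals(st$sim)
    st$decomp <- learn_dictionary(st$signals, m = config$m,
                                  lambda = config$lambda,
                                  n_iter = config$n_iter,
                                  batch_size = config$batch_size,
                                  seed = derive_seed(config$seed, 4))
    if (length(st$signals$excluded_ids))
      message(sprintf("normalization excluded %d zero-variance vertices",
                      length(st$signals$excluded_ids)))
    if (!is.null(out_dir))
      write_decomposition(st$decomp, file.path(out_dir, "decomp"))
  }, load = function() {
    st$signals <- normalize_signals(st$sim)
    st$decomp <- read_decomposition(file.path(out_dir, "decomp"))
  })

  ## -- identify ------------------------------------------------------------
  run_stage("identify", "matches.csv", compute = function() {
    maps <- extract_spatial_maps(st$decomp)
    st$matches <- match_networks(maps, st$templates,
                                 rule = config$binarize_rule, tau = config$tau)
    if (!is.null(out_dir))
      write.csv(st$matches, file.path(out_dir, "matches.csv"),
                row.names = FALSE)
  }, load = function() {
    st$matches <- read.csv(file.path(out_dir, "matches.csv"))
  })

  ## -- assess --------------------------------------------------------------
  run_stage("assess", "accuracy.csv", compute = function() {
    st$accuracy <- representation_accuracy(st$signals, st$decomp)
    part <- partition_by_curvature(st$mesh)
    st$roi_acc <- lapply(st$templates, function(nt)
      lapply(seq_along(nt$rois), function(j)
        collect_roi_accuracy(st$accuracy, nt$rois[[j]], part,
                             roi_id = paste0(nt$id, "_roi", j))))
    names(st$roi_acc) <- template_ids(st$templates)
    st$summaries <- lapply(st$roi_acc, summarize_network)
    if (!is.null(out_dir)) {
      roi_labels <- rep(NA_character_, n_vertices(st$mesh))
      for (nt in st$templates) roi_labels[nt$vertices] <- nt$id
      write_accuracy(st$accuracy, st$mesh,
                     file.path(out_dir, "accuracy.csv"), roi_labels)
    }
  }, load = function() {
    st$accuracy <- representation_accuracy(st$signals, st$decomp)
    part <- partition_by_curvature(st$mesh)
    st$roi_acc <- lapply(st$templates, function(nt)
      lapply(seq_along(nt$rois), function(j)
        collect_roi_accuracy(st$accuracy, nt$rois[[j]], part,
                             roi_id = paste0(nt$id, "_roi", j))))
    names(st$roi_acc) <- template_ids(st$templates)
    st$summaries <- lapply(st$roi_acc, summarize_network)
  })

  ## -- stats ---------------------------------------------------------------
  run_stage("stats", c("roi_tests.csv", "network_tests.csv"), compute = function() {
    st$roi_tests <- pipeline_roi_tests(st$roi_acc)
    st$network_tests <- pipeline_network_tests(
      st$roi_acc, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 5),
      k_networks = length(st$roi_acc))
    st$fa_tests <- pipeline_fa_tests(st$roi_acc, st$accuracy, st$fa)
    if (!is.null(out_dir)) {
      write.csv(st$roi_tests, file.path(out_dir, "roi_tests.csv"),
                row.names = FALSE)
      write.csv(st$network_tests, file.path(out_dir, "network_tests.csv"),
                row.names = FALSE)
      write.csv(st$fa_tests, file.path(out_dir, "fa_tests.csv"),
                row.names = FALSE)
    }
  }, load = function() {
    st$roi_tests <- read.csv(file.path(out_dir, "roi_tests.csv"))
    st$network_tests <- read.csv(file.path(out_dir, "network_tests.csv"))
    st$fa_tests <- read.csv(file.path(out_dir, "fa_tests.csv"))
  })

  report <- structure(
    list(config = config, config_md5 = unname(hash), status = status,
         matches = st$matches, summaries = st$summaries,
         roi_tests = st$roi_tests, network_tests = st$network_tests,
         fa_tests = st$fa_tests,
         excluded_vertices = if (!is.null(st$signals))
           st$signals$excluded_ids else integer(0),
         reseeded_atoms = if (!is.null(st$decomp)) st$decomp$reseeded else NA,
         version = as.character(utils::packageVersion("foldnet"))),
    class = "fold_report")
  if (!is.null(out_dir)) {
    rep_json <- report
    rep_json$config <- unclass(config)
    rep_json$summaries <- lapply(rep_json$summaries, as.list)
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}

# per-region one-tailed t-tests, Bonferroni family = regions per network
pipeline_roi_tests <- function(roi_acc) {
  rows <- list()
  for (nid in names(roi_acc)) {
    rois <- roi_acc[[nid]]
    fam <- length(rois)
    for (r in rois) {
      degenerate <- r$flagged || length(r$P_gyri) < 2 ||
        length(r$P_sulci) < 2 || pop_sd(r$P_gyri) < 1e-12 ||
        pop_sd(r$P_sulci) < 1e-12
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          network_id = nid, roi_id = r$roi_id, statistic = NA_real_,
          p_raw = NA_real_, p_adjusted = NA_real_,
          mean_gyri = NA_real_, mean_sulci = NA_real_,
          n_gyri = length(r$P_gyri), n_sulci = length(r$P_sulci),
          method = "t_test", degenerate = TRUE)
        next
      }
      tt <- t_test_one_tailed(r$P_gyri, r$P_sulci)
      rows[[length(rows) + 1L]] <- data.frame(
        network_id = nid, roi_id = r$roi_id, statistic = tt$statistic,
        p_raw = tt$p, p_adjusted = bonferroni_adjust(tt$p, fam),
        mean_gyri = tt$mean_a, mean_sulci = tt$mean_b,
        n_gyri = tt$n_a, n_sulci = tt$n_b,
        method = "t_test", degenerate = FALSE)
    }
  }
  do.call(rbind, rows)
}

# per-network permutation tests on pooled accuracy values, plus a pooled
# t-test whose Bonferroni family is the number of networks
pipeline_network_tests <- function(roi_acc, n_perm, seed, k_networks) {
  rows <- list()
  for (i in seq_along(roi_acc)) {
    nid <- names(roi_acc)[i]
    pg <- unlist(lapply(roi_acc[[i]], `[[`, "P_gyri"))
    ps <- unlist(lapply(roi_acc[[i]], `[[`, "P_sulci"))
    if (length(pg) < 2 || length(ps) < 2) next
    pm <- permutation_mean_diff(c(pg, ps),
                                c(rep(TRUE, length(pg)), rep(FALSE, length(ps))),
                                n_perm = n_perm,
                                seed = derive_seed(seed, i))
    tt <- t_test_one_tailed(pg, ps)
    rows[[length(rows) + 1L]] <- data.frame(
      network_id = nid, observed_diff = pm$observed_diff,
      perm_p = pm$p, n_perm = pm$n_perm,
      t_statistic = tt$statistic, t_p_raw = tt$p,
      t_p_adjusted = bonferroni_adjust(tt$p, k_networks),
      n_gyri = length(pg), n_sulci = length(ps))
  }
  do.call(rbind, rows)
}

# FA vs accuracy Pearson correlation per network (retained vertices only)
pipeline_fa_tests <- function(roi_acc, accuracy, fa) {
  rows <- list()
  for (nid in names(roi_acc)) {
    verts <- unlist(lapply(roi_acc[[nid]],
                           function(r) c(r$V_gyri, r$V_sulci)))
    idx <- match(verts, accuracy$vertex_ids)
    P <- accuracy$P[idx]
    f <- fa[verts]
    ok <- !is.na(P) & !is.na(f)
    if (sum(ok) < 3) next
    pc <- pearson_correlation(f[ok], P[ok])
    rows[[length(rows) + 1L]] <- data.frame(
      network_id = nid, r = pc$r, p = pc$p, n = pc$n)
  }
  do.call(rbind, rows)
}

#' @export
print.fold_report <- function(x, ...) {
  cat("fold_report\n")
  for (s in names(x$status)) cat(sprintf("  %-10s %s\n", s, x$status[[s]]))
  if (!is.null(x$matches)) {
    cat("  template matches:\n")
    print(x$matches, row.names = FALSE)
  }
  if (!is.null(x$roi_tests))
    cat(sprintf("  %d/%d region tests significant (adjusted p < %g)\n",
                sum(x$roi_tests$p_adjusted < x$config$alpha_level,
                    na.rm = TRUE),
                nrow(x$roi_tests), x$config$alpha_level))
  invisible(x)
}

#' Simulate a cohort of subjects and tabulate significance proportions
#'
#' Runs independent, deterministically seeded subject-level pipelines
#' (each subject gets fresh template placement, signals and learning) and
#' reports, per network, the fraction of subjects whose pooled
#' gyral-vs-sulcal one-tailed t-test survives Bonferroni correction over
#' the number of networks at `alpha_level`.
#'
#' @param config a `fold_config` (its `out_dir` is ignored; cohort runs
#'   are in-memory).
#' @param n_subjects number of subjects (>= 1).
#' @return list with `proportions` (a [subject_proportion()] table) and
#'   `detail` (per subject and network statistics).
#' @export
run_cohort <- function(config, n_subjects) {
  stopifnot(inherits(config, "fold_config"), n_subjects >= 1)
  detail <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$out_dir <- NULL
    cfg$seed <- derive_seed(config$seed, 104729 * s)
    rep_s <- run_pipeline(cfg)
    nt <- rep_s$network_tests
    detail[[s]] <- data.frame(
      subject = s, network_id = nt$network_id,
      statistic = nt$t_statistic, p_adjusted = nt$t_p_adjusted,
      perm_p = nt$perm_p,
      significant = nt$t_p_adjusted < config$alpha_level)
  }
  detail <- do.call(rbind, detail)
  list(proportions = subject_proportion(detail), detail = detail)
}
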