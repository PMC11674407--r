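#' Run the full synthetic study: simulate, fit both models, evaluate
#'
#' Generates the three synthetic groups (A/B/C) with their stated design
#' parameters, fits every subject with the structurally constrained model
#' (sfCICA) and with the `gamma = 0` baseline (CICA) under identical seeds,
#' and computes the whole evaluation battery: per-subject FNC matrices and
#' time-course distances for both models, ground-truth spatial recovery,
#' the global-cost-efficiency threshold (selected on the sfCICA FNC set),
#' binary graph metrics per subject at that threshold, and both models'
#' sparsity. Subjects are generated group by group and their raw data
#' discarded after fitting, so memory stays modest.
#'
#' @param seed master seed driving every random draw.
#' @param n_subjects subjects per group (default 10; 30 total).
#' @param n_time time points (default 3000).
#' @param coupling SC-correlation coupling of the generator (default 0.5).
#' @param config optimizer configuration for the sfCICA fit; the baseline
#'   uses the same configuration with `gamma = 0`. The default caps outer
#'   iterations at 100 with `tol = 1e-5`: spatial recovery, template
#'   similarity and the graph metrics plateau well before that, while the
#'   slow residual creep of the structural term does not change the
#'   study-level conclusions.
#' @param n_null null graphs for small-worldness/nonrandomness.
#' @param grid threshold grid for global cost efficiency.
#' @param verbose print per-subject progress.
#' @return list with per-subject results (`W_sf`, `W_cica`, `fnc_sf`,
#'   `fnc_cica` lists; `dis_sf`, `dis_cica` subjects x L matrices;
#'   `recovery_sf`, `recovery_cica` mean absolute map correlations;
#'   `metrics_sf`, `metrics_cica` data frames), the selected `threshold`,
#'   `sparsity_sf`/`sparsity_cica`, `group` labels, `sc`, `template`, and a
#'   `summary` list of study-level means.
#' @export
synthetic_study <- function(seed = 1L, n_subjects = 10L, n_time = 3000L,
                            coupling = 0.5,
                            config = sfcica_config(max_iter = 100L,
                                                   tol = 1e-5),
                            n_null = 100L,
                            grid = seq(0.05, 0.95, by = 0.01),
                            verbose = FALSE) {
  maps <- make_phantom_regions(grid = 64L, n_regions = 16L, seed = seed)
  sc <- make_structural_connectivity()
  gridsz <- attr(maps, "grid")
  ref_maps <- lapply(c(A = 1.2, B = 0.9, C = 1.3), function(sf)
    t(vapply(seq_len(nrow(maps)),
             function(l) warp_map(maps[l, ], gridsz, scale = sf),
             numeric(ncol(maps)))))
  template <- make_template(ref_maps, seed = seed + 97L)
  cfg_cica <- config
  cfg_cica$gamma <- 0

  W_sf <- W_cica <- fnc_sf <- fnc_cica <- list()
  recovery_sf <- recovery_cica <- numeric(0)
  min_cost_step_sf <- min_cost_step_cica <- numeric(0)
  group <- character(0)
  L <- nrow(maps)

  for (gname in c("A", "B", "C")) {
    spec <- group_spec(gname, n_subjects = n_subjects,
                       seed = seed + 17L * match(gname, c("A", "B", "C")))
    sims <- simulate_group(spec, maps, n_time = n_time, sc = sc,
                           coupling = coupling)
    for (i in seq_len(n_subjects)) {
      sub <- sims$subjects[[i]]
      fit1 <- fit_subject(sub, template, sc, config)
      fit0 <- fit_subject(sub, template, sc, cfg_cica)
      truth <- sims$truth$maps[[i]]
      rec <- function(S) mean(abs(vapply(seq_len(L), function(l)
        stats::cor(S[l, ], truth[l, ]), numeric(1))))
      k <- length(W_sf) + 1L
      W_sf[[k]] <- fit1$W; W_cica[[k]] <- fit0$W
      fnc_sf[[k]] <- compute_fnc(fit1$W)
      fnc_cica[[k]] <- compute_fnc(fit0$W)
      recovery_sf[k] <- rec(fit1$S)
      recovery_cica[k] <- rec(fit0$S)
      min_cost_step_sf[k] <- min(diff(fit1$cost_trace))
      min_cost_step_cica[k] <- min(diff(fit0$cost_trace))
      group[k] <- gname
      if (verbose)
        message(sprintf("subject %s: sfCICA %d iters, CICA %d iters, recovery %.3f",
                        sub$subject_id, fit1$n_iter, fit0$n_iter,
                        recovery_sf[k]))
    }
    rm(sims)
  }

  n_all <- length(W_sf)
  dis_sf <- t(vapply(W_sf, timecourse_distance, numeric(L)))
  dis_cica <- t(vapply(W_cica, timecourse_distance, numeric(L)))

  threshold <- optimal_threshold_gce(fnc_sf, grid = grid)
  met <- function(fncs) {
    rows <- lapply(seq_along(fncs), function(i) {
      gm <- graph_metrics(fncs[[i]], as.numeric(threshold),
                          n_null = n_null, seed = seed + 7L * i)
      data.frame(modularity = gm$modularity,
                 global_efficiency = gm$global_efficiency,
                 local_efficiency = gm$local_efficiency,
                 small_worldness = gm$small_worldness,
                 nonrandomness = gm$nonrandomness,
                 sparsity = gm$sparsity)
    })
    do.call(rbind, rows)
  }
  metrics_sf <- met(fnc_sf)
  metrics_cica <- met(fnc_cica)

  summary <- list(
    threshold = as.numeric(threshold),
    modularity_sf = mean(metrics_sf$modularity),
    global_efficiency_sf = mean(metrics_sf$global_efficiency),
    local_efficiency_sf = mean(metrics_sf$local_efficiency),
    small_worldness_sf = mean(metrics_sf$small_worldness, na.rm = TRUE),
    sparsity_sf = mean(metrics_sf$sparsity),
    sparsity_cica = mean(metrics_cica$sparsity),
    recovery_sf = mean(recovery_sf),
    recovery_cica = mean(recovery_cica),
    mean_distance_diff = mean(dis_sf - dis_cica))

  list(seed = seed, group = group, sc = sc, template = template,
       W_sf = W_sf, W_cica = W_cica, fnc_sf = fnc_sf, fnc_cica = fnc_cica,
       dis_sf = dis_sf, dis_cica = dis_cica,
       recovery_sf = recovery_sf, recovery_cica = recovery_cica,
       min_cost_step_sf = min_cost_step_sf,
       min_cost_step_cica = min_cost_step_cica,
       threshold = as.numeric(threshold), gce_curve = attr(threshold, "curve"),
       metrics_sf = metrics_sf, metrics_cica = metrics_cica,
       summary = summary)
}

#' Run a configured pipeline end to end
#'
#' Executes the requested stages in order -- simulate (or load inputs), fit
#' (with an optional parallel `gamma = 0` baseline fit for paired
#' comparison), metrics, stats -- writing every stage's outputs under
#' `config$out` together with a JSON manifest of the configuration echo,
#' package version, seeds, per-file checksums and timestamps. A stage
#' failure is recorded in the manifest (`failed_stage`) and earlier outputs
#' are retained.
#'
#' @param config `sfcica_run_config` from [read_run_config()] /
#'   [as_run_config()].
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "sfcica_run_config")) config <- as_run_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("sfcica")),
                   seed = config$seed, started = format(Sys.time()),
                   config = config[setdiff(names(config), "optimizer")],
                   optimizer = unclass(config$optimizer),
                   stages = list(), files = list())
  written <- character(0)
  failed <- NULL

  run_stage <- function(name, fn) {
    if (!is.null(failed)) return(NULL)
    res <- tryCatch(fn(), error = function(e) {
      failed <<- list(stage = name, error = conditionMessage(e))
      NULL
    })
    manifest$stages[[name]] <<- if (is.null(failed)) "ok" else "failed"
    res
  }

  subjects <- template <- sc <- truth <- NULL
  run_stage("inputs", function() {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      n_time <- if (is.null(sim$n_time)) 3000L else as.integer(sim$n_time)
      nsub <- if (is.null(sim$n_subjects)) 10L else as.integer(sim$n_subjects)
      coupling <- if (is.null(sim$coupling)) 0.5 else sim$coupling
      gsel <- if (is.null(sim$group) || identical(sim$group, "all"))
        c("A", "B", "C") else sim$group
      maps <- make_phantom_regions(seed = config$seed)
      sc <<- make_structural_connectivity()
      subs <- list(); tmaps <- list()
      for (g in gsel) {
        spec <- group_spec(g, n_subjects = nsub,
                           seed = config$seed + 17L * match(g, c("A", "B", "C")))
        sim_g <- simulate_group(spec, maps, n_time = n_time, sc = sc,
                                coupling = coupling)
        subs <- c(subs, sim_g$subjects)
        tmaps <- c(tmaps, sim_g$truth$maps)
      }
      subjects <<- subs
      truth <<- tmaps
      gridsz <- attr(maps, "grid")
      ref <- lapply(c(1.2, 0.9, 1.3)[match(gsel, c("A", "B", "C"))],
                    function(sf) t(vapply(seq_len(nrow(maps)), function(l)
                      warp_map(maps[l, ], gridsz, scale = sf),
                      numeric(ncol(maps)))))
      template <<- make_template(ref, seed = config$seed + 97L)
      write_sc_matrix(sc, file.path(out, "sc.csv"))
      written <<- c(written, file.path(out, "sc.csv"))
    } else {
      mask <- read_nifti_mask(config$paths$mask)
      tpl_img <- read_nifti_series(config$paths$template)
      Lp <- dim(tpl_img$data)[4]
      flat <- matrix(tpl_img$data, ncol = Lp)
      template <<- spatial_template(t(flat[which(mask), , drop = FALSE]))
      sc <<- if (is.null(config$paths$sc)) NULL
             else read_sc_matrix(config$paths$sc)
      subjects <<- lapply(seq_along(config$paths$data), function(i) {
        ser <- read_nifti_series(config$paths$data[[i]])
        standardize_subject(ser$data, mask, sprintf("sub%03d", i))
      })
    }
    invisible(NULL)
  })

  fits <- fits0 <- NULL
  run_stage("fit", function() {
    cfg <- config$optimizer
    cfg$seed <- config$seed
    fits <<- fit_dataset(subjects, template, sc, cfg)
    for (i in seq_along(fits))
      written <<- c(written, write_fit_result(fits[[i]], subjects[[i]],
                                              file.path(out, "fits")))
    if (isTRUE(config$baseline)) {
      cfg0 <- cfg; cfg0$gamma <- 0
      fits0 <<- fit_dataset(subjects, template, sc, cfg0)
      for (i in seq_along(fits0))
        written <<- c(written, write_fit_result(fits0[[i]], subjects[[i]],
                                                file.path(out, "fits_cica")))
    }
    invisible(NULL)
  })

  run_stage("metrics", function() {
    fncs <- lapply(fits, compute_fnc)
    thr <- config$metrics$threshold
    if (is.null(thr) || identical(thr, "auto"))
      thr <- as.numeric(optimal_threshold_gce(fncs))
    nn <- if (is.null(config$metrics$n_null)) 100L
          else as.integer(config$metrics$n_null)
    mt <- do.call(rbind, lapply(seq_along(fncs), function(i) {
      gm <- graph_metrics(fncs[[i]], thr, n_null = nn,
                          seed = config$seed + 7L * i)
      data.frame(subject = fits[[i]]$subject_id,
                 modularity = gm$modularity,
                 global_efficiency = gm$global_efficiency,
                 local_efficiency = gm$local_efficiency,
                 small_worldness = gm$small_worldness,
                 nonrandomness = gm$nonrandomness, sparsity = gm$sparsity,
                 threshold = thr)
    }))
    utils::write.csv(mt, file.path(out, "graph_metrics.csv"),
                     row.names = FALSE)
    dis <- t(vapply(fits, function(f) timecourse_distance(f$W),
                    numeric(nrow(fits[[1]]$W))))
    utils::write.csv(dis, file.path(out, "distances.csv"), row.names = FALSE)
    written <<- c(written, file.path(out, "graph_metrics.csv"),
                  file.path(out, "distances.csv"))
    if (!is.null(fits0)) {
      dis0 <- t(vapply(fits0, function(f) timecourse_distance(f$W),
                       numeric(nrow(fits0[[1]]$W))))
      dd <- dis - dis0
      utils::write.csv(dd, file.path(out, "distance_diff.csv"),
                       row.names = FALSE)
      written <<- c(written, file.path(out, "distance_diff.csv"))
    }
    invisible(NULL)
  })

  run_stage("stats", function() {
    if (is.null(fits0) && is.null(config$stats$covariates))
      return(invisible(NULL))
    if (!is.null(fits0)) {
      dis <- t(vapply(fits, function(f) timecourse_distance(f$W),
                      numeric(nrow(fits[[1]]$W))))
      dis0 <- t(vapply(fits0, function(f) timecourse_distance(f$W),
                       numeric(nrow(fits0[[1]]$W))))
      pt <- if (nrow(dis) >= 3L) paired_ttest(rowMeans(dis), rowMeans(dis0))
            else list(note = "paired test needs at least three subjects")
      jsonlite::write_json(
        list(paired_distance_test = pt,
             mean_distance_sfcica = mean(dis),
             mean_distance_cica = mean(dis0)),
        file.path(out, "paired_stats.json"), auto_unbox = TRUE, digits = NA)
      written <<- c(written, file.path(out, "paired_stats.json"))
    }
    if (!is.null(config$stats$covariates)) {
      cov <- utils::read.csv(config$stats$covariates)
      fncs <- lapply(fits, compute_fnc)
      em <- edgewise_analysis(fncs, cov, q_level = config$stats$q_level)
      utils::write.csv(em$signed_logp, file.path(out, "edgewise_signed_logp.csv"),
                       row.names = FALSE)
      written <<- c(written, file.path(out, "edgewise_signed_logp.csv"))
    }
    invisible(NULL)
  })

  manifest$files <- as.list(tools::md5sum(unique(written[file.exists(written)])))
  manifest$finished <- format(Sys.time())
  if (!is.null(failed)) manifest$failed_stage <- failed
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
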