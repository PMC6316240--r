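#' Pipeline configuration
#'
#' A fully serializable configuration for the end-to-end campaign pipeline.
#' Round-trips losslessly through YAML via [read_config()] / [write_config()].
#'
#' @param seed master seed for every stochastic stage
#' @param design `"packaged_table1"` or a path to a design CSV
#' @param replicates replicates per condition
#' @param t_end campaign duration, h
#' @param grid_step analysis grid spacing, h
#' @param pca_horizon history horizon for outlier detection, h
#' @param cluster_horizon history horizon for clustering, h
#' @param target_times evaluation times for prediction and optimization, h
#' @param sweep_horizons history horizons of the soft-sensor sweep, h
#' @param folds cross-validation folds
#' @param params_override named list of kinetic-parameter overrides
#' @param failure_run run receiving the injected sensor failure (`NA` = none)
#' @param out_dir output directory (`NULL` = in-memory only)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(seed = 1, design = "packaged_table1",
                            replicates = 3, t_end = 48, grid_step = 2,
                            pca_horizon = 22, cluster_horizon = 32,
                            target_times = c(26, 35),
                            sweep_horizons = c(12, 16, 20, 24, 28, 32, 35),
                            folds = 10, params_override = list(),
                            failure_run = 46, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML path
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

#' Run the full campaign pipeline
#'
#' design -> feed schedules -> simulation -> preprocessing -> outlier
#' detection -> clustering + cluster characterization -> soft-sensor history
#' sweep -> four-target optimization. Every stage draws randomness from the
#' config seed via named substreams; given a fixed config the output manifest
#' hashes are identical across re-runs. Stages that cannot run on degenerate
#' inputs (e.g. clustering with too few runs) are skipped and logged.
#'
#' @param cfg a [pipeline_config()]
#' @param quiet suppress progress messages
#' @return a `campaign_report`: `campaign`, `gridded`, `outliers`, `clusters`,
#'   `cluster_tree`, `sweep`, `optimization`, `log`, `manifest`
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (!quiet) message(msg)
  }

  design <- if (identical(cfg$design, "packaged_table1")) default_design()
            else read_design(cfg$design)
  params <- do.call(kinetic_params, cfg$params_override)

  say("simulate: %d conditions x %d replicates", nrow(design), cfg$replicates)
  campaign <- generate_campaign(design, params, seed = cfg$seed,
                                replicates = cfg$replicates, t_end = cfg$t_end,
                                failure_run = cfg$failure_run)

  say("preprocess: %.0f-h grid to %d h", cfg$grid_step, cfg$t_end)
  meas <- campaign$measurements
  norm <- normalize_biomass(meas, meas[meas$variable == "volume", ])
  meas_n <- meas
  bio <- meas$variable == "biomass"
  # V/V0 dilution factor per (run, time); identical across replicates
  idx <- match(paste(meas$run_id[bio], meas$time_h[bio]),
               paste(norm$run_id, norm$time_h))
  meas_n$value[bio] <- meas$value[bio] * (norm$X_N / norm$X)[idx]
  gridded <- align_to_grid(meas_n, grid_step = cfg$grid_step,
                           horizon = cfg$t_end - cfg$grid_step)

  pca_vars <- c("biomass", "glucose", "ethanol", "pH", "DOT", "base", "volume")
  m22 <- batch_wise_unfold(gridded, variables = pca_vars,
                           horizon = cfg$pca_horizon)
  pca <- fit_pca(m22)
  if (nrow(m22) >= 5) {
    outliers <- detect_outliers(pca)
    say("diagnose: %d/%d runs flagged at %g-h horizon",
        sum(outliers$outlier), nrow(outliers), cfg$pca_horizon)
  } else {
    outliers <- data.frame(run_id = rownames(m22), T2 = NA_real_,
                           limit = NA_real_, outlier = FALSE)
    say("diagnose: skipped (fewer than 5 runs)")
  }

  keep <- !outliers$outlier
  clusters <- cluster_tree <- NULL
  if (sum(keep) >= 6) {
    m24 <- batch_wise_unfold(gridded, variables = pca_vars,
                             horizon = cfg$cluster_horizon)
    pca2 <- fit_pca(autoscale(m24[keep, , drop = FALSE]))
    clusters <- cluster_scores(pca2, k = 2,
                               seed = substream_seed(cfg$seed, "kmeans"))
    cluster_tree <- characterize_clusters(clusters$assignments, campaign$runs)
    say("cluster: sizes %s at %g-h horizon",
        paste(clusters$sizes, collapse = "/"), cfg$cluster_horizon)
  } else {
    say("cluster: skipped (fewer than 6 retained runs)")
  }

  sweep <- NULL
  target_time <- max(cfg$target_times)
  horizons <- cfg$sweep_horizons[cfg$sweep_horizons <= target_time]
  if (sum(keep) >= cfg$folds + 2) {
    gr_keep <- structure(gridded[keep, , , drop = FALSE],
                         grid = attr(gridded, "grid"),
                         class = class(gridded))
    sweep <- history_sweep(gr_keep, campaign$runs, target_time = target_time,
                           horizons = horizons, folds = cfg$folds,
                           seed = substream_seed(cfg$seed, "cv"))
    say("predict: RMSECV %.1f%% -> %.1f%% across %d horizons",
        100 * sweep$rmsecv_mean[1], 100 * sweep$rmsecv_mean[nrow(sweep)],
        nrow(sweep))
  } else {
    say("predict: skipped (too few runs for %d-fold CV)", cfg$folds)
  }

  optimization <- NULL
  if (sum(keep) >= 12) {
    gr_keep <- structure(gridded[keep, , , drop = FALSE],
                         grid = attr(gridded, "grid"),
                         class = class(gridded))
    optimization <- optimize_conditions(gr_keep, campaign$runs, design,
                                        times = cfg$target_times)
    inter <- optimization$superposition$intersection
    say("optimize: %d recurring condition(s): %s", length(inter),
        paste(inter, collapse = ", "))
  } else {
    say("optimize: skipped (fewer than 12 retained runs)")
  }

  manifest <- NULL
  if (!is.null(cfg$out_dir)) {
    manifest <- .write_outputs(cfg, campaign, gridded, outliers, clusters,
                               sweep, optimization)
    say("wrote %d files to %s", nrow(manifest), cfg$out_dir)
  }
  say("done in %.1f s", proc.time()[["elapsed"]] - t_all)

  structure(list(campaign = campaign, gridded = gridded, pca = pca,
                 outliers = outliers, clusters = clusters,
                 cluster_tree = cluster_tree, sweep = sweep,
                 optimization = optimization, config = cfg, log = log,
                 manifest = manifest),
            class = "campaign_report")
}

.write_outputs <- function(cfg, campaign, gridded, outliers, clusters,
                           sweep, optimization) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(cfg$out_dir, name)
  write_measurements(campaign$measurements, fp("measurements.csv"))
  write_schedule_csv(campaign$schedules, fp("schedules.csv"))
  write_unfolded_csv(batch_wise_unfold(gridded), fp("unfolded.csv"))
  utils::write.csv(outliers, fp("outliers.csv"), row.names = FALSE)
  if (!is.null(clusters)) {
    utils::write.csv(data.frame(run_id = names(clusters$assignments),
                                cluster = clusters$assignments),
                     fp("clusters.csv"), row.names = FALSE)
  }
  if (!is.null(sweep)) {
    utils::write.csv(as.data.frame(sweep), fp("history_sweep.csv"),
                     row.names = FALSE)
  }
  if (!is.null(optimization)) {
    utils::write.csv(optimization$table, fp("optimal_paths.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(intersection = optimization$superposition$intersection,
           common_levels = optimization$superposition$common_levels),
      fp("superposition.json"), auto_unbox = TRUE, digits = NA)
  }
  write_config(cfg, fp("config.yaml"))
  files <- sort(list.files(cfg$out_dir, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, fp("manifest.csv"), row.names = FALSE)
  manifest
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("Mini-bioreactor campaign report\n")
  cat(sprintf("  runs: %d (seed %d)\n", nrow(x$campaign$runs), x$config$seed))
  cat(sprintf("  flagged outliers: %s\n",
              paste(x$outliers$run_id[x$outliers$outlier], collapse = ", ")))
  if (!is.null(x$clusters)) {
    cat(sprintf("  clusters (%g h): sizes %s\n", x$config$cluster_horizon,
                paste(x$clusters$sizes, collapse = "/")))
  }
  if (!is.null(x$sweep)) {
    cat(sprintf("  soft sensor: RMSECV %.1f%% at %g h history\n",
                100 * x$sweep$rmsecv_mean[nrow(x$sweep)],
                x$sweep$horizon[nrow(x$sweep)]))
  }
  if (!is.null(x$optimization)) {
    cat(sprintf("  recurring optimal condition(s): %s\n",
                paste(x$optimization$superposition$intersection, collapse = ", ")))
  }
  invisible(x)
}
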