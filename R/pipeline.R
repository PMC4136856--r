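#' Default configuration for the full corridor-planning pipeline
#'
#' One nested list with a block per stage. Every stochastic stage draws its
#' own seed deterministically from the global seed and its stage name, so
#' stages can be re-run in isolation and the whole run is reproducible.
#'
#' @param seed global integer seed.
#' @param n_rows,n_cols landscape grid size.
#' @return a `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1, n_rows = 120, n_cols = 120) {
  structure(list(
    seed = seed,
    landscape = list(n_rows = n_rows, n_cols = n_cols),
    truth = list(),
    survey = list(n_sites = 250, n_occasions = 8),
    model = list(
      occ_pool = c("elevation", "bamboo", "forest_age"),
      det_pool = c("lure", "temperature", "camera_view"),
      screen = c("elevation", "slope_deg", "dist_road", "dist_residence_large",
                 "dist_residence_small", "dist_cropland"),
      n_starts = 3, delta_threshold = 2),
    validation = list(n_segments = 216, radius = 1000),
    corridor = list(n_per_side = 5, scale = 99, cost_min = 1),
    circuit = list(enabled = TRUE, buffer_width = 4, n_perimeter_nodes = 10,
                   pair_subsample = 12),
    scenario = list(enabled = TRUE, tunnel_length_m = 1000)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of stage-block overrides and merges it over
#' [default_pipeline_config()]. See `inst/extdata/demo_config.yaml` for a
#' small runnable example.
#'
#' @param path YAML file with any subset of the config blocks.
#' @return a `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  over <- yaml::read_yaml(path)
  config <- utils::modifyList(default_pipeline_config(), over)
  class(config) <- "pipeline_config"
  config
}

# deterministic per-stage seed from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- 17
  for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% 1000000007
  as.integer((seed * 7919 + h) %% 2147483647)
}

#' Default management scenarios for a generated valley landscape
#'
#' Builds the three canonical edits from the landscape's own geometry:
#' forest/bamboo restoration of the valley band, relocation of all large
#' residences, and a road tunnel through the central stretch of the valley
#' road.
#'
#' @param landscape result of [generate_landscape()].
#' @param tunnel_length_m tunnelled road length (default 1000 m).
#' @return named list of [scenario_spec()]s.
#' @export
default_scenarios <- function(landscape, tunnel_length_m = 1000) {
  cfg <- landscape$config
  width_m <- cfg$n_cols * cfg$cell_size
  height_m <- cfg$n_rows * cfg$cell_size
  valley_poly <- tibble::tibble(
    x = c(width_m / 2 - cfg$valley_width, width_m / 2 + cfg$valley_width,
          width_m / 2 + cfg$valley_width, width_m / 2 - cfg$valley_width),
    y = c(0, 0, height_m, height_m))
  road <- landscape$features$roads
  road_len <- max(polyline_chainage(road$x[road$road_id == 1],
                                    road$y[road$road_id == 1]))
  list(
    restoration = scenario_spec("restoration",
                                list(edit_restore_forest(valley_poly))),
    relocation = scenario_spec("relocation",
                               list(edit_remove_residences("large"))),
    tunnel = scenario_spec("tunnel",
                           list(edit_tunnel(1L,
                                            road_len / 2 - tunnel_length_m / 2,
                                            road_len / 2 + tunnel_length_m / 2)))
  )
}

# pick n detected sites per valley side, spread along the north-south axis
corridor_endpoints <- function(sites, history, landscape, n_per_side = 5) {
  cfg <- landscape$config
  mid <- cfg$n_cols * cfg$cell_size / 2
  detected <- sites[rowSums(history$y == 1, na.rm = TRUE) > 0, , drop = FALSE]
  pick_side <- function(side_sel, label) {
    side <- detected[side_sel, , drop = FALSE]
    if (nrow(side) < n_per_side) {
      stop(sprintf("only %d detected sites on the %s side; need %d.",
                   nrow(side), label, n_per_side), call. = FALSE)
    }
    side <- side[order(side$y), , drop = FALSE]
    side[unique(round(seq(1, nrow(side), length.out = n_per_side))), , drop = FALSE]
  }
  list(sources = pick_side(detected$x < mid, "west"),
       sinks = pick_side(detected$x >= mid, "east"))
}

#' Run the full corridor-planning pipeline
#'
#' Orchestrates: landscape simulation, true-occupancy surface, camera-trap
#' surveys, collinearity screening, detection-covariate selection,
#' all-subsets occupancy selection with model averaging, suitability
#' prediction and ROC/AUC validation, least-cost pathway enumeration,
#' optional omnidirectional circuit mapping, and the scenario comparison
#' (re-costing, two-way ANOVA, Holm-corrected paired tests).
#'
#' @param config a [default_pipeline_config()] list (or a path to a YAML
#'   file holding overrides of its blocks).
#' @param out_dir optional run directory; when given, rasters (ASCII grid),
#'   features (GeoJSON), tables (CSV) and a `manifest.json` with checksums
#'   are written there.
#' @return list of stage results (`landscape`, `truth_map`, `surveys`,
#'   `screen`, `detection`, `modelset`, `avg`, `psi_map`, `validation`,
#'   `paths`, `current_map`, `comparison`, `anova`, `pairwise`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  required <- c("seed", "landscape", "truth", "survey", "model", "validation",
                "corridor", "circuit", "scenario")
  miss <- setdiff(required, names(config))
  if (length(miss)) {
    stop(sprintf("pipeline config is missing block(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  seed <- config$seed
  res <- list(config = config)

  lc <- do.call(landscape_config,
                utils::modifyList(config$landscape,
                                  list(seed = stage_seed(seed, "landscape"))))
  res$landscape <- generate_landscape(lc)
  stack <- res$landscape$stack
  features <- res$landscape$features

  truth <- do.call(true_model, config$truth)
  res$truth <- truth
  res$truth_map <- simulate_truth(stack, truth)

  design <- do.call(survey_design, config$survey)
  res$surveys <- simulate_surveys(res$truth_map, design, truth, stack = stack,
                                  seed = stage_seed(seed, "survey"))
  sites <- res$surveys$sites
  history <- res$surveys$history

  res$screen <- screen_collinearity(sites, config$model$screen)
  res$detection <- select_detection_model(history, sites, config$model$occ_pool,
                                          det_pool = config$model$det_pool,
                                          n_starts = config$model$n_starts)
  res$modelset <- all_subsets_selection(history, sites, config$model$occ_pool,
                                        det_terms = res$detection$best,
                                        n_starts = config$model$n_starts)
  res$avg <- model_average(res$modelset, config$model$delta_threshold)
  res$psi_map <- predict_suitability(res$avg, stack)

  transects <- simulate_validation_transects(
    res$truth_map, n_segments = config$validation$n_segments,
    seed = stage_seed(seed, "validation"))
  labelled <- assign_validation_labels(transects,
                                       radius = config$validation$radius)
  res$validation <- list(points = labelled,
                         roc = validate_suitability(res$psi_map, labelled))

  cost <- cost_surface(res$psi_map, scale = config$corridor$scale,
                       cost_min = config$corridor$cost_min)
  ends <- corridor_endpoints(sites, history, res$landscape,
                             n_per_side = config$corridor$n_per_side)
  res$cost <- cost
  res$paths <- enumerate_pathways(cost, ends$sources, ends$sinks)

  if (isTRUE(config$circuit$enabled)) {
    res$current_map <- omnidirectional_current(
      cost, buffer_width = config$circuit$buffer_width,
      n_perimeter_nodes = config$circuit$n_perimeter_nodes,
      pair_subsample = config$circuit$pair_subsample,
      seed = stage_seed(seed, "circuit"))
  }

  if (isTRUE(config$scenario$enabled)) {
    scen <- default_scenarios(res$landscape,
                              tunnel_length_m = config$scenario$tunnel_length_m)
    res$comparison <- scenario_costs(scen, res$avg, stack, features, res$paths,
                                     scale = config$corridor$scale,
                                     cost_min = config$corridor$cost_min)
    res$anova <- two_way_anova(res$comparison)
    res$pairwise <- holm_paired_tests(res$comparison)
  }

  if (!is.null(out_dir)) res$manifest <- write_run(res, out_dir)
  res
}

# write run artifacts + manifest with md5 checksums
write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  suppressWarnings({
    write_raster(res$truth_map, p("psi_true.asc"))
    write_raster(res$psi_map, p("psi_pred.asc"))
    write_raster(res$cost, p("cost.asc"))
    if (!is.null(res$current_map)) write_raster(res$current_map, p("current.asc"))
    write_features(res$landscape$features, p("features.geojson"))
  })
  utils::write.csv(res$surveys$sites, p("sites.csv"), row.names = FALSE)
  utils::write.csv(cbind(site_id = res$surveys$history$site_id,
                         as.data.frame(res$surveys$history$y)),
                   p("history.csv"), row.names = FALSE)
  utils::write.csv(res$validation$points, p("validation_points.csv"),
                   row.names = FALSE)
  utils::write.csv(tibble::as_tibble(res$modelset)[, c("model", "K", "AIC",
                                                       "dAIC", "weight",
                                                       "cum_weight")],
                   p("model_set.csv"), row.names = FALSE)
  utils::write.csv(res$paths[, setdiff(names(res$paths), "cells")],
                   p("pathways.csv"), row.names = FALSE)
  if (!is.null(res$comparison)) {
    utils::write.csv(res$comparison$long, p("scenario_costs.csv"), row.names = FALSE)
    utils::write.csv(res$anova, p("anova.csv"), row.names = FALSE)
    utils::write.csv(res$pairwise, p("pairwise.csv"), row.names = FALSE)
  }
  cfg_path <- p("config.yaml")
  yaml::write_yaml(unclass(res$config), cfg_path)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    seed = res$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  manifest
}
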