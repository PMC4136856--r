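#' Scenario edits
#'
#' Constructors for the three landscape-management edits compared by the
#' scenario analysis: restoring young forest to mature forest with a bamboo
#' understory inside a polygon, relocating residences (by size class,
#' optionally within a region), and replacing a road segment with a tunnel
#' (the segment is removed from the road network, representing the abandoned
#' roadbed becoming passable).
#'
#' @param polygon tibble with `x`, `y` vertices.
#' @param size residence size class to remove ("small"/"large").
#' @param region optional polygon restricting the removal.
#' @param road_id id of the road to tunnel.
#' @param start_m,end_m chainage (m along the polyline) of the tunnelled
#'   segment.
#' @name scenario_edits
NULL

#' @rdname scenario_edits
#' @export
edit_restore_forest <- function(polygon) {
  structure(list(type = "restore_forest", polygon = tibble::as_tibble(polygon)),
            class = "scenario_edit")
}

#' @rdname scenario_edits
#' @export
edit_remove_residences <- function(size = "large", region = NULL) {
  stopifnot(size %in% c("small", "large"))
  structure(list(type = "remove_residences", size = size, region = region),
            class = "scenario_edit")
}

#' @rdname scenario_edits
#' @export
edit_tunnel <- function(road_id, start_m, end_m) {
  if (end_m <= start_m) stop("tunnel segment must have positive length.", call. = FALSE)
  structure(list(type = "tunnel", road_id = road_id, start_m = start_m,
                 end_m = end_m), class = "scenario_edit")
}

#' Specify a management scenario
#'
#' @param name scenario name.
#' @param edits list of [scenario_edits] objects, applied in order.
#' @return a `scenario_spec`.
#' @export
scenario_spec <- function(name, edits = list()) {
  stopifnot(all(vapply(edits, inherits, TRUE, "scenario_edit")))
  structure(list(name = name, edits = edits), class = "scenario_spec")
}

# interpolate a point at chainage s along a polyline
point_at_chainage <- function(vx, vy, s) {
  ch <- polyline_chainage(vx, vy)
  s <- min(max(s, 0), ch[length(ch)])
  k <- max(which(ch <= s))
  if (k == length(ch)) return(c(vx[k], vy[k]))
  f <- (s - ch[k]) / (ch[k + 1] - ch[k])
  c(vx[k] + f * (vx[k + 1] - vx[k]), vy[k] + f * (vy[k + 1] - vy[k]))
}

# split one road's polyline, removing [start_m, end_m] of chainage
tunnel_road <- function(roads, road_id, start_m, end_m) {
  seg <- roads[roads$road_id == road_id, , drop = FALSE]
  if (!nrow(seg)) stop(sprintf("no road with id %s.", road_id), call. = FALSE)
  rest <- roads[roads$road_id != road_id, , drop = FALSE]
  ch <- polyline_chainage(seg$x, seg$y)
  total <- ch[length(ch)]
  if (start_m >= total) return(roads)  # segment beyond the road: no-op
  end_m <- min(end_m, total)
  p1 <- point_at_chainage(seg$x, seg$y, start_m)
  p2 <- point_at_chainage(seg$x, seg$y, end_m)
  new_id_base <- max(roads$road_id) * 10L
  part1 <- seg[ch < start_m, , drop = FALSE]
  part1 <- dplyr::bind_rows(part1, tibble::tibble(road_id = road_id,
                                                  class = seg$class[1],
                                                  x = p1[1], y = p1[2]))
  part2 <- dplyr::bind_rows(tibble::tibble(road_id = new_id_base + 1L,
                                           class = seg$class[1],
                                           x = p2[1], y = p2[2]),
                            seg[ch > end_m, , drop = FALSE])
  part2$road_id <- new_id_base + 1L
  keep1 <- nrow(part1) >= 2
  keep2 <- nrow(part2) >= 2
  dplyr::bind_rows(rest,
                   if (keep1) part1,
                   if (keep2) part2)
}

#' Apply a scenario's edits to a landscape
#'
#' Applies the edits in declared order, then recomputes exactly the derived
#' layers whose inputs changed (distance-to-road after a tunnel,
#' residence-distance layers after relocation, forest age and bamboo after
#' restoration). Untouched layers are returned bit-identical.
#'
#' @param stack a [covariate_stack()].
#' @param features a [feature_set()].
#' @param spec a [scenario_spec()].
#' @return list with the modified `stack` and `features`.
#' @export
apply_scenario <- function(stack, features, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ref <- stack$layers[[1]]
  layers <- stack$layers
  touched_roads <- FALSE; touched_res <- FALSE
  for (edit in spec$edits) {
    if (edit$type == "restore_forest") {
      poly <- edit$polygon
      idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
      ctr <- cell_center(ref, idx$row, idx$col)
      inside <- points_in_polygon(ctr$x, ctr$y, poly$x, poly$y)
      if (!any(inside)) warning("restoration polygon covers no cells; no-op.")
      mask <- matrix(inside, ref$n_rows, ref$n_cols)
      if ("forest_age" %in% names(layers)) {
        v <- layers$forest_age$values
        v[mask & !is.na(v)] <- 1  # primary
        layers$forest_age <- raster_grid(v, ref$cell_size, ref$origin_x,
                                         ref$origin_y, ref$nodata)
      }
      if ("bamboo" %in% names(layers)) {
        v <- layers$bamboo$values
        v[mask & !is.na(v)] <- 2  # present
        layers$bamboo <- raster_grid(v, ref$cell_size, ref$origin_x,
                                     ref$origin_y, ref$nodata)
      }
    } else if (edit$type == "remove_residences") {
      res <- features$residences
      sel <- res$size == edit$size
      if (!is.null(edit$region)) {
        sel <- sel & points_in_polygon(res$x, res$y, edit$region$x, edit$region$y)
      }
      if (!any(sel)) warning("residence removal matched nothing; no-op.")
      features$residences <- res[!sel, , drop = FALSE]
      touched_res <- TRUE
    } else if (edit$type == "tunnel") {
      features$roads <- tunnel_road(features$roads, edit$road_id,
                                    edit$start_m, edit$end_m)
      touched_roads <- TRUE
    }
  }
  recompute <- function(layer, feature_layer, class_filter = NULL) {
    distance_to_features(ref, features, feature_layer,
                         class_filter = attr(layer, "dist_class") %||% class_filter,
                         cap = attr(layer, "dist_cap"))
  }
  if (touched_roads && "dist_road" %in% names(layers)) {
    layers$dist_road <- recompute(layers$dist_road, "roads")
  }
  if (touched_res) {
    if ("dist_residence_large" %in% names(layers)) {
      layers$dist_residence_large <- recompute(layers$dist_residence_large,
                                               "residences", "large")
    }
    if ("dist_residence_small" %in% names(layers)) {
      layers$dist_residence_small <- recompute(layers$dist_residence_small,
                                               "residences", "small")
    }
  }
  list(stack = covariate_stack(layers, stack$kind, stack$labels),
       features = features)
}

#' Re-cost fixed pathways under management scenarios
#'
#' For every scenario (a baseline with no edits is always included first):
#' apply the edits, re-predict suitability with the *same* averaged model,
#' re-invert to cost, and re-evaluate each fixed baseline path geometry's
#' cost-per-100-m index. Pathways are not re-routed — the comparison asks
#' how the identified pathways fare under each management option. Paths
#' crossing a cell made impassable are recorded infeasible with a warning.
#'
#' @param scenarios list of [scenario_spec()]s (baseline added
#'   automatically).
#' @param avg an `occu_avg` predictive model.
#' @param stack,features the baseline landscape.
#' @param paths a `path_set` from [enumerate_pathways()] (baseline).
#' @param scale,cost_min,method passed to [cost_surface()].
#' @return a `scenario_comparison`: list with `cost_matrix`
#'   (path x scenario), `long` tibble, `summary` (mean +- SE per scenario),
#'   and the per-scenario suitability/cost rasters.
#' @export
scenario_costs <- function(scenarios, avg, stack, features, paths,
                           scale = 99, cost_min = 1, method = "affine") {
  stopifnot(inherits(paths, "path_set"))
  specs <- c(list(scenario_spec("baseline")), scenarios)
  names(specs) <- vapply(specs, function(s) s$name, "")
  feas <- paths[paths$role != "infeasible", , drop = FALSE]
  M <- matrix(NA_real_, nrow(feas), length(specs),
              dimnames = list(paste0("path", feas$path_id), names(specs)))
  rasters <- list()
  for (s in names(specs)) {
    land <- if (length(specs[[s]]$edits)) {
      apply_scenario(stack, features, specs[[s]])
    } else list(stack = stack, features = features)
    psi <- predict_suitability(avg, land$stack)
    cost <- cost_surface(psi, scale = scale, cost_min = cost_min, method = method)
    rasters[[s]] <- list(psi = psi, cost = cost)
    for (k in seq_len(nrow(feas))) {
      M[k, s] <- evaluate_path_cost(feas$cells[[k]], cost)$cost_index
    }
  }
  if (anyNA(M)) warning("some pathways are infeasible under at least one scenario.")
  long <- tibble::as_tibble(as.table(M), .name_repair = "minimal")
  names(long) <- c("pathway", "scenario", "cost_index")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$scenario),
    mean_cost = mean(.data$cost_index, na.rm = TRUE),
    se_cost = stats::sd(.data$cost_index, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$cost_index))),
    .groups = "drop")
  structure(list(cost_matrix = M, long = long, summary = summary,
                 rasters = rasters, scenarios = specs),
            class = "scenario_comparison")
}

#' @method print scenario_comparison
#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %d pathway(s) x %d scenario(s)\n",
              nrow(x$cost_matrix), ncol(x$cost_matrix)))
  print(x$summary)
  invisible(x)
}

#' @rdname scenario_costs
#' @param x a `scenario_comparison`.
#' @param ... unused.
#' @export
tidy.scenario_comparison <- function(x, ...) x$long

#' @rdname scenario_costs
#' @export
glance.scenario_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "scenario",
                     values_from = c("mean_cost", "se_cost"))
}

#' @method autoplot scenario_comparison
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$scenario, y = .data$mean_cost)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cost - .data$se_cost,
                                        ymax = .data$mean_cost + .data$se_cost),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean cost index (per 100 m)")
}

#' Two-way ANOVA of a pathway x scenario cost matrix
#'
#' Additive two-factor decomposition without interaction (one observation
#' per cell): factors are scenario (columns) and pathway (rows); each
#' factor's F statistic is tested against the residual mean square.
#'
#' @param M numeric matrix, pathways in rows, scenarios in columns (or a
#'   `scenario_comparison`).
#' @return a tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value` (residual row included).
#' @export
two_way_anova <- function(M) {
  if (inherits(M, "scenario_comparison")) M <- M$cost_matrix
  M <- as.matrix(M)
  if (anyNA(M)) stop("cost matrix is incomplete; cannot run the ANOVA.", call. = FALSE)
  a <- nrow(M); b <- ncol(M)
  if (a < 2 || b < 2) stop("need at least two levels per factor.", call. = FALSE)
  grand <- mean(M)
  rm_ <- rowMeans(M); cm_ <- colMeans(M)
  ss_path <- b * sum((rm_ - grand)^2)
  ss_scen <- a * sum((cm_ - grand)^2)
  ss_tot <- sum((M - grand)^2)
  ss_res <- ss_tot - ss_path - ss_scen
  df_path <- a - 1; df_scen <- b - 1; df_res <- df_path * df_scen
  ms_res <- ss_res / df_res
  mk_row <- function(term, df, ss) {
    ms <- ss / df
    f <- ms / ms_res
    tibble::tibble(term = term, df = df, sumsq = ss, meansq = ms,
                   statistic = f,
                   p.value = stats::pf(f, df, df_res, lower.tail = FALSE))
  }
  dplyr::bind_rows(
    mk_row("scenario", df_scen, ss_scen),
    mk_row("pathway", df_path, ss_path),
    tibble::tibble(term = "residual", df = df_res, sumsq = ss_res,
                   meansq = ms_res, statistic = NA_real_, p.value = NA_real_))
}

#' Holm-corrected paired t-tests between scenario columns
#'
#' Paired t statistics on per-pathway differences for each requested
#' scenario pair, with the Holm step-down adjustment: raw p-values sorted
#' ascending, \eqn{p^{holm}_{(i)} = \max_{j \le i} (m - j + 1)\, p_{(j)}},
#' capped at 1. Significance is declared at family-wise level
#' `alpha`. Zero-variance differences are reported with `t = NA` and
#' adjusted p = 1 (identical columns) — the test is undefined there.
#'
#' @param M pathway x scenario matrix (or `scenario_comparison`).
#' @param comparisons 2-column matrix / list of scenario name pairs;
#'   default all column pairs.
#' @param alpha family-wise error level (default 0.05).
#' @return tibble with `scenario_a`, `scenario_b`, `mean_diff`, `t`, `df`,
#'   `p.value`, `p.holm`, `significant`.
#' @export
holm_paired_tests <- function(M, comparisons = NULL, alpha = 0.05) {
  if (inherits(M, "scenario_comparison")) M <- M$cost_matrix
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least two pathways for a paired test.", call. = FALSE)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(colnames(M), 2))
  } else if (is.list(comparisons)) {
    comparisons <- do.call(rbind, comparisons)
  }
  bad <- setdiff(as.vector(comparisons), colnames(M))
  if (length(bad)) stop(sprintf("unknown scenario column(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  n <- nrow(M)
  rows <- purrr::map(seq_len(nrow(comparisons)), function(k) {
    a <- comparisons[k, 1]; b <- comparisons[k, 2]
    d <- M[, a] - M[, b]
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      tibble::tibble(scenario_a = a, scenario_b = b, mean_diff = mean(d),
                     t = NA_real_, df = n - 1,
                     p.value = if (all(d == 0)) 1 else 0)
    } else {
      tstat <- mean(d) / (sd_d / sqrt(n))
      tibble::tibble(scenario_a = a, scenario_b = b, mean_diff = mean(d),
                     t = tstat, df = n - 1,
                     p.value = 2 * stats::pt(-abs(tstat), n - 1))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p.holm <- holm_adjust(out$p.value)
  out$significant <- out$p.holm < alpha
  out
}

#' Holm step-down adjustment
#'
#' @param p vector of raw p-values.
#' @return adjusted p-values, monotone and never below the raw values.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Saturate distance layers at an ecological radius
#'
#' Rebuilds the named distance layers with a hard cap: beyond `cap` metres a
#' feature's influence is assumed indistinguishable from absence. Keeps
#' scenario edits local — removing a feature then changes covariates only
#' within its radius of influence.
#'
#' @param stack a [covariate_stack()] holding `dist_road`,
#'   `dist_residence_large`, `dist_residence_small`, `dist_cropland` (any
#'   subset).
#' @param features the matching [feature_set()].
#' @param cap saturation radius in metres (default 3000).
#' @return the stack with capped distance layers.
#' @export
saturate_distances <- function(stack, features, cap = 3000) {
  ref <- stack$layers[[1]]
  spec <- list(dist_road = list("roads", NULL),
               dist_residence_large = list("residences", "large"),
               dist_residence_small = list("residences", "small"),
               dist_cropland = list("cropland", NULL))
  layers <- stack$layers
  for (nm in intersect(names(spec), names(layers))) {
    layers[[nm]] <- distance_to_features(ref, features, spec[[nm]][[1]],
                                         class_filter = spec[[nm]][[2]],
                                         cap = cap)
  }
  covariate_stack(layers, stack$kind, stack$labels)
}

#' Constructed predictive equation for scenario demonstrations
#'
#' A model-averaged-style predictive equation with *constructed* (not
#' fitted) effect sizes encoding a road/residence barrier landscape: a
#' strong road-avoidance effect, a weak large-residence effect, moderate
#' bamboo/mature-forest affinity, and a mild low-elevation preference.
#' Coefficients are on the population-standardised scale of the supplied
#' stack. Used by the scenario fixtures, where edits must act through known
#' pathways rather than estimated ones.
#'
#' @param stack a [covariate_stack()] with layers `elevation`, `dist_road`,
#'   `dist_residence_large`, `bamboo`, `forest_age`.
#' @param coef named coefficient vector on the standardised scale.
#' @return an `occu_avg` usable with [predict_suitability()] and
#'   [scenario_costs()].
#' @export
constructed_barrier_model <- function(stack,
                                      coef = c(`(Intercept)` = -0.2,
                                               elevation = -0.5,
                                               dist_road = 2.0,
                                               dist_residence_large = 0.4,
                                               bamboopresent = 0.6,
                                               forest_agesecondary = -0.6)) {
  terms <- c("elevation", "dist_road", "dist_residence_large", "bamboo",
             "forest_age")
  ref <- stack$layers[[1]]
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  dat <- stack_site_data(stack, idx$row, idx$col, layers = terms)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  info <- build_occ_design(dat, terms)$info
  structure(list(
    coef_occ = coef, coef_det = c(`(Intercept)` = 0),
    importance = tibble::tibble(covariate = terms, importance = 1),
    top = tibble::tibble(model = "constructed", K = length(coef) + 1,
                         AIC = NA_real_, dAIC = 0, weight = 1),
    top_weights = 1, delta_threshold = 2,
    occ_terms = terms, det_terms = character(0),
    design_meta = info$meta,
    site_summary = summarise_site_data(dat, terms)
  ), class = "occu_avg")
}

#' Road chainage where a path set crosses a road
#'
#' Returns the chainage (m along the road polyline) of the road vertex
#' nearest to the optimal path — the natural site for a tunnel under the
#' primary movement corridor.
#'
#' @param paths a `path_set`.
#' @param features a [feature_set()] with the road.
#' @param road_id which road (default 1).
#' @return chainage in metres.
#' @export
corridor_road_crossing <- function(paths, features, road_id = 1L) {
  opt <- paths$cells[[which(paths$role == "optimal")[1]]]
  road <- features$roads[features$roads$road_id == road_id, , drop = FALSE]
  ch <- polyline_chainage(road$x, road$y)
  d2 <- vapply(seq_len(nrow(opt)), function(i) {
    min((road$x - opt$x[i])^2 + (road$y - opt$y[i])^2)
  }, 0)
  i <- which.min(d2)
  vi <- which.min((road$x - opt$x[i])^2 + (road$y - opt$y[i])^2)
  ch[vi]
}

#' Bundled valley fixture for the scenario analysis
#'
#' A fully constructed demonstration landscape with known effect sizes: a
#' valley road with a strong avoidance effect, large residences lining the
#' road except along one settlement-free stretch (the corridor candidate),
#' saturating 1-km influence radii, and moderate bamboo/mature-forest
#' affinities. Twenty-five least-cost pathways are enumerated between five
#' points per valley side; the three management scenarios are built from
#' the fixture's own geometry, with the road tunnel placed under the
#' optimal corridor's crossing.
#'
#' @param seed landscape seed (default 42; the fixture is deterministic
#'   given it).
#' @param n_rows,n_cols grid size (default 80 x 80 at 100 m).
#' @return list with `landscape`, `stack` (saturated distances), `features`,
#'   `avg` (the constructed equation), `psi`, `cost`, `paths` (25 pathways),
#'   `scenarios` (restoration, relocation, tunnel), and `crossing`
#'   (tunnel chainage, m).
#' @export
valley_demo_fixture <- function(seed = 42, n_rows = 80, n_cols = 80) {
  land <- generate_landscape(landscape_config(
    n_rows = n_rows, n_cols = n_cols, seed = seed,
    n_residences = 24, n_large = 10, residence_spread = 250,
    residence_gap = c(0.40, 0.65)))
  stack <- saturate_distances(land$stack, land$features, cap = 1000)
  avg <- constructed_barrier_model(stack, coef = c(
    `(Intercept)` = 1.2, elevation = -0.3, dist_road = 3.5,
    dist_residence_large = 2.0, bamboopresent = 0.4,
    forest_agesecondary = -0.4))
  psi <- predict_suitability(avg, stack)
  cost <- cost_surface(psi)
  width_m <- n_cols * 100; height_m <- n_rows * 100
  rows <- round(seq(0.125 * n_rows, 0.875 * n_rows, length.out = 5))
  sources <- tibble::tibble(row = rows, col = round(0.1 * n_cols))
  sinks <- tibble::tibble(row = rows, col = round(0.9 * n_cols + 1))
  paths <- enumerate_pathways(cost, sources, sinks)
  crossing <- corridor_road_crossing(paths, land$features)
  valley_band <- tibble::tibble(
    x = width_m / 2 + c(-800, 800, 800, -800),
    y = c(0, 0, height_m, height_m))
  scenarios <- list(
    restoration = scenario_spec("restoration",
                                list(edit_restore_forest(valley_band))),
    relocation = scenario_spec("relocation",
                               list(edit_remove_residences("large"))),
    tunnel = scenario_spec("tunnel",
                           list(edit_tunnel(1L, crossing - 500, crossing + 500)))
  )
  list(landscape = land, stack = stack, features = land$features, avg = avg,
       psi = psi, cost = cost, paths = paths, scenarios = scenarios,
       crossing = crossing)
}
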