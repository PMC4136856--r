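#' Configuration for a synthetic valley landscape
#'
#' The generator emulates a river-valley corridor between two mountainside
#' reserve blocks: a smooth ridge-valley elevation field with its minimum
#' along a (gently meandering) north-south valley axis, a road following the
#' valley floor, residences clustered along the road (a few "large",
#' >= 3 households, the rest small), cropland polygons on the valley floor,
#' bamboo concentrated in a preferred elevation band, and patchy forest age
#' and composition fields. Distances to roads, residences and cropland are
#' derived from the features.
#'
#' @param n_rows,n_cols grid dimensions (default 200 x 200).
#' @param cell_size cell edge (m), default 100 (the working resolution of
#'   camera-grid landscape studies).
#' @param base_elev valley-floor elevation (m).
#' @param relief ridge rise above the valley floor (m).
#' @param valley_width Gaussian half-width of the valley (m).
#' @param road_wiggle meander amplitude of valley axis and road (m).
#' @param n_residences total residences; `n_large` of them are large.
#' @param n_large number of large (>= 3 household) residences along the road.
#' @param residence_spread lateral scatter of residences around the road (m).
#' @param n_cropland number of cropland polygons on the valley floor.
#' @param bamboo_prevalence peak probability of bamboo presence.
#' @param bamboo_elev_mid,bamboo_elev_sd centre and width (m) of the bamboo
#'   elevation band.
#' @param patch_scale correlation length (m) of forest patch fields.
#' @param noise_amp amplitude (m) of smooth elevation noise.
#' @param residence_gap optional length-2 fraction range of the north-south
#'   extent kept free of residences (a settlement-free valley stretch, the
#'   natural candidate for a movement corridor).
#' @param seed integer seed; the whole landscape is deterministic given it.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 200, n_cols = 200, cell_size = 100,
                             base_elev = 1000, relief = 1200,
                             valley_width = 2000, road_wiggle = 600,
                             n_residences = 30, n_large = 7,
                             residence_spread = 400, n_cropland = 6,
                             bamboo_prevalence = 0.6, bamboo_elev_mid = 1600,
                             bamboo_elev_sd = 400, patch_scale = 1500,
                             noise_amp = 60, residence_gap = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (valley_width <= 0 || valley_width > n_cols * cell_size) {
    stop("valley width must be positive and narrower than the grid.", call. = FALSE)
  }
  if (n_large > n_residences) stop("n_large cannot exceed n_residences.", call. = FALSE)
  structure(cfg, class = "landscape_config")
}

# smooth standard-normal random field via periodic FFT convolution with a
# Gaussian kernel; scale in cells
smooth_field <- function(nr, nc, scale_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale_cells <= 0.5) return(z)
  fx <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fy <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  K <- exp(-2 * pi^2 * scale_cells^2 * outer(fx^2, fy^2, `+`))
  s <- Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (nr * nc)
  (s - mean(s)) / stats::sd(s)
}

#' Generate a synthetic valley landscape
#'
#' @param config a [landscape_config()].
#' @return list with `stack` (a [covariate_stack()]) and `features`
#'   (a [feature_set()]). Layers: `elevation`, `slope_deg` (continuous),
#'   `slope_class`, `forest_age`, `forest_comp`, `bamboo`, `reserve`
#'   (categorical), and continuous distances `dist_road`,
#'   `dist_residence_large`, `dist_residence_small`, `dist_cropland`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  withr::with_seed(config$seed, generate_landscape_impl(config))
}

generate_landscape_impl <- function(cfg) {
  nr <- cfg$n_rows; nc <- cfg$n_cols; cs <- cfg$cell_size
  ref <- raster_grid(matrix(0, nr, nc), cs)
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cell_center(ref, idx$row, idx$col)
  width_m <- nc * cs; height_m <- nr * cs
  axis_x <- function(y) {
    width_m / 2 + cfg$road_wiggle * sin(2 * pi * y / (height_m / 1.5))
  }
  # idx is in column-major order (row varies fastest), so matrix() refills it
  mk <- function(v) raster_grid(matrix(v, nr, nc), cs, nodata = -9999)
  # elevation: Gaussian valley profile + smooth noise
  dx <- abs(ctr$x - axis_x(ctr$y))
  profile <- 1 - exp(-0.5 * (dx / cfg$valley_width)^2)
  noise <- smooth_field(nr, nc, cfg$patch_scale / cs)
  elev_v <- cfg$base_elev + cfg$relief * profile +
    cfg$noise_amp * noise[cbind(idx$row, idx$col)]
  elevation <- mk(elev_v)
  slopes <- slope_from_elevation(elevation)

  # road along the valley floor
  ry <- seq(0, height_m, by = 4 * cs)
  roads <- tibble::tibble(road_id = 1L, class = "provincial",
                          x = axis_x(ry), y = ry)

  # residences clustered along the road; large ones nearer the road
  n_res <- cfg$n_residences
  draw_res_y <- function(n) {
    y <- stats::runif(n, 0.05 * height_m, 0.95 * height_m)
    if (!is.null(cfg$residence_gap)) {
      lo <- cfg$residence_gap[1] * height_m; hi <- cfg$residence_gap[2] * height_m
      for (tries in 1:50) {
        bad <- y > lo & y < hi
        if (!any(bad)) break
        y[bad] <- stats::runif(sum(bad), 0.05 * height_m, 0.95 * height_m)
      }
      y[y > lo & y < hi] <- lo  # pathological configs collapse to the gap edge
    }
    y
  }
  res_y <- draw_res_y(n_res)
  is_large <- seq_len(n_res) <= cfg$n_large
  spread <- ifelse(is_large, cfg$residence_spread / 2, cfg$residence_spread)
  res_x <- axis_x(res_y) + stats::rnorm(n_res, 0, spread)
  res_x <- pmin(pmax(res_x, cs), width_m - cs)
  households <- ifelse(is_large, 3L + stats::rpois(n_res, 4), 1L + stats::rbinom(n_res, 1, 0.5))
  residences <- tibble::tibble(
    res_id = seq_len(n_res), size = residence_size_class(households),
    households = as.integer(households), x = res_x, y = res_y)

  # cropland rectangles on the valley floor
  crop <- NULL
  if (cfg$n_cropland > 0) {
    cy <- stats::runif(cfg$n_cropland, 0.1 * height_m, 0.9 * height_m)
    cx <- axis_x(cy) + stats::rnorm(cfg$n_cropland, 0, cfg$valley_width / 3)
    w <- stats::runif(cfg$n_cropland, 3, 8) * cs
    h <- stats::runif(cfg$n_cropland, 3, 8) * cs
    crop <- dplyr::bind_rows(lapply(seq_len(cfg$n_cropland), function(i) {
      tibble::tibble(poly_id = i,
                     x = pmin(pmax(c(cx[i] - w[i], cx[i] + w[i], cx[i] + w[i], cx[i] - w[i]), 0), width_m),
                     y = pmin(pmax(c(cy[i] - h[i], cy[i] - h[i], cy[i] + h[i], cy[i] + h[i]), 0), height_m))
    }))
  }

  # two national reserve blocks flanking the valley
  margin <- cfg$valley_width * 1.5
  reserves <- dplyr::bind_rows(
    tibble::tibble(poly_id = 1L, level = "national",
                   x = c(0, width_m / 2 - margin, width_m / 2 - margin, 0),
                   y = c(0, 0, height_m, height_m)),
    tibble::tibble(poly_id = 2L, level = "national",
                   x = c(width_m / 2 + margin, width_m, width_m, width_m / 2 + margin),
                   y = c(0, 0, height_m, height_m)))
  features <- feature_set(roads = roads, residences = residences,
                          cropland = crop, reserves = reserves)

  # bamboo: elevation band preference modulated by a patch field
  band <- exp(-0.5 * ((elev_v - cfg$bamboo_elev_mid) / cfg$bamboo_elev_sd)^2)
  bfield <- smooth_field(nr, nc, cfg$patch_scale / cs)[cbind(idx$row, idx$col)]
  p_bam <- pmin(1, cfg$bamboo_prevalence * band * stats::plogis(1.2 * bfield + 0.5))
  bamboo <- mk(1 + stats::rbinom(length(p_bam), 1, p_bam))

  # forest age: secondary forest concentrated near the valley floor
  afield <- smooth_field(nr, nc, cfg$patch_scale / cs)[cbind(idx$row, idx$col)]
  p_secondary <- stats::plogis(1.5 * exp(-0.5 * (dx / (2 * cfg$valley_width))^2) * 3 - 1.5 + afield)
  forest_age <- mk(ifelse(stats::runif(length(p_secondary)) < p_secondary, 2, 1))

  # forest composition: nonforest near road/cropland, else patchy 3 classes
  ffield <- smooth_field(nr, nc, cfg$patch_scale / cs)[cbind(idx$row, idx$col)]
  comp <- ifelse(ffield < -0.5, 1, ifelse(ffield < 0.6, 2, 3))  # broadleaf/mixed/conifer
  near_road <- dx < cfg$valley_width / 4
  comp[near_road & stats::runif(length(comp)) < 0.6] <- 4
  forest_comp <- mk(comp)

  # reserve membership
  in_res <- rep(1, nrow(idx))
  for (id in unique(reserves$poly_id)) {
    seg <- reserves[reserves$poly_id == id, ]
    lv <- if (seg$level[1] == "national") 3 else 2
    inside <- points_in_polygon(ctr$x, ctr$y, seg$x, seg$y)
    in_res[inside] <- pmax(in_res[inside], lv)
  }
  reserve <- mk(in_res)

  stack <- covariate_stack(
    layers = list(
      elevation = elevation, slope_deg = slopes$slope_deg,
      slope_class = slopes$slope_class, forest_age = forest_age,
      forest_comp = forest_comp, bamboo = bamboo, reserve = reserve,
      dist_road = distance_to_features(ref, features, "roads"),
      dist_residence_large = distance_to_features(ref, features, "residences", "large"),
      dist_residence_small = distance_to_features(ref, features, "residences", "small"),
      dist_cropland = distance_to_features(ref, features, "cropland")
    ),
    kind = c(elevation = "continuous", slope_deg = "continuous",
             slope_class = "categorical", forest_age = "categorical",
             forest_comp = "categorical", bamboo = "categorical",
             reserve = "categorical",
             dist_road = "continuous", dist_residence_large = "continuous",
             dist_residence_small = "continuous", dist_cropland = "continuous"),
    labels = list(slope_class = c("flat", "moderate", "steep"),
                  forest_age = c("primary", "secondary"),
                  forest_comp = c("broadleaf", "mixed", "conifer", "nonforest"),
                  bamboo = c("absent", "present"),
                  reserve = c("none", "provincial", "national"))
  )
  list(stack = stack, features = features, config = cfg)
}

#' Generating ("true") model parameters for simulation
#'
#' Occupancy coefficients are on the logit scale for *population-standardised*
#' covariates (each continuous layer z-scored over its non-nodata cells;
#' categorical terms as treatment dummies). The defaults encode the valley
#' template's ecology: occupancy higher at lower elevation, with bamboo
#' present, and far from roads; detection improved by scent lure and cool
#' weather, unaffected by camera view.
#'
#' @param beta named occupancy coefficients; names are design columns
#'   (`"(Intercept)"` plus e.g. `"elevation"`, `"bamboopresent"`).
#' @param alpha named detection coefficients (`"(Intercept)"`, `"lure"`,
#'   `"temperaturemedium"`, `"temperaturehigh"`, `"camera_viewlimited"`).
#' @param occ_terms occupancy term strings matching the covariate stack.
#' @return a `true_model` list.
#' @export
true_model <- function(beta = c(`(Intercept)` = 0.4, elevation = -1.2,
                                bamboopresent = 1.2,
                                forest_agesecondary = -1.2),
                       alpha = c(`(Intercept)` = -0.3, lure = 1.0,
                                 temperaturemedium = -0.4,
                                 temperaturehigh = -0.9,
                                 camera_viewlimited = 0),
                       occ_terms = c("elevation", "bamboo", "forest_age")) {
  if (any(!is.finite(beta)) || any(!is.finite(alpha))) {
    stop("true coefficients must be finite.", call. = FALSE)
  }
  structure(list(beta = beta, alpha = alpha, occ_terms = occ_terms),
            class = "true_model")
}

# design metadata for a stack under population standardisation
stack_design_info <- function(stack, occ_terms) {
  ref <- stack$layers[[1]]
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  data <- stack_site_data(stack, idx$row, idx$col,
                          layers = unique(vapply(occ_terms, function(t) parse_term(t)$base, "")))
  data <- data[stats::complete.cases(data), , drop = FALSE]
  list(data = data, info = build_occ_design(data, occ_terms)$info)
}

#' True occupancy surface from a generating model
#'
#' \eqn{\psi(\mathrm{cell}) = \mathrm{logit}^{-1}(\beta \cdot x)} with the
#' generating coefficients; nodata propagates.
#'
#' @param stack a [covariate_stack()].
#' @param truth a [true_model()].
#' @return a [raster_grid()] suitability map in \[0, 1\].
#' @export
simulate_truth <- function(stack, truth) {
  stopifnot(inherits(truth, "true_model"))
  miss <- setdiff(vapply(truth$occ_terms, function(t) parse_term(t)$base, ""),
                  names(stack$layers))
  if (length(miss)) stop(sprintf("stack is missing layer(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  ref <- stack$layers[[1]]
  sd_info <- stack_design_info(stack, truth$occ_terms)
  idx <- expand.grid(row = seq_len(ref$n_rows), col = seq_len(ref$n_cols))
  data <- stack_site_data(stack, idx$row, idx$col,
                          layers = unique(vapply(truth$occ_terms, function(t) parse_term(t)$base, "")))
  complete <- stats::complete.cases(data)
  X <- build_occ_design(data[complete, , drop = FALSE], truth$occ_terms,
                        info = sd_info$info)$X
  if (!all(names(truth$beta) %in% colnames(X))) {
    stop(sprintf("true beta names not in design: %s",
                 paste(setdiff(names(truth$beta), colnames(X)), collapse = ", ")),
         call. = FALSE)
  }
  psi <- rep(NA_real_, nrow(data))
  psi[complete] <- stats::plogis(drop(X[, names(truth$beta), drop = FALSE] %*% truth$beta))
  vals <- matrix(NA_real_, ref$n_rows, ref$n_cols)
  vals[cbind(idx$row, idx$col)] <- psi
  raster_grid(vals, ref$cell_size, ref$origin_x, ref$origin_y, ref$nodata)
}

#' True coefficients on the raw covariate scale
#'
#' Converts the generating (population-standardised) slopes to the raw
#' covariate scale, the scale on which fitted models can be compared to the
#' truth regardless of how either was standardised.
#'
#' @param stack the generating [covariate_stack()].
#' @param truth a [true_model()].
#' @return named numeric vector of raw-scale slopes (intercept omitted).
#' @export
truth_raw_coefficients <- function(stack, truth) {
  info <- stack_design_info(stack, truth$occ_terms)$info
  out <- c()
  for (tm in truth$occ_terms) {
    m <- info$meta[[tm]]
    pt <- parse_term(tm)
    if (m$type == "numeric") {
      nms <- switch(pt$form, raw = pt$base, log = sprintf("log(%s)", pt$base),
                    quadratic = c(pt$base, sprintf("I(%s^2)", pt$base)))
      for (k in seq_along(nms)) {
        if (nms[k] %in% names(truth$beta)) {
          out[nms[k]] <- truth$beta[[nms[k]]] / m$scale[k]
        }
      }
    } else {
      for (l in m$levels[-1]) {
        nm <- paste0(pt$base, l)
        if (nm %in% names(truth$beta)) out[nm] <- truth$beta[[nm]]
      }
    }
  }
  out
}

#' Survey design for simulated camera trapping
#'
#' @param n_sites number of survey sites.
#' @param n_occasions occasions per site (5-day segments by default).
#' @param segment_days occasion length in days.
#' @param lure_prob probability a deployment uses scent lure.
#' @param temp_probs named probabilities of the low/medium/high temperature
#'   classes for a deployment's month.
#' @param limited_view_prob probability the camera view is "limited".
#' @param min_spacing minimum distance between concurrent sites (m).
#' @return a `survey_design` list.
#' @export
survey_design <- function(n_sites = 250, n_occasions = 8, segment_days = 5,
                          lure_prob = 0.8,
                          temp_probs = c(low = 0.3, medium = 0.4, high = 0.3),
                          limited_view_prob = 0.4, min_spacing = 500) {
  stopifnot(n_sites > 0, n_occasions > 0, segment_days > 0, min_spacing >= 0)
  structure(as.list(environment()), class = "survey_design")
}

#' Simulate camera-trap surveys on a true occupancy surface
#'
#' Latent occupancy \eqn{z_i \sim \mathrm{Bern}(\psi_i)} is drawn once per
#' site (closed season); detections are
#' \eqn{y_{it} \sim \mathrm{Bern}(z_i\, p_{it})} with \eqn{p} logit-linear
#' in the generating detection coefficients and the simulated deployment
#' covariates. Sites are placed at random passable cells respecting the
#' minimum spacing.
#'
#' @param truth_map [raster_grid()] of true \eqn{\psi} (from
#'   [simulate_truth()]).
#' @param design a [survey_design()].
#' @param truth a [true_model()] (supplies detection coefficients).
#' @param stack optional [covariate_stack()]; when given, site covariate
#'   values are attached to the site table.
#' @param seed integer seed.
#' @return list with `sites` (tibble incl. `psi_true`, `z`, deployment
#'   covariates and any stack covariates) and `history`
#'   (a [detection_history()]).
#' @export
simulate_surveys <- function(truth_map, design, truth, stack = NULL, seed = 1) {
  stopifnot(inherits(design, "survey_design"), inherits(truth, "true_model"))
  withr::with_seed(seed, {
    ok <- which(!is.na(truth_map$values), arr.ind = TRUE)
    if (nrow(ok) < design$n_sites) stop("not enough passable cells for the design.",
                                        call. = FALSE)
    cand <- ok[sample.int(nrow(ok)), , drop = FALSE]
    ctr_all <- cell_center(truth_map, cand[, 1], cand[, 2])
    sel <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(sel) == design$n_sites) break
      if (length(sel)) {
        d2 <- (ctr_all$x[sel] - ctr_all$x[i])^2 + (ctr_all$y[sel] - ctr_all$y[i])^2
        if (min(d2) < design$min_spacing^2) next
      }
      sel <- c(sel, i)
    }
    if (length(sel) < design$n_sites) {
      stop(sprintf("could only place %d of %d sites at %g m spacing.",
                   length(sel), design$n_sites, design$min_spacing), call. = FALSE)
    }
    rows <- cand[sel, 1]; cols <- cand[sel, 2]
    n <- design$n_sites; T_ <- design$n_occasions
    psi <- truth_map$values[cbind(rows, cols)]
    z <- stats::rbinom(n, 1, psi)
    lure <- stats::runif(n) < design$lure_prob
    temperature <- sample(names(design$temp_probs), n, replace = TRUE,
                          prob = design$temp_probs)
    camera_view <- ifelse(stats::runif(n) < design$limited_view_prob,
                          "limited", "open")
    eta_p <- truth$alpha[["(Intercept)"]] +
      truth$alpha[["lure"]] * as.numeric(lure) +
      truth$alpha[["temperaturemedium"]] * (temperature == "medium") +
      truth$alpha[["temperaturehigh"]] * (temperature == "high") +
      truth$alpha[["camera_viewlimited"]] * (camera_view == "limited")
    p <- stats::plogis(eta_p)
    y <- matrix(stats::rbinom(n * T_, 1, rep(z * p, T_)), n, T_)
    ctr <- cell_center(truth_map, rows, cols)
    sites <- tibble::tibble(site_id = seq_len(n), row = rows, col = cols,
                            x = ctr$x, y = ctr$y, psi_true = psi, z = z,
                            p_true = p, lure = lure, temperature = temperature,
                            camera_view = camera_view)
    if (!is.null(stack)) {
      sites <- dplyr::bind_cols(sites, stack_site_data(stack, rows, cols))
    }
    rep_mat <- function(v) matrix(rep(v, T_), n, T_)
    history <- structure(list(
      y = y, site_id = sites$site_id,
      occ_cov = list(lure = rep_mat(as.numeric(lure)),
                     temperature = rep_mat(temperature),
                     camera_view = rep_mat(camera_view)),
      segment_days = design$segment_days
    ), class = "detection_history")
    list(sites = sites, history = history)
  })
}

#' Simulate validation sign-transect segments
#'
#' Segment centres are random passable cells; each is labelled presence with
#' probability \eqn{\psi} at its cell, emulating an independent sign survey
#' whose 250-m segments are classified as with or without sign.
#'
#' @param truth_map [raster_grid()] of true \eqn{\psi}.
#' @param n_segments number of segments (default 216, a realistic transect
#'   campaign for a ~400 km^2 study area).
#' @param seed integer seed.
#' @param segments_per_transect segments grouped per transect id.
#' @return tibble with `point_id`, `transect_id`, `row`, `col`, `x`, `y`,
#'   `psi_true`, `sign` (logical).
#' @export
simulate_validation_transects <- function(truth_map, n_segments = 216, seed = 1,
                                          segments_per_transect = 5) {
  stopifnot(n_segments > 0)
  withr::with_seed(seed, {
    ok <- which(!is.na(truth_map$values), arr.ind = TRUE)
    pick <- ok[sample.int(nrow(ok), n_segments), , drop = FALSE]
    psi <- truth_map$values[pick]
    ctr <- cell_center(truth_map, pick[, 1], pick[, 2])
    tibble::tibble(
      point_id = seq_len(n_segments),
      transect_id = ceiling(seq_len(n_segments) / segments_per_transect),
      row = pick[, 1], col = pick[, 2], x = ctr$x, y = ctr$y,
      psi_true = psi, sign = stats::runif(n_segments) < psi)
  })
}
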