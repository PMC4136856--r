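#' Distance-to-feature raster
#'
#' Euclidean distance (m) from every cell centre to the nearest feature of
#' the requested layer, optionally filtered by class. When no feature
#' matches the filter, every cell gets the "no feature" cap (the grid
#' diagonal by default) so covariates stay finite.
#'
#' @param grid a [raster_grid()] supplying the geometry.
#' @param features a [feature_set()].
#' @param layer one of `"roads"`, `"residences"`, `"cropland"`, `"reserves"`.
#' @param class_filter optional class/size/level label to keep (e.g.
#'   `"large"` for residences, `"provincial"` for roads).
#' @param cap distance (m) used when no feature matches; defaults to the
#'   grid diagonal.
#' @return a [raster_grid()] of distances; nodata cells of `grid` propagate.
#' @export
distance_to_features <- function(grid, features, layer,
                                 class_filter = NULL, cap = NULL) {
  stopifnot_raster(grid)
  layer <- match.arg(layer, c("roads", "residences", "cropland", "reserves"))
  tb <- features[[layer]]
  if (!is.null(class_filter)) {
    fld <- switch(layer, roads = "class", residences = "size", reserves = "level",
                  cropland = stop("cropland has no class labels.", call. = FALSE))
    if (!class_filter %in% c("local", "provincial", "small", "large", "national")) {
      stop(sprintf("unknown class label '%s'.", class_filter), call. = FALSE)
    }
    tb <- tb[tb[[fld]] == class_filter, , drop = FALSE]
  }
  if (is.null(cap)) {
    cap <- sqrt((grid$n_rows * grid$cell_size)^2 + (grid$n_cols * grid$cell_size)^2)
  }
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  ctr <- cell_center(grid, idx$row, idx$col)
  d <- rep(cap, nrow(idx))
  if (nrow(tb)) {
    if (layer == "residences") {
      for (i in seq_len(nrow(tb))) {
        d <- pmin(d, sqrt((ctr$x - tb$x[i])^2 + (ctr$y - tb$y[i])^2))
      }
    } else if (layer == "roads") {
      for (id in unique(tb$road_id)) {
        seg <- tb[tb$road_id == id, ]
        d <- pmin(d, dist_points_to_polyline(ctr$x, ctr$y, seg$x, seg$y))
      }
    } else {
      for (id in unique(tb$poly_id)) {
        seg <- tb[tb$poly_id == id, ]
        d <- pmin(d, dist_points_to_polygon(ctr$x, ctr$y, seg$x, seg$y))
      }
    }
    d <- pmin(d, cap)
  }
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  vals[cbind(idx$row, idx$col)] <- d
  vals[is.na(grid$values)] <- NA_real_
  out <- raster_grid(vals, grid$cell_size, grid$origin_x, grid$origin_y, grid$nodata)
  # remember the construction so scenario edits can recompute consistently
  attr(out, "dist_cap") <- cap
  attr(out, "dist_class") <- class_filter
  out
}

#' Slope from elevation
#'
#' Slope in degrees from the 8-neighbour finite-difference (Horn) kernel.
#' Edge cells use one-sided differences (via linear extrapolation of the
#' elevation beyond the edge, which reduces Horn to a one-sided scheme and
#' is exact on planes). A categorical companion raster cuts slope at 5 and
#' 20 degrees into classes 1 = [0,5), 2 = [5,20), 3 = [20,90].
#'
#' @param elev elevation [raster_grid()] in metres.
#' @return a list with `slope_deg` and `slope_class` rasters.
#' @export
slope_from_elevation <- function(elev) {
  stopifnot_raster(elev)
  z <- elev$values
  if (all(is.na(z))) stop("elevation raster is entirely nodata.", call. = FALSE)
  nr <- nrow(z); nc <- ncol(z)
  # fill nodata with cell's nearest finite neighbour value is overkill; Horn
  # windows touching nodata use the centre value for the missing neighbours.
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- z
  # linear extrapolation beyond each edge: z_out = 2*z_edge - z_inner
  pad[1, 2:(nc + 1)] <- 2 * z[1, ] - z[min(2, nr), ]
  pad[nr + 2, 2:(nc + 1)] <- 2 * z[nr, ] - z[max(nr - 1, 1), ]
  pad[2:(nr + 1), 1] <- 2 * z[, 1] - z[, min(2, nc)]
  pad[2:(nr + 1), nc + 2] <- 2 * z[, nc] - z[, max(nc - 1, 1)]
  pad[1, 1] <- 2 * pad[1, 2] - pad[1, 3]
  pad[1, nc + 2] <- 2 * pad[1, nc + 1] - pad[1, nc]
  pad[nr + 2, 1] <- 2 * pad[nr + 2, 2] - pad[nr + 2, 3]
  pad[nr + 2, nc + 2] <- 2 * pad[nr + 2, nc + 1] - pad[nr + 2, nc]
  nb <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ctr <- z
  fill <- function(m) { m[is.na(m)] <- ctr[is.na(m)]; m }
  a <- fill(nb(-1, -1)); b <- fill(nb(-1, 0)); cc <- fill(nb(-1, 1))
  d <- fill(nb(0, -1));                         f <- fill(nb(0, 1))
  g <- fill(nb(1, -1)); h <- fill(nb(1, 0));   i <- fill(nb(1, 1))
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * elev$cell_size)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * elev$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  cls <- matrix(NA_real_, nr, nc)
  cls[!is.na(slope)] <- cut(slope[!is.na(slope)], breaks = c(-Inf, 5, 20, Inf),
                            labels = FALSE, right = FALSE)
  mk <- function(v) raster_grid(v, elev$cell_size, elev$origin_x, elev$origin_y,
                                elev$nodata)
  list(slope_deg = mk(slope), slope_class = mk(cls))
}

#' Screen covariates for collinearity
#'
#' Greedy elimination until every retained pair has |r| below the threshold:
#' while any pair is at or above it, the member of the worst pair with the
#' larger mean absolute correlation to all other candidates is dropped. Ties
#' are broken by the `priority` order (earlier = kept), then alphabetically.
#' Zero-variance covariates are reported and dropped first.
#'
#' @param data data frame of site covariates.
#' @param covariates column names to screen.
#' @param threshold pairwise |r| cut-off (default 0.7).
#' @param priority optional character vector; covariates earlier in it win
#'   ties.
#' @return a list with `retained` (names), `dropped` (tibble of name +
#'   reason), and `correlation` (matrix over the input covariates).
#' @export
screen_collinearity <- function(data, covariates, threshold = 0.7,
                                priority = covariates) {
  if (length(covariates) < 2) stop("need at least two covariates.", call. = FALSE)
  if (nrow(data) < 3) stop("need at least three sites.", call. = FALSE)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop(sprintf("unknown covariates: %s", paste(miss, collapse = ", ")),
                         call. = FALSE)
  X <- as.matrix(data[, covariates, drop = FALSE])
  dropped <- tibble::tibble(covariate = character(0), reason = character(0))
  zero_var <- covariates[apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                                 all(is.na(v)))]
  if (length(zero_var)) {
    warning(sprintf("zero-variance covariate(s) dropped: %s",
                    paste(zero_var, collapse = ", ")))
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(covariate = zero_var,
                                                        reason = "zero variance"))
  }
  keep <- setdiff(covariates, zero_var)
  # zero-variance columns (already reported above) make cor() warn; their
  # rows/cols are NA in the reported matrix, which is fine
  cmat <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  rank_key <- function(nm) {
    p <- match(nm, priority)
    p[is.na(p)] <- length(priority) + 1L
    order(p, nm)  # not used directly; see prefer()
  }
  prefer <- function(a, b) {
    # TRUE if a should be KEPT over b on ties
    pa <- match(a, priority); pb <- match(b, priority)
    pa <- ifelse(is.na(pa), Inf, pa); pb <- ifelse(is.na(pb), Inf, pb)
    if (pa != pb) return(pa < pb)
    a < b
  }
  repeat {
    if (length(keep) < 2) break
    sub <- abs(cmat[keep, keep, drop = FALSE])
    diag(sub) <- 0
    worst <- max(sub)
    if (worst < threshold) break
    pr <- which(sub == worst, arr.ind = TRUE)[1, ]
    a <- keep[pr[1]]; b <- keep[pr[2]]
    others <- function(nm) mean(abs(cmat[nm, setdiff(keep, nm)]))
    ma <- others(a); mb <- others(b)
    victim <- if (ma > mb) a else if (mb > ma) b else if (prefer(a, b)) b else a
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      covariate = victim,
      reason = sprintf("|r| = %.3f with %s", worst, setdiff(c(a, b), victim))))
    keep <- setdiff(keep, victim)
  }
  list(retained = covariates[covariates %in% keep], dropped = dropped,
       correlation = cmat)
}

#' Choose the functional form of an occupancy covariate
#'
#' Fits three single-covariate occupancy models — raw `x`, `log(x + 1)`, and
#' quadratic `x + x^2` — with an intercept-only detection model, and keeps
#' the form with the smallest AIC. Ties go to the simpler form (raw, then
#' log, then quadratic). Non-convergent candidates are excluded with a note.
#'
#' @param history a [detection_history()].
#' @param site_data site covariate data frame aligned to the history rows.
#' @param covariate name of a continuous column of `site_data`.
#' @param n_starts optimiser starts per candidate fit.
#' @return a tibble (class `form_choice`) with one row per candidate:
#'   `covariate`, `form`, `AIC`, `converged`, `chosen`.
#' @export
select_covariate_form <- function(history, site_data, covariate, n_starts = 3) {
  if (!covariate %in% names(site_data)) {
    stop(sprintf("covariate '%s' not in site data.", covariate), call. = FALSE)
  }
  x <- site_data[[covariate]]
  if (stats::sd(x, na.rm = TRUE) == 0) {
    stop(sprintf("covariate '%s' has zero variance.", covariate), call. = FALSE)
  }
  forms <- c("raw", "log", "quadratic")
  term_of <- list(raw = covariate, log = sprintf("log(%s)", covariate),
                  quadratic = sprintf("quad(%s)", covariate))
  if (any(x < 0, na.rm = TRUE)) {
    forms <- setdiff(forms, "log")  # log(x+1) needs non-negative distances
  }
  rows <- purrr::map(forms, function(fm) {
    fit <- tryCatch(
      fit_occupancy(occu_spec(occ_terms = term_of[[fm]], det_terms = character(0)),
                    history, site_data, n_starts = n_starts),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged
    tibble::tibble(covariate = covariate, form = fm,
                   AIC = if (ok) fit$AIC else NA_real_, converged = ok)
  })
  out <- dplyr::bind_rows(rows)
  ok <- which(out$converged)
  if (!length(ok)) stop(sprintf("no candidate form converged for '%s'.", covariate),
                        call. = FALSE)
  best_aic <- min(out$AIC[ok])
  # ties (within numerical noise) resolved toward the simpler form; `forms`
  # is already ordered raw > log > quadratic
  chosen <- ok[which(out$AIC[ok] <= best_aic + 1e-8)][1]
  out$chosen <- seq_len(nrow(out)) == chosen
  class(out) <- c("form_choice", class(out))
  out
}
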