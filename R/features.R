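#' Construct a feature set
#'
#' Vector features of the landscape: roads (polylines with class local or
#' provincial), residences (points, small < 3 households vs large >= 3),
#' cropland polygons and reserve polygons (protection level none, provincial
#' or national). Geometries are stored as long tibbles of vertices in planar
#' metres.
#'
#' @param roads tibble with `road_id`, `class` ("local"/"provincial"), `x`,
#'   `y` (vertices in order along the line).
#' @param residences tibble with `res_id`, `size` ("small"/"large"),
#'   `households`, `x`, `y`.
#' @param cropland tibble with `poly_id`, `x`, `y` (polygon rings, closed
#'   implicitly).
#' @param reserves tibble with `poly_id`, `level` ("provincial"/"national"),
#'   `x`, `y`.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(roads = NULL, residences = NULL, cropland = NULL,
                        reserves = NULL) {
  empty <- function(cols) {
    tibble::as_tibble(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  if (is.null(roads)) roads <- tibble::tibble(road_id = integer(0),
                                              class = character(0),
                                              x = numeric(0), y = numeric(0))
  if (is.null(residences)) residences <- tibble::tibble(res_id = integer(0),
                                                        size = character(0),
                                                        households = integer(0),
                                                        x = numeric(0), y = numeric(0))
  if (is.null(cropland)) cropland <- tibble::tibble(poly_id = integer(0),
                                                    x = numeric(0), y = numeric(0))
  if (is.null(reserves)) reserves <- tibble::tibble(poly_id = integer(0),
                                                    level = character(0),
                                                    x = numeric(0), y = numeric(0))
  if (nrow(roads) && !all(roads$class %in% c("local", "provincial"))) {
    stop("road class must be 'local' or 'provincial'.", call. = FALSE)
  }
  if (nrow(residences) && !all(residences$size %in% c("small", "large"))) {
    stop("residence size must be 'small' or 'large'.", call. = FALSE)
  }
  if (nrow(reserves) && !all(reserves$level %in% c("provincial", "national"))) {
    stop("reserve level must be 'provincial' or 'national'.", call. = FALSE)
  }
  for (tb in list(roads, residences, cropland, reserves)) {
    if (nrow(tb) && any(!is.finite(tb$x) | !is.finite(tb$y))) {
      stop("feature coordinates must be finite.", call. = FALSE)
    }
  }
  structure(list(roads = tibble::as_tibble(roads),
                 residences = tibble::as_tibble(residences),
                 cropland = tibble::as_tibble(cropland),
                 reserves = tibble::as_tibble(reserves)),
            class = "feature_set")
}

#' @method print feature_set
#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d road(s), %d residence(s), %d cropland polygon(s), %d reserve(s)\n",
              length(unique(x$roads$road_id)), nrow(x$residences),
              length(unique(x$cropland$poly_id)), length(unique(x$reserves$poly_id))))
  invisible(x)
}

# residence size class from household count (large >= 3 households)
residence_size_class <- function(households) {
  ifelse(households >= 3, "large", "small")
}

#' Write a feature set to GeoJSON
#'
#' Roads become LineString features, residences Point features, cropland and
#' reserves Polygon features; class attributes travel in `properties`.
#' Coordinates are the package's planar metres (no CRS member is written).
#'
#' @param features a [feature_set()].
#' @param path destination `.geojson` file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  feats <- list()
  add <- function(geom_type, coords, props) {
    feats[[length(feats) + 1]] <<- list(
      type = "Feature",
      geometry = list(type = geom_type, coordinates = coords),
      properties = props
    )
  }
  for (id in unique(features$roads$road_id)) {
    seg <- features$roads[features$roads$road_id == id, ]
    add("LineString", unname(as.matrix(seg[, c("x", "y")])),
        list(layer = "road", road_id = id, class = seg$class[1]))
  }
  if (nrow(features$residences)) {
    for (i in seq_len(nrow(features$residences))) {
      r <- features$residences[i, ]
      add("Point", c(r$x, r$y),
          list(layer = "residence", res_id = r$res_id, size = r$size,
               households = r$households))
    }
  }
  poly_coords <- function(tb) {
    m <- unname(as.matrix(tb[, c("x", "y")]))
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])  # close ring
    list(m)
  }
  for (id in unique(features$cropland$poly_id)) {
    add("Polygon", poly_coords(features$cropland[features$cropland$poly_id == id, ]),
        list(layer = "cropland", poly_id = id))
  }
  for (id in unique(features$reserves$poly_id)) {
    seg <- features$reserves[features$reserves$poly_id == id, ]
    add("Polygon", poly_coords(seg),
        list(layer = "reserve", poly_id = id, level = seg$level[1]))
  }
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature set from GeoJSON written by [write_features()]
#'
#' @param path a `.geojson` file.
#' @return a [feature_set()].
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path)
  if (is.null(obj$type) || obj$type != "FeatureCollection") {
    stop(sprintf("%s is not a GeoJSON FeatureCollection.", path), call. = FALSE)
  }
  roads <- list(); res <- list(); crop <- list(); resv <- list()
  for (f in obj$features) {
    p <- f$properties; g <- f$geometry
    mat_of <- function(coords) {
      do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
    }
    if (identical(p$layer, "road")) {
      m <- mat_of(g$coordinates)
      roads[[length(roads) + 1]] <- tibble::tibble(
        road_id = p$road_id, class = p$class, x = m[, 1], y = m[, 2])
    } else if (identical(p$layer, "residence")) {
      res[[length(res) + 1]] <- tibble::tibble(
        res_id = p$res_id, size = p$size,
        households = as.integer(p$households),
        x = g$coordinates[[1]], y = g$coordinates[[2]])
    } else if (identical(p$layer, "cropland")) {
      m <- mat_of(g$coordinates[[1]])
      m <- m[-nrow(m), , drop = FALSE]  # drop closing vertex
      crop[[length(crop) + 1]] <- tibble::tibble(poly_id = p$poly_id,
                                                 x = m[, 1], y = m[, 2])
    } else if (identical(p$layer, "reserve")) {
      m <- mat_of(g$coordinates[[1]])
      m <- m[-nrow(m), , drop = FALSE]
      resv[[length(resv) + 1]] <- tibble::tibble(poly_id = p$poly_id,
                                                 level = p$level,
                                                 x = m[, 1], y = m[, 2])
    }
  }
  bind0 <- function(l) if (length(l)) dplyr::bind_rows(l) else NULL
  feature_set(roads = bind0(roads), residences = bind0(res),
              cropland = bind0(crop), reserves = bind0(resv))
}

# ---- planar geometry helpers -------------------------------------------

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2); vectorised
# over points.
dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# minimum distance from points to a polyline given as vertex tibble
dist_points_to_polyline <- function(px, py, vx, vy) {
  if (length(vx) == 1) return(sqrt((px - vx)^2 + (py - vy)^2))
  d2 <- rep(Inf, length(px))
  for (k in seq_len(length(vx) - 1)) {
    d2 <- pmin(d2, dist2_point_segment(px, py, vx[k], vy[k], vx[k + 1], vy[k + 1]))
  }
  sqrt(d2)
}

# point-in-polygon (even-odd rule); vectorised over points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a polygon: 0 inside, else distance to boundary
dist_points_to_polygon <- function(px, py, vx, vy) {
  d <- dist_points_to_polyline(px, py, c(vx, vx[1]), c(vy, vy[1]))
  d[points_in_polygon(px, py, vx, vy)] <- 0
  d
}

# cumulative chainage (m) along a polyline's vertices
polyline_chainage <- function(vx, vy) {
  c(0, cumsum(sqrt(diff(vx)^2 + diff(vy)^2)))
}
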