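#' Movement cost surface from a suitability map
#'
#' Inverts habitat suitability into per-cell movement cost. The default is
#' the affine inversion \eqn{c = c_{\min} + S (1 - \psi)} (range
#' \eqn{[c_{\min}, c_{\min} + S]}, strictly positive and bounded — the
#' dominant convention in connectivity studies). A reciprocal option
#' \eqn{c = 1/\max(\psi, \epsilon)} is available since "inverse" is
#' ambiguous in the literature.
#'
#' @param psi [raster_grid()] of occupancy probability in \[0, 1\].
#' @param scale affine scale S (default 99, giving range 1-100).
#' @param cost_min minimum cost (default 1).
#' @param method `"affine"` (default) or `"reciprocal"`.
#' @param eps floor for \eqn{\psi} under the reciprocal method.
#' @return a [raster_grid()] of costs with a `provenance` attribute.
#' @export
cost_surface <- function(psi, scale = 99, cost_min = 1, method = "affine",
                         eps = 1e-3) {
  stopifnot_raster(psi)
  method <- match.arg(method, c("affine", "reciprocal"))
  v <- psi$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("suitability values must lie in [0, 1].", call. = FALSE)
  }
  cv <- if (method == "affine") cost_min + scale * (1 - v) else 1 / pmax(v, eps)
  out <- raster_grid(cv, psi$cell_size, psi$origin_x, psi$origin_y, psi$nodata)
  attr(out, "provenance") <- list(method = method, scale = scale,
                                  cost_min = cost_min)
  out
}

#' Accumulated-cost and backlink rasters (Dijkstra)
#'
#' Runs Dijkstra's algorithm over the 8-neighbour raster graph from a set of
#' source cells. Edge weights average the two cell costs times the step
#' length (cell size, or \eqn{\sqrt 2} times it diagonally). The backlink
#' raster codes each cell's optimal predecessor direction (0 = source,
#' 1-8 = N, NE, E, SE, S, SW, W, NW); unreachable and nodata cells are NA.
#'
#' @param cost a cost [raster_grid()] (strictly positive; NA impassable).
#' @param sources tibble/data frame with `row`, `col` of source cells.
#' @return list with `accumulation` and `backlink` [raster_grid()]s.
#' @export
accumulated_cost <- function(cost, sources) {
  stopifnot_raster(cost)
  sources <- as.data.frame(sources)
  if (!nrow(sources)) stop("at least one source cell is required.", call. = FALSE)
  res <- .dijkstra_grid(cost$values, cost$cell_size,
                        as.integer(sources$row), as.integer(sources$col))
  mk <- function(v) raster_grid(v, cost$cell_size, cost$origin_x, cost$origin_y,
                                cost$nodata)
  bl <- res$backlink
  storage.mode(bl) <- "double"
  list(accumulation = mk(res$accumulation), backlink = mk(bl))
}

# compass steps 1..8 = N, NE, E, SE, S, SW, W, NW as (drow, dcol)
compass_steps <- function() {
  cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1), dc = c(0, 1, 1, 1, 0, -1, -1, -1))
}

#' Trace a least-cost path from the backlink raster
#'
#' Follows predecessor directions from the destination back to the nearest
#' source, then reverses. The traced total cost equals the accumulation at
#' the destination.
#'
#' @param acc accumulation [raster_grid()] from [accumulated_cost()].
#' @param backlink backlink [raster_grid()] from the same call.
#' @param destination list/row with `row`, `col`.
#' @return a `corridor_path`: list with `cells` tibble (row, col, x, y),
#'   `total_cost`, `length_m`, `cost_index` (cost per 100 m).
#' @export
trace_least_cost_path <- function(acc, backlink, destination) {
  r <- as.integer(destination$row); c <- as.integer(destination$col)
  if (is.na(backlink$values[r, c])) {
    stop("destination is unreachable from the sources.", call. = FALSE)
  }
  steps <- compass_steps()
  rows <- r; cols <- c
  repeat {
    code <- backlink$values[r, c]
    if (code == 0) break
    r <- unname(r + steps[code, 1]); c <- unname(c + steps[code, 2])
    rows <- c(rows, r); cols <- c(cols, c)
    if (length(rows) > acc$n_rows * acc$n_cols) {
      stop("backlink cycle detected; corrupt backlink raster.", call. = FALSE)
    }
  }
  rows <- rev(rows); cols <- rev(cols)
  ctr <- cell_center(acc, rows, cols)
  len <- path_length_m(rows, cols, acc$cell_size)
  total <- acc$values[destination$row, destination$col]
  structure(list(
    cells = tibble::tibble(row = rows, col = cols, x = ctr$x, y = ctr$y),
    total_cost = total, length_m = len,
    cost_index = if (len > 0) total * 100 / len else NA_real_
  ), class = "corridor_path")
}

path_length_m <- function(rows, cols, cell_size) {
  if (length(rows) < 2) return(0)
  drs <- diff(rows); dcs <- diff(cols)
  sum(ifelse(drs != 0 & dcs != 0, sqrt(2), 1)) * cell_size
}

#' @method print corridor_path
#' @export
print.corridor_path <- function(x, ...) {
  cat(sprintf("<corridor_path> %d cells, length %.0f m, total cost %.2f, cost/100m %.2f\n",
              nrow(x$cells), x$length_m, x$total_cost, x$cost_index))
  invisible(x)
}

#' Cost-per-100-m index of a path
#'
#' @param path a `corridor_path`, or a list with `total_cost` and `length_m`.
#' @return total accumulated cost scaled to a 100-m basis.
#' @export
path_cost_index <- function(path) {
  if (is.null(path$length_m) || path$length_m <= 0) {
    stop("path has zero length; cost index undefined.", call. = FALSE)
  }
  path$total_cost * 100 / path$length_m
}

#' Re-evaluate a path geometry on a (possibly different) cost surface
#'
#' Sums the edge weights mean(cost_a, cost_b) * step length along a fixed
#' cell sequence. Used to re-cost baseline pathways under scenario-edited
#' landscapes.
#'
#' @param cells tibble with `row`, `col` along the path.
#' @param cost cost [raster_grid()].
#' @return list with `total_cost`, `length_m`, `cost_index`; `total_cost`
#'   is NA if the path crosses an impassable cell.
#' @export
evaluate_path_cost <- function(cells, cost) {
  stopifnot_raster(cost)
  rows <- cells$row; cols <- cells$col
  cv <- cost$values[cbind(rows, cols)]
  len <- path_length_m(rows, cols, cost$cell_size)
  if (anyNA(cv)) {
    return(list(total_cost = NA_real_, length_m = len, cost_index = NA_real_))
  }
  if (length(rows) < 2) return(list(total_cost = 0, length_m = 0, cost_index = NA_real_))
  drs <- diff(rows); dcs <- diff(cols)
  if (any(abs(drs) > 1 | abs(dcs) > 1 | (drs == 0 & dcs == 0))) {
    stop("path cells are not 8-connected.", call. = FALSE)
  }
  step <- ifelse(drs != 0 & dcs != 0, sqrt(2), 1) * cost$cell_size
  total <- sum(0.5 * (cv[-length(cv)] + cv[-1]) * step)
  list(total_cost = total, length_m = len, cost_index = total * 100 / len)
}

#' Enumerate least-cost pathways between source and sink point sets
#'
#' One least-cost path per source x sink pair (for 5 points per side, the
#' classic 25-pathway set). The globally cheapest pathway is flagged
#' `"optimal"`, the rest `"alternative"`. Unreachable pairs are recorded as
#' infeasible rather than dropped.
#'
#' @param cost cost [raster_grid()].
#' @param sources,sinks tibbles with either `row`/`col` or `x`/`y` columns.
#' @return a `path_set` tibble: `path_id`, `source_id`, `sink_id`,
#'   `total_cost`, `length_m`, `cost_index`, `role`
#'   ("optimal"/"alternative"/"infeasible"), and a `cells` list column.
#' @export
enumerate_pathways <- function(cost, sources, sinks) {
  to_cells <- function(tb) {
    tb <- tibble::as_tibble(tb)
    if (!all(c("row", "col") %in% names(tb))) {
      cc <- cell_at(cost, tb$x, tb$y)
      tb$row <- cc$row; tb$col <- cc$col
    }
    if (anyNA(tb$row) || anyNA(tb$col)) stop("point outside the grid.", call. = FALSE)
    if (anyNA(cost$values[cbind(tb$row, tb$col)])) {
      stop("all source/sink points must be on passable cells.", call. = FALSE)
    }
    tb
  }
  src <- to_cells(sources); snk <- to_cells(sinks)
  out <- list()
  pid <- 0L
  for (i in seq_len(nrow(src))) {
    accres <- accumulated_cost(cost, src[i, c("row", "col")])
    for (j in seq_len(nrow(snk))) {
      pid <- pid + 1L
      feasible <- !is.na(accres$accumulation$values[snk$row[j], snk$col[j]])
      if (feasible) {
        p <- trace_least_cost_path(accres$accumulation, accres$backlink,
                                   list(row = snk$row[j], col = snk$col[j]))
        out[[pid]] <- tibble::tibble(
          path_id = pid, source_id = i, sink_id = j,
          total_cost = p$total_cost, length_m = p$length_m,
          cost_index = p$cost_index, role = "alternative",
          cells = list(p$cells))
      } else {
        out[[pid]] <- tibble::tibble(
          path_id = pid, source_id = i, sink_id = j,
          total_cost = NA_real_, length_m = NA_real_, cost_index = NA_real_,
          role = "infeasible", cells = list(NULL))
      }
    }
  }
  tab <- dplyr::bind_rows(out)
  feas <- which(!is.na(tab$total_cost))
  if (length(feas)) tab$role[feas[which.min(tab$total_cost[feas])]] <- "optimal"
  class(tab) <- c("path_set", class(tab))
  tab
}

#' @method print path_set
#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %d pathway(s): %d optimal, %d alternative, %d infeasible\n",
              nrow(x), sum(x$role == "optimal"), sum(x$role == "alternative"),
              sum(x$role == "infeasible")))
  print(tibble::as_tibble(x)[, setdiff(names(x), "cells")], n = 10)
  invisible(x)
}

#' @method autoplot path_set
#' @export
autoplot.path_set <- function(object, ...) {
  segs <- dplyr::bind_rows(purrr::map(seq_len(nrow(object)), function(i) {
    cells <- object$cells[[i]]
    if (is.null(cells)) return(NULL)
    dplyr::mutate(cells, path_id = object$path_id[i], role = object$role[i])
  }))
  ggplot2::ggplot(segs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$path_id,
                                     colour = .data$role)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = NULL)
}
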