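#' Build a conductance graph from a cost surface
#'
#' The landscape becomes a resistor network: every passable (non-nodata)
#' cell is a node, every 8-neighbour adjacency an edge with resistance
#' mean(cost_a, cost_b) * step length and conductance its reciprocal — the
#' same edge weights as the least-cost analysis, so the two connectivity
#' models are directly comparable.
#'
#' @param cost cost [raster_grid()] (strictly positive; NA impassable).
#' @return a `conductance_graph`: node index rasters, edge tibble
#'   (`i`, `j`, `resistance`, `conductance`), sparse Laplacian, component
#'   membership.
#' @export
build_conductance_graph <- function(cost) {
  stopifnot_raster(cost)
  passable <- !is.na(cost$values)
  if (sum(passable) < 2) stop("need at least two passable cells.", call. = FALSE)
  if (any(cost$values <= 0, na.rm = TRUE)) {
    stop("cost values must be strictly positive where passable.", call. = FALSE)
  }
  nr <- cost$n_rows; nc <- cost$n_cols
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[passable] <- seq_len(sum(passable))
  n <- sum(passable)
  # half the compass rose to enumerate each undirected edge once
  steps <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  step_len <- c(1, 1, sqrt(2), sqrt(2)) * cost$cell_size
  el <- list()
  for (k in 1:4) {
    dr <- steps[k, 1]; dc <- steps[k, 2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    a <- as.vector(node_id[r1, c1, drop = FALSE])
    b <- as.vector(node_id[r1 + dr, c1 + dc, drop = FALSE])
    ca <- as.vector(cost$values[r1, c1, drop = FALSE])
    cb <- as.vector(cost$values[r1 + dr, c1 + dc, drop = FALSE])
    keep <- !is.na(a) & !is.na(b)
    if (any(keep)) {
      el[[k]] <- tibble::tibble(
        i = a[keep], j = b[keep],
        resistance = 0.5 * (ca[keep] + cb[keep]) * step_len[k])
    }
  }
  edges <- dplyr::bind_rows(el)
  edges$conductance <- 1 / edges$resistance
  L <- Matrix::sparseMatrix(
    i = c(edges$i, edges$j, edges$i, edges$j),
    j = c(edges$j, edges$i, edges$i, edges$j),
    x = c(-edges$conductance, -edges$conductance,
          edges$conductance, edges$conductance),
    dims = c(n, n))
  g <- igraph::graph_from_edgelist(cbind(edges$i, edges$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  structure(list(node_id = node_id, n_nodes = n, edges = edges,
                 laplacian = L, component = comp, cost = cost),
            class = "conductance_graph")
}

#' @method print conductance_graph
#' @export
print.conductance_graph <- function(x, ...) {
  cat(sprintf("<conductance_graph> %d nodes, %d edges, %d component(s)\n",
              x$n_nodes, nrow(x$edges), max(x$component)))
  invisible(x)
}

graph_nodes_at <- function(graph, cells) {
  cells <- as.data.frame(cells)
  ids <- graph$node_id[cbind(cells$row, cells$col)]
  if (anyNA(ids)) stop("terminal cell is impassable (nodata).", call. = FALSE)
  ids
}

# per-node current density: half the summed absolute branch currents
node_current_density <- function(graph, potentials) {
  dv <- abs(potentials[graph$edges$i] - potentials[graph$edges$j])
  branch <- dv * graph$edges$conductance
  dens <- numeric(graph$n_nodes)
  agg_i <- rowsum(branch, graph$edges$i)
  agg_j <- rowsum(branch, graph$edges$j)
  dens[as.integer(rownames(agg_i))] <- dens[as.integer(rownames(agg_i))] + agg_i[, 1]
  dens[as.integer(rownames(agg_j))] <- dens[as.integer(rownames(agg_j))] + agg_j[, 1]
  dens / 2
}

current_raster <- function(graph, dens) {
  vals <- matrix(NA_real_, graph$cost$n_rows, graph$cost$n_cols)
  vals[!is.na(graph$node_id)] <- dens[graph$node_id[!is.na(graph$node_id)]]
  raster_grid(vals, graph$cost$cell_size, graph$cost$origin_x,
              graph$cost$origin_y, graph$cost$nodata)
}

#' Solve the circuit between source and ground terminal sets
#'
#' Grounds are fixed at potential 0 and removed from the Laplacian; the
#' injected current (split equally over the source cells) drives the
#' reduced Kirchhoff system \eqn{L_{ff} v = I}. Effective resistance is the
#' mean source potential divided by the injected current; per-cell current
#' density is half the summed absolute branch currents.
#'
#' @param graph a [build_conductance_graph()] result.
#' @param source_cells,ground_cells tibbles with `row`, `col` (disjoint,
#'   same component).
#' @param current total injected current (default 1).
#' @return a `circuit_result`: `potentials` (per node), `current_map`
#'   ([raster_grid()]), `effective_resistance`, `kirchhoff_residual`
#'   (max relative imbalance at non-terminal nodes).
#' @export
solve_pairwise <- function(graph, source_cells, ground_cells, current = 1) {
  stopifnot(inherits(graph, "conductance_graph"))
  src <- graph_nodes_at(graph, source_cells)
  gnd <- graph_nodes_at(graph, ground_cells)
  if (length(intersect(src, gnd))) {
    stop("source and ground cells must be disjoint.", call. = FALSE)
  }
  if (length(unique(graph$component[c(src, gnd)])) != 1) {
    stop("source and ground are in disconnected components.", call. = FALSE)
  }
  keep <- setdiff(seq_len(graph$n_nodes), gnd)
  rhs <- numeric(graph$n_nodes)
  rhs[src] <- current / length(src)
  v_red <- tryCatch(
    as.numeric(Matrix::solve(graph$laplacian[keep, keep], rhs[keep])),
    error = function(e) stop("singular circuit system: ", conditionMessage(e),
                             call. = FALSE))
  potentials <- numeric(graph$n_nodes)
  potentials[keep] <- v_red
  # Kirchhoff residual at non-terminal nodes, relative to injected current
  resid <- as.numeric(graph$laplacian %*% potentials) - rhs
  interior <- setdiff(seq_len(graph$n_nodes), c(src, gnd))
  kres <- if (length(interior)) max(abs(resid[interior])) / current else 0
  dens <- node_current_density(graph, potentials)
  structure(list(
    potentials = potentials,
    current_map = current_raster(graph, dens),
    effective_resistance = mean(potentials[src]) / current,
    kirchhoff_residual = kres,
    source_nodes = src, ground_nodes = gnd, current = current
  ), class = "circuit_result")
}

#' @method print circuit_result
#' @export
print.circuit_result <- function(x, ...) {
  cat(sprintf("<circuit_result> R_eff = %.6g, Kirchhoff residual = %.2e\n",
              x$effective_resistance, x$kirchhoff_residual))
  invisible(x)
}

#' Omnidirectional (buffered) cumulative current map
#'
#' Pads the cost surface with a uniform-cost buffer, places focal nodes
#' evenly around the buffer perimeter, solves a current source-ground pair
#' for every focal pair (or a seeded subsample), sums the per-cell current
#' densities, and crops the buffer off. The buffer removes the edge bias of
#' focal placement; one Cholesky factorisation (with a single fixed ground
#' node) is reused across all pairs.
#'
#' @param cost cost [raster_grid()].
#' @param buffer_width buffer width in cells (>= 1).
#' @param n_perimeter_nodes focal nodes on the buffer perimeter (>= 2).
#' @param pair_subsample optional number of focal pairs to solve (all pairs
#'   when NULL).
#' @param seed seed for the pair subsample.
#' @param buffer_cost per-cell cost of the buffer (default: mean passable
#'   cost).
#' @return cumulative current [raster_grid()] on the original extent.
#' @export
omnidirectional_current <- function(cost, buffer_width = 5,
                                    n_perimeter_nodes = 16,
                                    pair_subsample = NULL, seed = 1,
                                    buffer_cost = NULL) {
  stopifnot_raster(cost)
  if (buffer_width < 1) stop("buffer_width must be >= 1 cell.", call. = FALSE)
  if (n_perimeter_nodes < 2) stop("need at least two perimeter nodes.", call. = FALSE)
  if (is.null(buffer_cost)) buffer_cost <- mean(cost$values, na.rm = TRUE)
  nr <- cost$n_rows; nc <- cost$n_cols; b <- buffer_width
  padded <- matrix(buffer_cost, nr + 2 * b, nc + 2 * b)
  padded[(b + 1):(b + nr), (b + 1):(b + nc)] <- cost$values
  # interior nodata stays impassable; the buffer ring is uniformly passable
  pad_grid <- raster_grid(padded, cost$cell_size,
                          cost$origin_x - b * cost$cell_size,
                          cost$origin_y - b * cost$cell_size, cost$nodata)
  graph <- build_conductance_graph(pad_grid)

  # perimeter ring cells in clockwise order from the NW corner
  pr <- nrow(padded); pc <- ncol(padded)
  ring <- rbind(
    cbind(1, 1:pc), cbind(2:pr, pc), cbind(pr, (pc - 1):1), cbind((pr - 1):2, 1))
  focal_idx <- unique(round(seq(1, nrow(ring), length.out = n_perimeter_nodes + 1)))
  focal_idx <- focal_idx[seq_len(min(n_perimeter_nodes, length(focal_idx)))]
  focal <- ring[focal_idx, , drop = FALSE]
  focal_nodes <- graph$node_id[focal]
  pairs <- utils::combn(seq_len(nrow(focal)), 2)
  if (!is.null(pair_subsample) && pair_subsample < ncol(pairs)) {
    pick <- withr::with_seed(seed, sample.int(ncol(pairs), pair_subsample))
    pairs <- pairs[, pick, drop = FALSE]
  }
  # one fixed ground: drop the first focal node's row/col, factorise once;
  # injecting +I at a and -I at b needs no explicit ground per pair
  gnd <- focal_nodes[1]
  keep <- setdiff(seq_len(graph$n_nodes), gnd)
  L_red <- graph$laplacian[keep, keep]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(L_red), LDL = FALSE, perm = TRUE)
  pos <- integer(graph$n_nodes)
  pos[keep] <- seq_along(keep)
  dens_total <- numeric(graph$n_nodes)
  for (k in seq_len(ncol(pairs))) {
    a <- focal_nodes[pairs[1, k]]; z <- focal_nodes[pairs[2, k]]
    rhs <- numeric(length(keep))
    if (a != gnd) rhs[pos[a]] <- rhs[pos[a]] + 1
    if (z != gnd) rhs[pos[z]] <- rhs[pos[z]] - 1
    v <- numeric(graph$n_nodes)
    v[keep] <- as.numeric(Matrix::solve(fac, rhs))
    dens_total <- dens_total + node_current_density(graph, v)
  }
  cur <- current_raster(graph, dens_total)
  vals <- cur$values[(b + 1):(b + nr), (b + 1):(b + nc), drop = FALSE]
  raster_grid(vals, cost$cell_size, cost$origin_x, cost$origin_y, cost$nodata)
}

#' Corridor width along a transect of a current map
#'
#' An artifact convention for summarising a corridor's breadth: take the
#' currents along a straight transect, threshold them at their q-quantile,
#' and report the longest contiguous run of strictly-above-threshold cells
#' times the cell size.
#'
#' @param current_map cumulative current [raster_grid()].
#' @param axis `"row"` (east-west transect) or `"col"` (north-south).
#' @param index row or column index of the transect.
#' @param q quantile threshold (default 0.75).
#' @return width in metres (0 when no cell exceeds the threshold).
#' @export
measure_corridor_width <- function(current_map, axis = c("col", "row"), index,
                                   q = 0.75) {
  stopifnot_raster(current_map)
  axis <- match.arg(axis)
  nmax <- if (axis == "row") current_map$n_rows else current_map$n_cols
  if (index < 1 || index > nmax) stop("transect lies outside the grid.", call. = FALSE)
  v <- if (axis == "row") current_map$values[index, ] else current_map$values[, index]
  v <- v[!is.na(v)]
  if (!length(v)) return(0)
  thr <- stats::quantile(v, q, names = FALSE)
  above <- v > thr
  if (!any(above)) return(0)
  runs <- rle(above)
  max(runs$lengths[runs$values]) * current_map$cell_size
}
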