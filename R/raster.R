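#' Construct a raster grid
#'
#' A `raster_grid` is the package's common spatial currency: a numeric matrix
#' of cell values plus planar-metre geometry. Row 1 is the top (northernmost)
#' row and cell centres, not corners, carry the values. Nodata cells are held
#' as `NA` internally; the `nodata` sentinel is only used on disk.
#'
#' All coordinates are planar metres with no datum: study areas of a few tens
#' of kilometres do not need geodesy, and synthetic landscapes have none.
#'
#' @param values numeric matrix (rows x cols); `NA` marks nodata cells.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin_x,origin_y coordinates (m) of the lower-left corner of the
#'   grid.
#' @param nodata sentinel value written to file for `NA` cells.
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, nrow = 2), cell_size = 100)
#' cell_center(g, 1, 1)
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = 0,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres).", call. = FALSE)
  }
  if (any(is.infinite(values))) {
    stop("raster values must be finite or NA (nodata).", call. = FALSE)
  }
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @method print raster_grid
#' @export
print.raster_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<raster_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  cat(sprintf("  values: [%g, %g], %d nodata cell(s)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

stopifnot_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_raster_grid(x)) stop(sprintf("`%s` must be a raster_grid.", arg), call. = FALSE)
  invisible(x)
}

same_geometry <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

#' Coordinates of a cell centre
#'
#' Rows are numbered from the top: row 1 is the northernmost row, so its
#' centre has the largest y. Inverse of [cell_at()].
#'
#' @param grid a [raster_grid()].
#' @param row,col 1-based cell indices (vectors allowed, recycled).
#' @return a tibble with columns `x`, `y` (metres).
#' @export
cell_center <- function(grid, row, col) {
  stopifnot_raster(grid)
  n <- max(length(row), length(col))
  row <- rep_len(as.integer(row), n); col <- rep_len(as.integer(col), n)
  if (any(row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols)) {
    stop("cell index out of range.", call. = FALSE)
  }
  tibble::tibble(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y + (grid$n_rows - row + 0.5) * grid$cell_size
  )
}

#' Cell indices containing a point
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates in metres (vectors allowed).
#' @return a tibble with columns `row`, `col`; `NA` for points off the grid.
#' @export
cell_at <- function(grid, x, y) {
  stopifnot_raster(grid)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Parses the plain-text `.asc` dialect (ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value header followed by row-major values, first row =
#' north). Cells equal to the declared nodata sentinel become `NA`.
#'
#' @param path file to read.
#' @param format raster dialect; only `"ascii_grid"` is supported.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, format = "ascii_grid") {
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported by this build; use format = \"ascii_grid\".",
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 6) stop(sprintf("malformed ASCII grid header in %s: fewer than 6 lines", path), call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("malformed ASCII grid header line %d in %s: '%s'", i, path, lines[i]),
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop(sprintf("malformed ASCII grid header value in %s: '%s'", path, lines[i]),
           call. = FALSE)
    }
    hdr[[tolower(parts[1])]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("malformed ASCII grid header in %s: missing %s", path,
                 paste(setdiff(need, names(hdr)), collapse = ", ")), call. = FALSE)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  if (length(body) != nr) {
    stop(sprintf("ASCII grid %s declares %d rows but has %d data lines", path, nr,
                 length(body)), call. = FALSE)
  }
  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) != nc || anyNA(v)) {
      stop(sprintf("ASCII grid %s row %d has %d values, expected %d numeric values",
                   path, i, length(v), nc), call. = FALSE)
    }
    v
  })
  vals <- do.call(rbind, rows)
  vals[vals == hdr$nodata_value] <- NA_real_
  raster_grid(vals, cell_size = hdr$cellsize, origin_x = hdr$xllcorner,
              origin_y = hdr$yllcorner, nodata = hdr$nodata_value)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' `NA` cells are written as the grid's nodata sentinel. Overwriting an
#' existing file succeeds with a warning.
#'
#' @param grid a [raster_grid()].
#' @param path destination file.
#' @param format raster dialect; only `"ascii_grid"` is supported.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, format = "ascii_grid") {
  stopifnot_raster(grid)
  format <- match.arg(format, c("ascii_grid", "geotiff"))
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported by this build; use format = \"ascii_grid\".",
         call. = FALSE)
  }
  if (file.exists(path)) warning(sprintf("overwriting existing raster file %s", path))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(vals, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Convert a raster to a long tibble
#'
#' One row per cell with indices, centre coordinates and value; handy for
#' dplyr/ggplot2 work.
#'
#' @param grid a [raster_grid()].
#' @param drop_na drop nodata cells?
#' @return tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
raster_to_tibble <- function(grid, drop_na = FALSE) {
  stopifnot_raster(grid)
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  ctr <- cell_center(grid, idx$row, idx$col)
  out <- tibble::tibble(row = idx$row, col = idx$col, x = ctr$x, y = ctr$y,
                        value = grid$values[cbind(idx$row, idx$col)])
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

#' Plot a raster grid
#'
#' @param object a [raster_grid()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_to_tibble(object, drop_na = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Build a covariate stack
#'
#' A named collection of co-registered rasters plus a kind tag per layer
#' (`"continuous"` or `"categorical"`); categorical layers carry ordered
#' category labels and hold 1-based integer codes (or NA).
#'
#' @param layers named list of [raster_grid()]s sharing geometry.
#' @param kind named character vector, `"continuous"` or `"categorical"` per
#'   layer; defaults to all continuous.
#' @param labels named list of character label vectors for categorical layers.
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, kind = NULL, labels = list()) {
  if (length(layers) == 0 || is.null(names(layers)) || any(!nzchar(names(layers)))) {
    stop("`layers` must be a non-empty named list of raster_grid objects.", call. = FALSE)
  }
  for (nm in names(layers)) stopifnot_raster(layers[[nm]], nm)
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!same_geometry(ref, layers[[nm]])) {
      stop(sprintf("layer '%s' does not share the stack geometry.", nm), call. = FALSE)
    }
  }
  if (is.null(kind)) kind <- stats::setNames(rep("continuous", length(layers)), names(layers))
  kind <- kind[names(layers)]
  if (anyNA(kind) || !all(kind %in% c("continuous", "categorical"))) {
    stop("`kind` must tag every layer as 'continuous' or 'categorical'.", call. = FALSE)
  }
  for (nm in names(layers)[kind == "categorical"]) {
    v <- layers[[nm]]$values
    codes <- v[!is.na(v)]
    if (length(codes) && any(codes != round(codes) | codes < 1)) {
      stop(sprintf("categorical layer '%s' must hold 1-based integer codes.", nm),
           call. = FALSE)
    }
    if (!is.null(labels[[nm]]) && length(codes) &&
        max(codes) > length(labels[[nm]])) {
      stop(sprintf("categorical layer '%s' has codes beyond its label list.", nm),
           call. = FALSE)
    }
  }
  structure(list(layers = layers, kind = kind, labels = labels),
            class = "covariate_stack")
}

#' @method print covariate_stack
#' @export
print.covariate_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<covariate_stack> %d layer(s) on %d x %d grid @ %g m\n",
              length(x$layers), g$n_rows, g$n_cols, g$cell_size))
  for (nm in names(x$layers)) cat(sprintf("  %s (%s)\n", nm, x$kind[[nm]]))
  invisible(x)
}

#' Extract stack values at cells
#'
#' @param stack a [covariate_stack()].
#' @param row,col cell indices.
#' @return tibble with one column per layer.
#' @export
stack_values_at <- function(stack, row, col) {
  out <- purrr::map(stack$layers, function(l) l$values[cbind(row, col)])
  tibble::as_tibble(out)
}
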