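#' Grid specification for the common analysis grid
#'
#' All layers of an analysis share one regular grid of square cells in a
#' projected (metre) coordinate system. Row 1 is the northernmost row and
#' `origin_x`/`origin_y` locate the top-left corner of the top-left cell.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (default 30 m, the common
#'   resolution of the analysis).
#' @param origin_x,origin_y Top-left corner coordinates in metres.
#' @param crs_label Free-text label of the projected CRS; never interpreted.
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(10, 10)
#' cell_area(gs)   # 900 m^2
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 30,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_label = "local-metres") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_label = as.character(crs_label)),
    class = "grid_spec")
}

#' @rdname grid_spec
#' @param spec A `grid_spec`.
#' @export
cell_area <- function(spec) spec$cell_size^2

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_label))
  invisible(x)
}

specs_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol
}

#' Single-band raster layer on an analysis grid
#'
#' A thin wrapper around a numeric matrix: row-major with row 1 north, plus
#' the grid metadata and a units label. Missing cells are held as `NA`
#' internally; a numeric nodata sentinel is only used at the file boundary.
#' `NA` never participates in arithmetic: all operations either propagate it
#' or mask it out explicitly.
#'
#' @param values Numeric matrix of dim `n_rows x n_cols`.
#' @param spec The `grid_spec` the values live on.
#' @param units Free-text units label (e.g. "mm", "t/pixel").
#' @return An object of class `es_raster`.
#' @export
es_raster <- function(values, spec, units = "") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop(sprintf("values are %d x %d but spec is %d x %d",
                 nrow(values), ncol(values), spec$n_rows, spec$n_cols))
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec, units = as.character(units)),
            class = "es_raster")
}

#' @export
print.es_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<es_raster> %d x %d [%s], %d NA, range [%s, %s]\n",
              nrow(v), ncol(v), x$units, sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @export
as.matrix.es_raster <- function(x, ...) x$values

# Internal: lift a matrix-valued computation back onto the grid.
wrap_raster <- function(values, template, units = template$units) {
  es_raster(values, template$spec, units)
}

check_coregistered <- function(...) {
  layers <- list(...)
  ref <- layers[[1]]$spec
  for (l in layers[-1]) {
    if (!specs_equal(ref, l$spec))
      stop("layers are not co-registered: grid specs differ")
  }
  invisible(ref)
}

#' Named collection of co-registered raster layers plus keyed tables
#'
#' The unit of data passed between pipeline stages. All layers share one
#' `grid_spec`; `tables` holds keyed record tables such as the per-subdistrict
#' water-use table.
#'
#' @param spec Common `grid_spec`.
#' @param layers Named list of `es_raster` objects.
#' @param tables Named list of data frames.
#' @return An object of class `landscape_stack`.
#' @export
landscape_stack <- function(spec, layers = list(), tables = list()) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(layers)) {
    if (is.null(names(layers)) || any(names(layers) == ""))
      stop("all layers must be named")
    for (nm in names(layers)) {
      l <- layers[[nm]]
      if (!inherits(l, "es_raster")) stop("layer '", nm, "' is not an es_raster")
      if (!specs_equal(spec, l$spec))
        stop("layer '", nm, "' is not on the stack grid")
    }
  }
  structure(list(spec = spec, layers = layers, tables = tables),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d, %d layers (%s), %d tables\n",
              x$spec$n_rows, x$spec$n_cols, length(x$layers),
              paste(names(x$layers), collapse = ", "), length(x$tables)))
  invisible(x)
}

stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers))
    stop("stack is missing required layer '", name, "'")
  stack$layers[[name]]
}

# Coordinates of cell centers; row 1 is north.
cell_centers <- function(spec) {
  x <- spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  y <- spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  list(x = x, y = y)
}
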