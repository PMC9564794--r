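#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The ASCII grid header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) carries the full grid geometry in plain text. Cells equal to
#' the file's nodata sentinel are mapped to `NA` on read.
#'
#' @param path Path to a `.asc` file.
#' @param expected_spec Optional `grid_spec`; if given, the file's grid must
#'   match it exactly or an alignment error naming both grids is raised.
#' @param units Units label to attach (ASCII grid has no units field; stacks
#'   record units in their layer manifest).
#' @return An `es_raster`.
#' @seealso [write_ascii_grid()], [write_landscape_stack()]
#' @export
read_ascii_grid <- function(path, expected_spec = NULL, units = "") {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  spec <- grid_spec(nr, nc, hdr$cellsize,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize)
  if (!is.null(expected_spec) && !specs_equal(spec, expected_spec))
    stop(sprintf(paste0(
      "grid alignment error: file %s has %dx%d cells of %g m at (%g, %g) ",
      "but %dx%d cells of %g m at (%g, %g) were expected"),
      path, spec$n_rows, spec$n_cols, spec$cell_size, spec$origin_x,
      spec$origin_y, expected_spec$n_rows, expected_spec$n_cols,
      expected_spec$cell_size, expected_spec$origin_x, expected_spec$origin_y))
  es_raster(m, spec, units)
}

#' Write a raster layer as an ESRI ASCII grid file
#'
#' `NA` cells are written as the nodata sentinel. Read followed by write
#' round-trips values (to full printed precision), the nodata mask, and the
#' grid geometry.
#'
#' @param layer An `es_raster`.
#' @param path Output path.
#' @param nodata Numeric sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "es_raster"))
  spec <- layer$spec
  m <- layer$values
  if (any(m[!is.na(m)] == nodata))
    stop("layer contains the nodata sentinel ", nodata, " as a real value")
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Write / read a landscape stack as a directory of ASCII grids
#'
#' Layers go to `<name>.asc`; a `layers.csv` manifest records name, file and
#' units; tables go to `table_<name>.csv`.
#'
#' @param stack A `landscape_stack`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) or a `landscape_stack` (read).
#' @export
write_landscape_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "landscape_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(name = character(), file = character(),
                         units = character())
  for (nm in names(stack$layers)) {
    f <- paste0(nm, ".asc")
    write_ascii_grid(stack$layers[[nm]], file.path(dir, f))
    manifest <- rbind(manifest, data.frame(name = nm, file = f,
                                           units = stack$layers[[nm]]$units))
  }
  utils::write.csv(manifest, file.path(dir, "layers.csv"), row.names = FALSE)
  for (nm in names(stack$tables))
    utils::write.csv(stack$tables[[nm]],
                     file.path(dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_landscape_stack
#' @export
read_landscape_stack <- function(dir) {
  mf <- file.path(dir, "layers.csv")
  if (!file.exists(mf)) stop("no layers.csv manifest in ", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  layers <- list(); spec <- NULL
  for (i in seq_len(nrow(manifest))) {
    l <- read_ascii_grid(file.path(dir, manifest$file[i]),
                         expected_spec = spec, units = manifest$units[i])
    if (is.null(spec)) spec <- l$spec
    layers[[manifest$name[i]]] <- l
  }
  tables <- list()
  for (f in list.files(dir, pattern = "^table_.*\\.csv$")) {
    nm <- sub("^table_", "", sub("\\.csv$", "", f))
    tables[[nm]] <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  }
  landscape_stack(spec, layers, tables)
}
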