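#' Gridded climate layers for one year or period
#'
#' A `climate_stack` bundles one or more named raster layers (matrices) that
#' share a single grid geometry, together with the year (or period label) the
#' layers describe. Layers are stored as plain numeric matrices with `NA` as
#' the nodata value; row 1 is the northernmost (top) row, following the usual
#' raster convention.
#'
#' The grid geometry is the tuple (`xmin`, `ymax`, `cell_size`, `nrow`,
#' `ncol`) in planar km coordinates: the top-left corner of the grid sits at
#' (`xmin`, `ymax`) and cell `[r, c]` covers the half-open rectangle
#' `[xmin + (c-1)*cs, xmin + c*cs)` by `(ymax - r*cs, ymax - (r-1)*cs]`,
#' so every point inside the extent maps to exactly one cell.
#'
#' @param layers named list of numeric matrices, all with identical dimensions.
#' @param year integer year, or a character period label such as `"2011-2015"`.
#' @param xmin,ymax coordinates of the grid's top-left corner (km).
#' @param cell_size cell edge length (km), positive.
#'
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(layers, year, xmin = 0, ymax = NULL, cell_size = 1) {
  if (!is.list(layers) || length(layers) == 0 || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    abort("`layers` must be a non-empty named list of matrices.")
  }
  if (anyDuplicated(names(layers))) abort("Layer names must be unique.")
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims == dims[, 1])) abort("All layers must share one grid geometry.")
  assert_scalar_number(cell_size, "cell_size", positive = TRUE)
  nr <- unname(dims[1, 1]); nc <- unname(dims[2, 1])
  if (is.null(ymax)) ymax <- nr * cell_size
  xmin <- unname(xmin); ymax <- unname(ymax)
  structure(
    list(
      year = year,
      layers = lapply(layers, unname),
      geometry = list(xmin = xmin, ymax = ymax, cell_size = cell_size,
                      nrow = nr, ncol = nc)
    ),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<climate_stack> %s | %d x %d cells @ %g km | %d layer(s): %s\n",
              as.character(x$year), g$nrow, g$ncol, g$cell_size,
              length(x$layers), paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.climate_stack <- function(x) names(x$layers)

stack_geometry <- function(stack) stack$geometry

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$geometry[c("xmin", "ymax", "cell_size", "nrow", "ncol")],
                   b$geometry[c("xmin", "ymax", "cell_size", "nrow", "ncol")]))
}

# Map planar points to 1-based (row, col) indices; points outside the extent
# get NA. Half-open cells: left/top edges belong to a cell, right/bottom don't.
point_to_cell <- function(geometry, x, y) {
  col <- floor((x - geometry$xmin) / geometry$cell_size) + 1
  row <- floor((geometry$ymax - y) / geometry$cell_size) + 1
  # the top edge y == ymax belongs to row 1
  row[y == geometry$ymax] <- 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > geometry$ncol | row < 1 | row > geometry$nrow
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

# Cell-centre coordinates for every cell, as a tibble in row-major order.
cell_centres <- function(geometry) {
  rc <- expand.grid(col = seq_len(geometry$ncol), row = seq_len(geometry$nrow))
  tibble::tibble(
    row = rc$row,
    col = rc$col,
    x = geometry$xmin + (rc$col - 0.5) * geometry$cell_size,
    y = geometry$ymax - (rc$row - 0.5) * geometry$cell_size
  )
}

# Extract layer values at (row, col) index pairs; NA indices give NA.
layer_values_at <- function(layer, row, col) {
  out <- rep(NA_real_, length(row))
  ok <- !is.na(row) & !is.na(col)
  out[ok] <- layer[cbind(row[ok], col[ok])]
  out
}

#' Convert a climate stack to a long tibble
#'
#' One row per cell per layer, with cell-centre coordinates; convenient for
#' ggplot2 and for joining against occurrence records.
#'
#' @param x a [climate_stack()].
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `variable`, `value`.
#' @export
tidy.climate_stack <- function(x, ...) {
  cc <- cell_centres(x$geometry)
  purrr::map_dfr(names(x$layers), function(v) {
    dplyr::mutate(cc,
      variable = v,
      value = as.vector(t(x$layers[[v]])),
      year = x$year
    )
  })
}

#' Write / read a climate stack as ESRI ASCII grids plus a manifest
#'
#' Each layer is written as one plain-text ESRI ASCII grid
#' (`<variable>_<year>.asc`) and a `manifest.csv` records the
#' variable-to-file mapping so the stack can be re-assembled. Nodata cells
#' are written using the declared nodata sentinel.
#'
#' @param stack a [climate_stack()].
#' @param dir output directory (created if missing).
#' @param nodata nodata sentinel written to file (default `-9999`).
#' @return `write_climate_stack()` returns the manifest tibble invisibly;
#'   `read_climate_stack()` returns a [climate_stack()].
#' @export
write_climate_stack <- function(stack, dir, nodata = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- stack$geometry
  files <- character(0)
  for (v in names(stack$layers)) {
    f <- file.path(dir, sprintf("%s_%s.asc", v, as.character(stack$year)))
    write_esri_ascii(stack$layers[[v]], f, g, nodata)
    files <- c(files, basename(f))
  }
  manifest <- tibble::tibble(variable = names(stack$layers),
                             year = as.character(stack$year), file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_climate_stack
#' @param year which year to read when the manifest covers several.
#' @export
read_climate_stack <- function(dir, year = NULL) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv found in '%s'.", dir))
  manifest <- readr::read_csv(mf, show_col_types = FALSE,
                              col_types = readr::cols(.default = "c"))
  if (!is.null(year)) manifest <- manifest[manifest$year == as.character(year), ]
  if (nrow(manifest) == 0) abort("Manifest has no layers for the requested year.")
  yr <- unique(manifest$year)
  if (length(yr) > 1) abort("Manifest covers several years; pass `year`.")
  parsed <- lapply(file.path(dir, manifest$file), read_esri_ascii)
  layers <- lapply(parsed, `[[`, "values")
  names(layers) <- manifest$variable
  hdr <- parsed[[1]]$header
  yr_num <- suppressWarnings(as.integer(yr))
  climate_stack(layers, year = if (is.na(yr_num)) yr else yr_num,
                xmin = hdr$xllcorner,
                ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                cell_size = hdr$cellsize)
}

write_esri_ascii <- function(mat, path, geometry, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", geometry$ncol),
    sprintf("NROWS %d", geometry$nrow),
    sprintf("XLLCORNER %.10g", geometry$xmin),
    sprintf("YLLCORNER %.10g", geometry$ymax - geometry$nrow * geometry$cell_size),
    sprintf("CELLSIZE %.10g", geometry$cell_size),
    sprintf("NODATA_VALUE %.10g", nodata)
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  # ESRI ASCII rows run from the top of the grid down, matching matrix rows
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " ")), con)
  invisible(path)
}

read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr_n <- 6
  hdr <- list()
  for (i in seq_len(hdr_n)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-seq_len(hdr_n)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  list(values = m, header = hdr)
}
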