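#' Occurrence-probability raster
#'
#' Per-cell calibrated occurrence probability on the geometry of the input
#' climate stack; cells where any input variable is nodata are nodata in the
#' output. Provenance (stack label, variable list) travels with the object.
#'
#' @name probability_raster
NULL

new_probability_raster <- function(values, geometry, label, variables) {
  structure(
    list(values = values, geometry = geometry, label = label,
         variables = variables),
    class = "probability_raster"
  )
}

#' @export
print.probability_raster <- function(x, ...) {
  g <- x$geometry
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<probability_raster> %s | %d x %d cells | %d nodata | range [%.3f, %.3f]\n",
              as.character(x$label), g$nrow, g$ncol, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Apply a calibrated model across a climate grid
#'
#' Predicts the calibrated occurrence probability for every grid cell from
#' that cell's covariate vector. Cells are evaluated in blocks of
#' `block_size` cells; the result is independent of the block size.
#'
#' @param model a [niche_model()].
#' @param stack a [climate_stack()] providing every model variable.
#' @param block_size number of cells predicted per block.
#' @return A [probability_raster].
#' @export
predict_raster <- function(model, stack, block_size = 10000) {
  missing <- setdiff(model$variables, names(stack$layers))
  if (length(missing)) {
    abort(sprintf("Stack lacks model variable(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  g <- stack$geometry
  n_cells <- g$nrow * g$ncol
  covar <- matrix(NA_real_, n_cells, length(model$variables),
                  dimnames = list(NULL, model$variables))
  for (v in model$variables) covar[, v] <- as.vector(stack$layers[[v]])
  valid <- which(!apply(covar, 1, anyNA))
  out <- rep(NA_real_, n_cells)
  for (start in seq(1, length(valid), by = block_size)) {
    idx <- valid[start:min(start + block_size - 1, length(valid))]
    out[idx] <- predict_probability(model, covar[idx, , drop = FALSE])
  }
  new_probability_raster(matrix(out, g$nrow, g$ncol),
                         g, label = stack$year, variables = model$variables)
}

#' Average climate layers across years
#'
#' Per-cell, per-variable arithmetic mean over a set of climate stacks with
#' identical geometry and variables; a cell that is nodata in any year is
#' nodata in the mean. Used to map long-run colonisation potential from
#' multi-year mean climate (the model is applied to the averaged layers,
#' not averaged over yearly prediction maps).
#'
#' @param stacks list of [climate_stack()]s.
#' @return A [climate_stack()] whose label records the period.
#' @export
average_layers <- function(stacks) {
  if (length(stacks) == 0) abort("Need at least one stack.")
  first <- stacks[[1]]
  for (st in stacks[-1]) {
    if (!same_geometry(first, st)) abort("Stacks differ in grid geometry.")
    if (!setequal(names(first$layers), names(st$layers))) {
      abort("Stacks differ in variable sets.")
    }
  }
  years <- vapply(stacks, function(s) as.character(s$year), character(1))
  label <- if (length(stacks) == 1) years else {
    yrs <- suppressWarnings(as.integer(years))
    if (!anyNA(yrs)) sprintf("%d-%d", min(yrs), max(yrs)) else paste(years, collapse = ",")
  }
  layers <- lapply(names(first$layers), function(v) {
    Reduce(`+`, lapply(stacks, function(s) s$layers[[v]])) / length(stacks)
  })
  names(layers) <- names(first$layers)
  g <- first$geometry
  climate_stack(layers, year = label, xmin = g$xmin, ymax = g$ymax,
                cell_size = g$cell_size)
}

#' Bin a probability raster into suitability categories
#'
#' Either cuts probabilities into labelled bins (default: 20-percent-wide
#' classes, the usual suitability-map legend) or applies a single threshold
#' giving a binary suitable/unsuitable map (cells at exactly the threshold
#' count as suitable).
#'
#' @param raster a [probability_raster].
#' @param bins increasing vector of bin edges spanning `[0, 1]`.
#' @param threshold alternative to `bins`: a single probability cut-off.
#' @return A list of class `categorical_raster` with an integer category
#'   matrix and the category `levels`.
#' @export
classify_raster <- function(raster, bins = seq(0, 1, 0.2), threshold = NULL) {
  p <- raster$values
  if (!is.null(threshold)) {
    assert_scalar_number(threshold, "threshold")
    cat_idx <- ifelse(is.na(p), NA_integer_, ifelse(p >= threshold, 2L, 1L))
    levels <- c("unsuitable", "suitable")
  } else {
    if (any(diff(bins) <= 0)) abort("`bins` must be strictly increasing.")
    cat_idx <- matrix(findInterval(p, bins, rightmost.closed = TRUE),
                      nrow(p), ncol(p))
    cat_idx[is.na(p)] <- NA_integer_
    levels <- sprintf("%g-%g%%", 100 * bins[-length(bins)], 100 * bins[-1])
  }
  structure(list(categories = cat_idx, levels = levels,
                 geometry = raster$geometry, label = raster$label),
            class = "categorical_raster")
}

#' @export
tidy.probability_raster <- function(x, ...) {
  cc <- cell_centres(x$geometry)
  cc$probability <- as.vector(t(x$values))
  cc$label <- as.character(x$label)
  cc
}

#' Write a probability raster as an ESRI ASCII grid
#'
#' @param raster a [probability_raster].
#' @param path output `.asc` path.
#' @param nodata nodata sentinel.
#' @return `path`, invisibly.
#' @export
write_probability_raster <- function(raster, path, nodata = -9999) {
  write_esri_ascii(raster$values, path, raster$geometry, nodata)
}
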