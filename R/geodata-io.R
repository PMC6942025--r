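#' Read species occurrence records
#'
#' Reads one occurrence table (CSV, or XLSX when the readxl package is
#' installed) with columns `species`, `year`, `x`, `y`; `species` may instead
#' be supplied via the `species` argument when the file holds a single
#' species, mirroring per-species database exports. Rows whose year or
#' coordinates cannot be parsed are dropped and the number of dropped rows is
#' reported.
#'
#' @param path path to a `.csv` or `.xlsx` file.
#' @param species species id to assign when the file has no `species` column.
#' @param roles optional named character vector `species -> role`
#'   (`"invasive"` or `"native"`); when given, a `role` column is attached
#'   and species missing from the map raise an error.
#' @param years optional integer vector; keep only these collection years.
#'
#' @return A tibble with columns `species`, `year`, `x`, `y` (and `role`).
#' @export
read_occurrences <- function(path, species = NULL, roles = NULL, years = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  raw <- read_table_any(path)
  names(raw) <- tolower(names(raw))
  if (!"species" %in% names(raw)) {
    if (is.null(species)) abort("Missing required column: 'species' (or pass `species=`).")
    raw$species <- species
  }
  for (col in c("year", "x", "y")) {
    if (!col %in% names(raw)) abort(sprintf("Missing required column: '%s'.", col))
  }
  if (nrow(raw) == 0) {
    warn(sprintf("'%s' contains no records.", basename(path)))
    return(tibble::tibble(species = character(0), year = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  parsed <- tibble::tibble(
    species = as.character(raw$species),
    year = suppressWarnings(as.integer(raw$year)),
    x = suppressWarnings(as.numeric(raw$x)),
    y = suppressWarnings(as.numeric(raw$y))
  )
  ok <- !is.na(parsed$year) & parsed$year >= 1000 & parsed$year <= 9999 &
    is.finite(parsed$x) & is.finite(parsed$y)
  if (any(!ok)) {
    inform(sprintf("read_occurrences: dropped %d of %d rows with unparseable year or coordinates.",
                   sum(!ok), nrow(parsed)))
  }
  out <- parsed[ok, ]
  if (!is.null(years)) out <- out[out$year %in% years, ]
  if (!is.null(roles)) {
    unknown <- setdiff(unique(out$species), names(roles))
    if (length(unknown)) {
      abort(sprintf("No role assigned for species: %s.",
                    paste(unknown, collapse = ", ")))
    }
    out$role <- unname(roles[out$species])
  }
  out
}

read_table_any <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading Excel files requires the 'readxl' package.")
    }
    tibble::as_tibble(readxl::read_excel(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Attach gridded covariate values to occurrence records
#'
#' Each record is joined to the values of the requested variables at the grid
#' cell containing its point, taken from the climate stack of the record's
#' own collection year (no interpolation: nearest-cell containment with
#' half-open cells). Records falling outside the grid extent or on nodata
#' cells are excluded; the exclusion counts are attached as the
#' `"exclusions"` attribute and reported.
#'
#' @param records tibble of occurrence records (`species`, `year`, `x`, `y`,
#'   plus any extra columns, which are preserved).
#' @param stacks list of [climate_stack()]s named by year (or a single
#'   stack, used for all records regardless of year).
#' @param variables ordered character vector of variables to attach; default
#'   all variables of the first stack.
#'
#' @return The records tibble with one numeric column per variable appended,
#'   rows with excluded records removed, in the original row order.
#' @export
attach_features <- function(records, stacks, variables = NULL) {
  if (inherits(stacks, "climate_stack")) {
    stacks <- stats::setNames(list(stacks), as.character(stacks$year))
    by_year <- FALSE
  } else {
    by_year <- TRUE
  }
  variables <- variables %||% names(stacks[[1]]$layers)
  for (st in stacks) {
    missing <- setdiff(variables, names(st$layers))
    if (length(missing)) {
      abort(sprintf("Stack '%s' lacks variable(s): %s.",
                    as.character(st$year), paste(missing, collapse = ", ")))
    }
  }
  if (by_year) {
    missing_years <- setdiff(unique(as.character(records$year)), names(stacks))
    if (length(missing_years)) {
      abort(sprintf("No climate stack for year(s): %s.",
                    paste(missing_years, collapse = ", ")))
    }
  }
  vals <- matrix(NA_real_, nrow(records), length(variables),
                 dimnames = list(NULL, variables))
  outside <- rep(FALSE, nrow(records))
  for (key in if (by_year) unique(as.character(records$year)) else names(stacks)) {
    sel <- if (by_year) which(as.character(records$year) == key) else seq_len(nrow(records))
    st <- stacks[[key]]
    cell <- point_to_cell(st$geometry, records$x[sel], records$y[sel])
    outside[sel] <- is.na(cell$row)
    for (v in variables) {
      vals[sel, v] <- layer_values_at(st$layers[[v]], cell$row, cell$col)
    }
  }
  nodata <- !outside & apply(vals, 1, anyNA)
  keep <- !outside & !nodata
  if (any(!keep)) {
    inform(sprintf("attach_features: excluded %d record(s) outside the extent and %d on nodata cells.",
                   sum(outside), sum(nodata)))
  }
  out <- dplyr::bind_cols(records[keep, , drop = FALSE],
                          tibble::as_tibble(vals[keep, , drop = FALSE]))
  attr(out, "exclusions") <- c(outside = sum(outside), nodata = sum(nodata))
  attr(out, "variables") <- variables
  out
}

#' Read and write labelled feature tables
#'
#' A feature table is the classifier's input: one row per occurrence with
#' `species`, `role` (`invasive`/`native`), `year`, `x`, `y` and one numeric
#' column per covariate. `write_feature_table()` / `read_feature_table()`
#' round-trip through CSV with full double precision.
#'
#' @param table a feature tibble.
#' @param path a `.csv` (or, for reading, `.xlsx`) file path.
#' @param variables covariates that must be present; default: every column
#'   not among the metadata columns.
#' @return `read_feature_table()` returns the feature tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, variables = NULL) {
  tab <- read_table_any(path)
  meta <- intersect(c("species", "role", "year", "x", "y", "date"), names(tab))
  vars <- variables %||% setdiff(names(tab), meta)
  missing <- setdiff(vars, names(tab))
  if (length(missing)) {
    abort(sprintf("Feature table lacks variable column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (v in vars) {
    bad <- which(!is.na(tab[[v]]) & is.na(suppressWarnings(as.numeric(tab[[v]]))))
    if (length(bad)) {
      abort(sprintf("Non-numeric covariate value in column '%s', row %d.",
                    v, bad[1]))
    }
    tab[[v]] <- as.numeric(tab[[v]])
  }
  if ("year" %in% names(tab)) tab$year <- as.integer(tab$year)
  tibble::as_tibble(tab)
}

# Covariate columns of a feature table (everything except record metadata).
feature_variables <- function(table) {
  vars <- attr(table, "variables")
  if (!is.null(vars)) return(vars)
  setdiff(names(table), c("species", "role", "year", "x", "y", "date"))
}

#' Assign the binary training-class label
#'
#' Attaches (or validates) the `role` column that marks each record as
#' belonging to the `invasive` target class or the pooled `native` contrast
#' class.
#'
#' @param table occurrence or feature tibble with a `species` column.
#' @param roles named character vector `species -> "invasive"/"native"`;
#'   omit if the table already has a `role` column.
#' @return The tibble with a validated `role` column.
#' @export
label_classes <- function(table, roles = NULL) {
  if (!is.null(roles)) {
    unknown <- setdiff(unique(table$species), names(roles))
    if (length(unknown)) {
      abort(sprintf("No role assigned for species: %s.",
                    paste(unknown, collapse = ", ")))
    }
    table$role <- unname(roles[table$species])
  }
  if (!"role" %in% names(table)) {
    abort("Feature table needs a `role` column (or pass `roles=`).")
  }
  bad <- setdiff(unique(table$role), c("invasive", "native"))
  if (length(bad)) {
    abort(sprintf("Roles must be 'invasive' or 'native'; found: %s.",
                  paste(bad, collapse = ", ")))
  }
  table
}
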