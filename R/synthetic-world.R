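#' Canonical weather variables
#'
#' The eight seasonal/monthly weather covariates the niche model is built on:
#' mean temperatures of spring (T13), September (T09), October (T10) and
#' December (T12) in degrees Celsius; precipitation sums of February (P02),
#' April (P04) and June (P06) in mm; and the autumn drought index (D15,
#' index units), which is consumed as a supplied layer.
#'
#' @return Character vector of variable names.
#' @export
canonical_variables <- function() {
  c("T13", "T09", "T10", "T12", "P02", "P04", "P06", "D15")
}

# Climatological level and spatial spread used by the field generator, per
# canonical variable; values are plausible central-European magnitudes so the
# raw-unit RBF kernel sees realistic squared distances. Unknown variables
# fall back to mean 0, sd 1. Precipitation is truncated at zero.
default_climate_norms <- function() {
  tibble::tribble(
    ~variable, ~mean, ~sd, ~nonnegative,
    "T13", 8.5, 1.8, FALSE,
    "T09", 13.5, 1.6, FALSE,
    "T10", 9.0, 1.6, FALSE,
    "T12", 1.5, 2.0, FALSE,
    "P02", 45, 20, TRUE,
    "P04", 45, 20, TRUE,
    "P06", 75, 30, TRUE,
    "D15", 2.0, 0.8, TRUE
  )
}

#' Configuration of a synthetic world
#'
#' Describes the virtual study region: grid dimensions, the years for which
#' weather grids exist, the variable set, and the two parameters of the
#' random weather fields — `smoothness`, the spatial correlation length in
#' km, and `noise_scale`, the relative amplitude of year-specific anomalies
#' on top of each variable's persistent spatial pattern (0 makes all years
#' identical).
#'
#' @param rows,cols grid dimensions (cells); `rows * cols >= 4`.
#' @param cell_size cell edge length in km.
#' @param years integer vector of simulated years.
#' @param variables character vector of layer names.
#' @param smoothness spatial correlation length of the weather fields (km).
#' @param noise_scale inter-annual anomaly amplitude relative to each
#'   variable's spatial standard deviation; non-negative.
#' @param seed integer seed controlling every weather field in this world.
#' @param climate_norms optional tibble (`variable`, `mean`, `sd`,
#'   `nonnegative`) overriding the per-variable field level and spread.
#'
#' @return An object of class `world_config`.
#' @export
world_config <- function(rows = 60, cols = 60, cell_size = 1,
                         years = 2011:2015,
                         variables = canonical_variables(),
                         smoothness = 15, noise_scale = 0.35,
                         seed = 1, climate_norms = NULL) {
  if (rows * cols < 4) abort("The grid must have at least 4 cells.")
  if (length(years) == 0) abort("`years` must be non-empty.")
  if (anyDuplicated(variables)) abort("`variables` must be unique.")
  assert_scalar_number(smoothness, "smoothness", positive = TRUE)
  assert_scalar_number(noise_scale, "noise_scale", nonnegative = TRUE)
  norms <- default_climate_norms()
  if (!is.null(climate_norms)) {
    norms <- dplyr::rows_upsert(norms, tibble::as_tibble(climate_norms),
                                by = "variable")
  }
  missing <- setdiff(variables, norms$variable)
  if (length(missing)) {
    norms <- dplyr::bind_rows(norms, tibble::tibble(
      variable = missing, mean = 0, sd = 1, nonnegative = FALSE))
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_size = cell_size, years = as.integer(years),
         variables = variables, smoothness = smoothness,
         noise_scale = noise_scale, seed = as.integer(seed),
         climate_norms = norms),
    class = "world_config"
  )
}

#' Per-variable Gaussian niche response of a virtual species
#'
#' A species' suitability in a cell is the product over variables of
#' `exp(-weight * ((value - optimum) / breadth)^2)`: a unimodal bell around
#' the species' optimum whose width is set by `breadth` (in the variable's
#' own units) and whose importance by `weight` (0 switches the variable off).
#'
#' @param species_id species identifier.
#' @param response tibble with columns `variable`, `optimum`, `breadth`
#'   (positive, variable units) and `weight` (in `[0, 1]`).
#' @param abundance expected number of occurrence records per year: either a
#'   single number or a numeric vector named by year.
#' @param role `"invasive"` or `"native"`; used when pooling training classes.
#'
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, response, abundance, role = c("native", "invasive")) {
  role <- match.arg(role)
  response <- tibble::as_tibble(response)
  needed <- c("variable", "optimum", "breadth", "weight")
  if (!all(needed %in% names(response))) {
    abort("`response` needs columns variable, optimum, breadth, weight.")
  }
  if (any(response$breadth <= 0)) abort("Every `breadth` must be positive.")
  if (any(response$weight < 0 | response$weight > 1)) {
    abort("Every `weight` must lie in [0, 1].")
  }
  if (any(abundance < 1)) abort("`abundance` must be at least 1.")
  structure(
    list(species_id = species_id, response = response,
         abundance = abundance, role = role),
    class = "niche_spec"
  )
}

niche_abundance <- function(niche, year) {
  a <- niche$abundance
  if (is.null(names(a))) return(unname(a[1]))
  key <- as.character(year)
  if (!key %in% names(a)) abort(sprintf(
    "Species '%s' has no abundance for year %s.", niche$species_id, key))
  unname(a[[key]])
}

# A smooth unit-variance random surface: a superposition of plane cosine
# waves with wavelengths at or above the correlation length.
random_surface <- function(geometry, length_scale, seed, k = 8) {
  cc <- cell_centres(geometry)
  with_seed(seed, {
    freq <- runif(k, 0.25, 1) / length_scale
    theta <- runif(k, 0, 2 * pi)
    phase <- runif(k, 0, 2 * pi)
    f <- numeric(nrow(cc))
    for (i in seq_len(k)) {
      f <- f + cos(2 * pi * freq[i] * (cos(theta[i]) * cc$x + sin(theta[i]) * cc$y) +
                     phase[i])
    }
    matrix(sqrt(2 / k) * f, nrow = geometry$nrow, ncol = geometry$ncol,
           byrow = TRUE)
  })
}

#' Simulate the weather grids of one year
#'
#' Every variable gets a persistent spatial pattern (shared by all years of
#' the same world) plus a year-specific anomaly surface scaled by the world's
#' `noise_scale`. The same `config` and `year` always reproduce the same
#' stack bit for bit.
#'
#' @param config a [world_config()].
#' @param year a year listed in `config$years`.
#' @return A [climate_stack()].
#' @export
generate_climate_stack <- function(config, year) {
  if (!year %in% config$years) {
    abort(sprintf("Year %d is not part of this world (years: %s).",
                  year, paste(config$years, collapse = ", ")))
  }
  geometry <- list(xmin = 0, ymax = config$rows * config$cell_size,
                   cell_size = config$cell_size,
                   nrow = config$rows, ncol = config$cols)
  layers <- list()
  for (v in config$variables) {
    norm <- config$climate_norms[config$climate_norms$variable == v, ]
    base <- random_surface(geometry, config$smoothness,
                           derive_seed(config$seed, v, "base"))
    field <- norm$mean + norm$sd * base
    if (config$noise_scale > 0) {
      anom <- random_surface(geometry, config$smoothness,
                             derive_seed(config$seed, v, year))
      field <- field + config$noise_scale * norm$sd * anom
    }
    if (isTRUE(norm$nonnegative)) field <- pmax(field, 0)
    layers[[v]] <- field
  }
  climate_stack(layers, year = year, xmin = geometry$xmin,
                ymax = geometry$ymax, cell_size = geometry$cell_size)
}

# Per-cell suitability of a niche on a stack (row-major matrix), NA where any
# input layer is NA.
niche_suitability <- function(niche, stack) {
  missing <- setdiff(niche$response$variable, names(stack$layers))
  if (length(missing)) {
    abort(sprintf("Stack lacks variable(s) referenced by niche '%s': %s.",
                  niche$species_id, paste(missing, collapse = ", ")))
  }
  g <- stack$geometry
  s <- matrix(1, g$nrow, g$ncol)
  for (i in seq_len(nrow(niche$response))) {
    r <- niche$response[i, ]
    v <- stack$layers[[r$variable]]
    s <- s * exp(-r$weight * ((v - r$optimum) / r$breadth)^2)
  }
  s
}

#' Simulate occurrence records of one species for one year
#'
#' Cells are sampled with probability proportional to the product of the
#' species' per-variable Gaussian responses evaluated at the cell's weather
#' values; each sampled point is jittered uniformly within its cell. The
#' number of records is a Poisson draw with the species' abundance for that
#' year as mean (override with `n` for a fixed count).
#'
#' @param config a [world_config()].
#' @param niche a [niche_spec()].
#' @param stack the [climate_stack()] of the year being simulated.
#' @param seed integer seed for this draw.
#' @param n optional fixed record count overriding the Poisson draw.
#' @return A tibble of occurrence records: `species`, `year`, `x`, `y`.
#' @export
generate_occurrences <- function(config, niche, stack, seed, n = NULL) {
  suit <- niche_suitability(niche, stack)
  valid <- which(!is.na(suit))
  if (length(valid) == 0) abort("No valid cells to sample from.")
  g <- stack$geometry
  with_seed(seed, {
    if (is.null(n)) n <- rpois(1, niche_abundance(niche, stack$year))
    if (n == 0) {
      return(tibble::tibble(species = character(0), year = integer(0),
                            x = numeric(0), y = numeric(0)))
    }
    w <- suit[valid]
    if (sum(w) == 0) w <- rep(1, length(w))
    idx <- sample(valid, n, replace = TRUE, prob = w)
    row <- ((idx - 1) %% g$nrow) + 1
    col <- ((idx - 1) %/% g$nrow) + 1
    tibble::tibble(
      species = niche$species_id,
      year = as.integer(stack$year),
      x = g$xmin + (col - 1 + runif(n)) * g$cell_size,
      y = g$ymax - (row - 1 + runif(n)) * g$cell_size
    )
  })
}

#' A ready-made four-species study scenario
#'
#' Builds a virtual world populated by one invasive container-breeding
#' mosquito and three native contrast species (a floodwater species, a
#' tree-hole species and a continentally distributed species) whose climate
#' responses overlap but differ, echoing the class structure of a national
#' mosquito-monitoring data set: about 5:20:3:1 records per year across the
#' four species during the training years, with the invasive species
#' expanding in the final (hold-out) year.
#'
#' `separation` scales all niche-optimum offsets: 1 is the configured
#' scenario; 0 makes all four response functions identical (and balances the
#' two class sizes) so that no classifier can beat chance — the null world
#' used to verify that the pipeline does not manufacture skill.
#'
#' @param seed integer master seed for the world's weather.
#' @param separation non-negative multiplier on the niche-optimum offsets.
#' @return A list with elements `config` (a [world_config()]), `niches`
#'   (list of four [niche_spec()]s, the first invasive), and `truth`
#'   (a tibble recording every niche parameter).
#' @export
make_paperlike_scenario <- function(seed = 1, separation = 1) {
  assert_scalar_number(separation, "separation", nonnegative = TRUE)
  config <- world_config(rows = 100, cols = 100, cell_size = 1,
                         years = 2011:2015, seed = seed)
  norms <- config$climate_norms
  norm_of <- function(v) norms[norms$variable == v, ]
  vars <- canonical_variables()

  # niche-optimum offsets in units of each variable's spatial sd
  offsets <- list(
    japonicus   = c(T13 = 1.3, T09 = 1.0, T10 = 1.0, T12 = 1.0,
                    P02 = 1.0, P04 = 0.8, P06 = 1.0, D15 = -1.0),
    vexans      = c(T13 = -0.5, T09 = -0.4, T10 = -0.5, T12 = -0.25,
                    P02 = -0.5, P04 = -0.25, P06 = 0.25, D15 = 0.4),
    geniculatus = c(T13 = 0.25, T09 = 0.25, T10 = 0.0, T12 = -0.65,
                    P02 = 0.25, P04 = 0.5, P06 = -0.4, D15 = 0.8),
    daciae      = c(T13 = -1.0, T09 = -0.8, T10 = -0.8, T12 = -1.6,
                    P02 = -1.0, P04 = -1.0, P06 = -1.0, D15 = 1.3)
  )
  breadths <- c(japonicus = 1.2, vexans = 1.5, geniculatus = 1.4, daciae = 1.3)
  weights  <- c(japonicus = 1.0, vexans = 0.8, geniculatus = 0.8, daciae = 0.9)
  if (separation == 0) {
    # identical responses: any residual response shape must be shared
    breadths[] <- 1.3
    weights[]  <- 0.8
  }
  # expected records per training year (hold-out year differs: the invasive
  # species is expanding while natives are sampled more sparsely)
  abundances <- list(
    japonicus   = c("2011" = 127, "2012" = 127, "2013" = 127, "2014" = 127,
                    "2015" = 308),
    vexans      = c("2011" = 514, "2012" = 514, "2013" = 514, "2014" = 514,
                    "2015" = 95),
    geniculatus = c("2011" = 80, "2012" = 80, "2013" = 80, "2014" = 80,
                    "2015" = 15),
    daciae      = c("2011" = 26, "2012" = 26, "2013" = 26, "2014" = 26,
                    "2015" = 5)
  )
  if (separation == 0) {
    # balanced classes so the no-skill weighted f1 reference is 0.5
    abundances <- list(
      japonicus = c("2011" = 75, "2012" = 75, "2013" = 75, "2014" = 75,
                    "2015" = 75),
      vexans = c("2011" = 25, "2012" = 25, "2013" = 25, "2014" = 25,
                 "2015" = 25),
      geniculatus = c("2011" = 25, "2012" = 25, "2013" = 25, "2014" = 25,
                      "2015" = 25),
      daciae = c("2011" = 25, "2012" = 25, "2013" = 25, "2014" = 25,
                 "2015" = 25)
    )
  }

  niches <- purrr::imap(offsets, function(off, sp) {
    resp <- purrr::map_dfr(vars, function(v) {
      nm <- norm_of(v)
      tibble::tibble(variable = v,
                     optimum = nm$mean + separation * off[[v]] * nm$sd,
                     breadth = breadths[[sp]] * nm$sd,
                     weight = weights[[sp]])
    })
    niche_spec(sp, resp, abundances[[sp]],
               role = if (sp == "japonicus") "invasive" else "native")
  })

  truth <- purrr::map_dfr(niches, function(n) {
    dplyr::mutate(n$response, species = n$species_id, role = n$role,
                  .before = 1)
  })
  list(config = config, niches = niches, truth = truth)
}

#' Simulate every species over every year of a scenario
#'
#' @param scenario output of [make_paperlike_scenario()].
#' @param seed integer seed for the occurrence draws.
#' @param counts optional named list `species -> year -> fixed count`
#'   overriding the Poisson draws.
#' @return A list with `occurrences` (one tibble) and `stacks` (a list of
#'   [climate_stack()]s named by year).
#' @export
simulate_scenario <- function(scenario, seed = 1, counts = NULL) {
  config <- scenario$config
  stacks <- purrr::map(config$years, ~generate_climate_stack(config, .x))
  names(stacks) <- as.character(config$years)
  occ <- purrr::map_dfr(scenario$niches, function(niche) {
    purrr::map_dfr(config$years, function(yr) {
      n <- counts[[niche$species_id]][[as.character(yr)]]
      generate_occurrences(config, niche, stacks[[as.character(yr)]],
                           seed = derive_seed(seed, niche$species_id, yr),
                           n = n)
    })
  })
  list(occurrences = occ, stacks = stacks)
}

#' Species-to-class assignment of a scenario
#'
#' @param scenario output of [make_paperlike_scenario()].
#' @return Named character vector mapping species id to
#'   `"invasive"`/`"native"`.
#' @export
scenario_roles <- function(scenario) {
  roles <- purrr::map_chr(scenario$niches, "role")
  names(roles) <- purrr::map_chr(scenario$niches, "species_id")
  roles
}
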