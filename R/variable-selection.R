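#' Configuration of the genetic covariate search
#'
#' The search encodes a candidate-variable subset as an inclusion bitmask
#' (one bit per candidate). Fitness of a chromosome is the weighted f1 score
#' of a classifier trained on the included variables and evaluated on a
#' stratified hold-out split. Standard operators: tournament selection
#' (size 2), uniform crossover, independent per-bit mutation, elitism.
#'
#' @param candidates ordered character vector of candidate variables.
#' @param population_size number of chromosomes per generation (>= 2).
#' @param generations number of generations (>= 1).
#' @param crossover_rate probability that a child is produced by uniform
#'   crossover rather than cloning.
#' @param mutation_rate per-bit flip probability; default `1/length(candidates)`.
#' @param elitism number of best chromosomes copied unchanged into the next
#'   generation.
#' @param holdout_fraction fraction of rows held out (stratified by class)
#'   for each fitness evaluation.
#' @param seed integer seed for the whole search.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(candidates, population_size = 24, generations = 15,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      elitism = 1, holdout_fraction = 0.25, seed = 1) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty.")
  if (population_size < 2) abort("`population_size` must be at least 2.")
  if (generations < 1) abort("Need at least 1 generation.")
  mutation_rate <- mutation_rate %||% (1 / length(candidates))
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    abort("Rates must lie in [0, 1].")
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    abort("`holdout_fraction` must lie in (0, 1).")
  }
  structure(
    list(candidates = candidates, population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = crossover_rate, mutation_rate = mutation_rate,
         elitism = as.integer(elitism), holdout_fraction = holdout_fraction,
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

# Shared fitness protocol for the GA and the exhaustive oracle: per-species
# cap, then one seeded stratified holdout split, train on raw-mode labels
# (no probability calibration needed for f1), score weighted f1 on the
# held-out rows.
make_fitness_fn <- function(table, config, ga) {
  table <- label_classes(table)
  table <- build_training_set(table, cap = config$per_species_cap,
                              seed = derive_seed(ga$seed, "cap"))
  split <- with_seed(derive_seed(ga$seed, "holdout"), {
    test <- unlist(lapply(split(seq_len(nrow(table)), table$role), function(idx) {
      sample(idx, max(1, round(length(idx) * ga$holdout_fraction)))
    }), use.names = FALSE)
    list(train = setdiff(seq_len(nrow(table)), test), test = test)
  })
  train_tab <- table[split$train, ]
  test_tab <- table[split$test, ]
  cache <- new.env(parent = emptyenv())
  function(mask) {
    if (!any(mask)) return(-Inf)
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    vars <- ga$candidates[mask]
    fit_cfg <- training_config(gamma = config$gamma, C = config$C,
                               tolerance = config$tolerance,
                               per_species_cap = config$per_species_cap,
                               subsample_seed = config$subsample_seed,
                               standardize = config$standardize)
    model <- suppressWarnings(
      e1071::svm(as.matrix(train_tab[, vars, drop = FALSE]),
                 factor(train_tab$role, levels = c("invasive", "native")),
                 scale = fit_cfg$standardize, kernel = "radial",
                 gamma = fit_cfg$gamma, cost = fit_cfg$C,
                 tolerance = fit_cfg$tolerance)
    )
    pred <- as.character(predict(model, as.matrix(test_tab[, vars, drop = FALSE])))
    val <- weighted_f1(test_tab$role, pred)
    # a subset whose classifier collapses to one class has undefined per-class
    # metrics; such chromosomes carry no usable fitness
    if (is.na(val)) val <- -Inf
    cache[[key]] <- val
    val
  }
}

#' Genetic-algorithm covariate subset selection
#'
#' Searches the space of candidate-variable subsets for the one whose
#' classifier attains the highest hold-out weighted f1 score, the procedure
#' used to reduce a large pool of pre-selected weather covariates to a
#' compact informative set.
#'
#' @param table labelled feature tibble containing every candidate column.
#' @param config a [training_config()] used inside each fitness evaluation.
#' @param ga a [ga_config()].
#' @return A list of class `ga_selection`: `variables` (the best subset ever
#'   seen), `fitness`, `trace` (tibble of per-generation best/mean fitness)
#'   and the configs.
#' @export
ga_select <- function(table, config = training_config(), ga) {
  fitness <- make_fitness_fn(table, config, ga)
  L <- length(ga$candidates)
  with_seed(derive_seed(ga$seed, "ga"), {
    pop <- lapply(seq_len(ga$population_size), function(i) runif(L) < 0.5)
    if (all(vapply(pop, Negate(any), logical(1))) && ga$mutation_rate == 0) {
      abort("All-empty initial population with zero mutation cannot improve.")
    }
    scores <- vapply(pop, fitness, numeric(1))
    best_mask <- pop[[which.max(scores)]]
    best_fit <- max(scores)
    trace <- tibble::tibble(generation = integer(0), best = numeric(0),
                            mean = numeric(0))
    for (gen in seq_len(ga$generations)) {
      ord <- order(scores, decreasing = TRUE)
      nxt <- pop[ord[seq_len(min(ga$elitism, length(pop)))]]
      tournament <- function() {
        i <- sample.int(length(pop), 2)
        pop[[i[which.max(scores[i])]]]
      }
      while (length(nxt) < ga$population_size) {
        a <- tournament(); b <- tournament()
        child <- if (runif(1) < ga$crossover_rate) {
          ifelse(runif(L) < 0.5, a, b)
        } else {
          a
        }
        flip <- runif(L) < ga$mutation_rate
        child[flip] <- !child[flip]
        nxt[[length(nxt) + 1]] <- child
      }
      pop <- nxt
      scores <- vapply(pop, fitness, numeric(1))
      if (max(scores) > best_fit) {
        best_fit <- max(scores)
        best_mask <- pop[[which.max(scores)]]
      }
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        generation = gen, best = best_fit,
        mean = mean(scores[is.finite(scores)])))
    }
    structure(
      list(variables = ga$candidates[best_mask], fitness = best_fit,
           trace = trace, ga = ga, config = config),
      class = "ga_selection"
    )
  })
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf("<ga_selection> %d/%d variable(s), fitness %.4f: %s\n",
              length(x$variables), length(x$ga$candidates), x$fitness,
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.ga_selection <- function(x, ...) x$trace

#' @export
glance.ga_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$variables),
                 n_candidates = length(x$ga$candidates),
                 fitness = x$fitness,
                 generations = x$ga$generations,
                 population_size = x$ga$population_size)
}

#' Exhaustive covariate subset search (oracle)
#'
#' Evaluates every non-empty subset of at most 12 candidates with exactly the
#' same fitness protocol as [ga_select()] and returns the best. Intended as
#' the ground-truth reference the genetic search is checked against.
#'
#' @inheritParams ga_select
#' @return A list of class `ga_selection` (with a complete `all_subsets`
#'   fitness table instead of a generation trace).
#' @export
exhaustive_select <- function(table, config = training_config(), ga) {
  L <- length(ga$candidates)
  if (L > 12) abort("Refusing exhaustive search over more than 12 candidates.")
  fitness <- make_fitness_fn(table, config, ga)
  masks <- lapply(seq_len(2^L - 1), function(i) {
    as.logical(bitwAnd(i, 2^(seq_len(L) - 1)))
  })
  scores <- vapply(masks, fitness, numeric(1))
  best <- which.max(scores)
  structure(
    list(variables = ga$candidates[masks[[best]]], fitness = scores[best],
         all_subsets = tibble::tibble(
           subset = vapply(masks, function(m) paste(ga$candidates[m], collapse = "+"),
                           character(1)),
           size = vapply(masks, sum, numeric(1)),
           fitness = scores),
         ga = ga, config = config),
    class = "ga_selection"
  )
}
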