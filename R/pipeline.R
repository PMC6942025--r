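#' Configuration of a full modelling experiment
#'
#' One object drives the whole study: simulate (or load) occurrences and
#' climate grids, attach covariates, optionally run the genetic covariate
#' search, train on the training years, validate on the held-out year, and
#' map. A single master seed deterministically derives the seed of every
#' stochastic stage, so an experiment is reproducible from its config alone.
#'
#' @param source `"synthetic"` (simulate a scenario), or `"data"` (use the
#'   supplied `occurrences` tibble and `stacks` list).
#' @param scenario for synthetic runs, the output of
#'   [make_paperlike_scenario()]; default: that scenario built from the
#'   master seed.
#' @param occurrences,stacks for `source = "data"`: an occurrence tibble
#'   (`species`, `year`, `x`, `y`) and a list of [climate_stack()]s named by
#'   year.
#' @param roles named character vector `species -> "invasive"/"native"`;
#'   derived from the scenario for synthetic runs.
#' @param variables covariates to train on; default: all canonical
#'   variables present.
#' @param train_years,test_year integer years; must be disjoint.
#' @param training a [training_config()].
#' @param ga optional [ga_config()] to select `variables` before training.
#' @param out_dir optional directory; when given, feature tables, the model,
#'   rasters and the report are written there as plain-text artifacts.
#' @param seed master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(source = c("synthetic", "data"),
                              scenario = NULL, occurrences = NULL,
                              stacks = NULL, roles = NULL, variables = NULL,
                              train_years = 2011:2014, test_year = 2015,
                              training = training_config(), ga = NULL,
                              out_dir = NULL, seed = 1) {
  source <- match.arg(source)
  if (length(intersect(train_years, test_year))) {
    abort("`train_years` and `test_year` must be disjoint.")
  }
  if (source == "data" && (is.null(occurrences) || is.null(stacks))) {
    abort("source = 'data' needs `occurrences` and `stacks`.")
  }
  structure(
    list(source = source, scenario = scenario, occurrences = occurrences,
         stacks = stacks, roles = roles, variables = variables,
         train_years = as.integer(train_years),
         test_year = as.integer(test_year),
         training = training, ga = ga, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a full train-validate-map experiment
#'
#' Executes the study workflow end to end: data acquisition, covariate
#' attachment, optional genetic covariate selection, per-species subsampling
#' cap, classifier training with probability calibration, temporal hold-out
#' validation (confusion matrix, per-class and weighted metrics, hold-out
#' probability summary, per-variable class contrasts) and habitat mapping
#' for the hold-out year plus the multi-year average climate.
#'
#' @param config an [experiment_config()].
#' @return An object of class `experiment_report`.
#' @export
run_experiment <- function(config) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s (check the experiment config for this stage).",
                    name, conditionMessage(e)))
    })
  }

  # -- data ------------------------------------------------------------------
  data <- stage("data", {
    if (config$source == "synthetic") {
      scenario <- config$scenario %||% make_paperlike_scenario(derive_seed(seed, "world"))
      sim <- simulate_scenario(scenario, seed = derive_seed(seed, "occurrences"))
      list(occurrences = sim$occurrences, stacks = sim$stacks,
           roles = scenario_roles(scenario))
    } else {
      roles <- config$roles
      if (is.null(roles)) abort("source = 'data' needs `roles`.")
      list(occurrences = config$occurrences, stacks = config$stacks,
           roles = roles)
    }
  })
  needed_years <- c(config$train_years, config$test_year)
  missing_years <- setdiff(as.character(needed_years), names(data$stacks))
  if (length(missing_years)) {
    abort(sprintf("Stage 'data' failed: no climate stack for year(s) %s.",
                  paste(missing_years, collapse = ", ")))
  }
  present <- setdiff(names(data$roles), unique(data$occurrences$species))
  if (length(present)) {
    abort(sprintf("Stage 'data' failed: species without records: %s.",
                  paste(present, collapse = ", ")))
  }

  # -- features --------------------------------------------------------------
  variables <- config$variables %||%
    (if (!is.null(config$ga)) config$ga$candidates else
      intersect(canonical_variables(), names(data$stacks[[1]]$layers)))
  features <- stage("features", {
    occ <- data$occurrences[data$occurrences$year %in% needed_years, ]
    tab <- attach_features(occ, data$stacks, variables = variables)
    label_classes(tab, roles = data$roles)
  })
  train_tab <- features[features$year %in% config$train_years, ]
  test_tab <- features[features$year %in% config$test_year, ]
  if (nrow(train_tab) == 0 || nrow(test_tab) == 0) {
    abort("Stage 'features' failed: empty training or test year set.")
  }
  counts_before <- table(train_tab$species)

  # -- variable selection ----------------------------------------------------
  selection <- NULL
  if (!is.null(config$ga)) {
    selection <- stage("select-vars", ga_select(train_tab, config$training, config$ga))
    variables <- selection$variables
  }

  # -- training --------------------------------------------------------------
  training <- config$training
  training$subsample_seed <- derive_seed(seed, "subsample")
  capped <- stage("train", build_training_set(
    train_tab, cap = training$per_species_cap, seed = training$subsample_seed))
  model <- stage("train", train_niche_model(capped, training, variables = variables))

  # -- validation ------------------------------------------------------------
  report_eval <- stage("validate", {
    predicted <- predict_class(model, test_tab)
    cm <- confusion_matrix(test_tab$role, predicted)
    inv_test <- test_tab[test_tab$role == "invasive", ]
    list(
      confusion = cm,
      metrics = metrics_table(cm),
      probability = probability_summary(model, inv_test),
      contrasts = class_contrast(capped, variables = variables)
    )
  })

  # -- mapping ---------------------------------------------------------------
  maps <- stage("map", {
    test_stack <- data$stacks[[as.character(config$test_year)]]
    mean_stack <- average_layers(data$stacks[as.character(needed_years)])
    list(holdout_year = predict_raster(model, test_stack),
         mean_climate = predict_raster(model, mean_stack))
  })

  report <- structure(
    list(
      config = config,
      variables = variables,
      selection = selection,
      class_counts = list(before_cap = counts_before,
                          after_cap = table(capped$species)),
      test_counts = table(test_tab$role),
      model = model,
      confusion = report_eval$confusion,
      metrics = report_eval$metrics,
      probability = report_eval$probability,
      contrasts = report_eval$contrasts,
      maps = maps,
      seeds = list(master = seed,
                   subsample = training$subsample_seed,
                   occurrences = derive_seed(seed, "occurrences")),
      version = as.character(utils::packageVersion("nichesvm"))
    ),
    class = "experiment_report"
  )
  if (!is.null(config$out_dir)) write_experiment_report(report, config$out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  variables: %s\n", paste(x$variables, collapse = ", ")))
  cat(sprintf("  training records (capped): %s\n",
              paste(sprintf("%s=%d", names(x$class_counts$after_cap),
                            x$class_counts$after_cap), collapse = ", ")))
  print(x$confusion)
  print(dplyr::mutate(x$metrics, dplyr::across(
    c("precision", "recall", "f1"), ~round_half_up(.x, 2))))
  print(x$probability)
  invisible(x)
}

#' @export
glance.experiment_report <- function(x, ...) {
  total <- x$metrics[x$metrics$class == "total", ]
  tibble::tibble(
    weighted_precision = total$precision,
    weighted_recall = total$recall,
    weighted_f1 = total$f1,
    prob_median = x$probability$median,
    prob_q1 = x$probability$q1,
    prob_q3 = x$probability$q3,
    n_test_invasive = unname(x$test_counts[["invasive"]]),
    n_test_native = unname(x$test_counts[["native"]])
  )
}

# Persist the report and its artifacts as plain-text files.
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_niche_model(report$model, file.path(dir, "model.json"))
  write_probability_raster(report$maps$holdout_year,
                           file.path(dir, "map_holdout_year.asc"))
  write_probability_raster(report$maps$mean_climate,
                           file.path(dir, "map_mean_climate.asc"))
  doc <- list(
    version = report$version,
    seeds = report$seeds,
    variables = report$variables,
    class_counts = lapply(report$class_counts, as.list),
    test_counts = as.list(report$test_counts),
    confusion = unclass(report$confusion),
    metrics = report$metrics,
    probability = c(glance(report$probability),
                    list(histogram = report$probability$histogram)),
    contrasts = report$contrasts
  )
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
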