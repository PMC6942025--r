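#' Training configuration for the niche classifier
#'
#' The kernel classifier is a C-support-vector machine with a radial basis
#' function kernel, trained on covariates in their raw physical units
#' (degrees Celsius, mm); `gamma` is therefore interpreted on those raw
#' scales, and the defaults are the settings used throughout this package's
#' reference analysis. Probability calibration refits the decision values
#' through a sigmoid (Platt scaling) using libsvm's internal five-fold
#' cross-validation.
#'
#' @param gamma RBF kernel width parameter (on raw covariate units).
#' @param C soft-margin cost.
#' @param tolerance optimizer stopping tolerance.
#' @param per_species_cap maximum records per species entering training;
#'   species with more records are randomly subsampled down to the cap.
#' @param subsample_seed integer seed for that subsampling.
#' @param standardize if `TRUE`, covariates are centred/scaled before
#'   training (off by default: the raw-unit kernel is the reference
#'   behaviour, and `gamma` is calibrated to raw units).
#'
#' @return An object of class `training_config`.
#' @export
training_config <- function(gamma = 5e-4, C = 1, tolerance = 1e-10,
                            per_species_cap = 1000, subsample_seed = 1,
                            standardize = FALSE) {
  assert_scalar_number(gamma, "gamma", positive = TRUE)
  assert_scalar_number(C, "C", positive = TRUE)
  assert_scalar_number(tolerance, "tolerance", positive = TRUE)
  if (per_species_cap < 1) abort("`per_species_cap` must be at least 1.")
  structure(
    list(gamma = gamma, C = C, tolerance = tolerance, kernel = "radial",
         per_species_cap = as.integer(per_species_cap),
         subsample_seed = as.integer(subsample_seed),
         standardize = isTRUE(standardize)),
    class = "training_config"
  )
}

#' Cap the per-species record counts of a training table
#'
#' Species with more than `cap` rows are reduced to a uniform random
#' subsample of exactly `cap` rows (without replacement, seeded); all other
#' species pass through unchanged. This mitigates class imbalance when one
#' abundant contrast species would otherwise dominate the pooled native
#' class.
#'
#' @param table a labelled feature tibble (needs `species` and `role`).
#' @param cap maximum rows per species.
#' @param seed integer seed for the subsample.
#' @return The capped feature tibble (original row order preserved).
#' @export
build_training_set <- function(table, cap = 1000, seed = 1) {
  table <- label_classes(table)
  if (length(unique(table$role)) < 2) {
    abort("Cannot train a binary separator: the table holds a single class.")
  }
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(table)), table$species), function(idx) {
      if (length(idx) > cap) sort(sample(idx, cap)) else idx
    }), use.names = FALSE)
  })
  out <- table[sort(keep), , drop = FALSE]
  attr(out, "variables") <- attr(table, "variables")
  out
}

#' Train the calibrated niche classifier
#'
#' Fits the RBF-kernel support vector machine that separates the invasive
#' species' occurrence sites from the pooled native sites in climate space,
#' with sigmoid (Platt) probability calibration, and evaluates the
#' resubstitution confusion matrix on the training rows.
#'
#' @param table labelled feature tibble (`role` in `invasive`/`native` plus
#'   covariate columns). Apply [build_training_set()] first if per-species
#'   caps are wanted.
#' @param config a [training_config()].
#' @param variables ordered covariate names to train on; default: every
#'   covariate column.
#' @return An object of class `niche_model`: the fitted classifier, its
#'   sigmoid calibration parameters, the ordered variable list and training
#'   metadata.
#' @export
train_niche_model <- function(table, config = training_config(),
                              variables = NULL) {
  table <- label_classes(table)
  variables <- variables %||% feature_variables(table)
  if (length(variables) == 0) abort("No covariate columns to train on.")
  x <- as.matrix(table[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) abort("Training covariates contain missing values.")
  y <- factor(table$role, levels = c("invasive", "native"))
  if (any(tabulate(y, 2) < 2)) abort("Need at least 2 rows per class.")
  if (all(apply(x, 2, stats::sd) == 0)) {
    abort("Degenerate covariates: zero variance in every variable.")
  }
  fit <- with_seed(derive_seed(config$subsample_seed, "platt"), {
    e1071::svm(x, y, scale = config$standardize, kernel = "radial",
               gamma = config$gamma, cost = config$C,
               tolerance = config$tolerance, probability = TRUE)
  })
  # libsvm orders classes by appearance; record whether the positive
  # (first-label) side of the decision function is the invasive class
  positive_first <- fit$levels[fit$labels[1]] == "invasive"
  model <- structure(
    list(
      fit = fit,
      variables = variables,
      config = config,
      platt = c(A = unname(fit$probA), B = unname(fit$probB)),
      positive_first = positive_first,
      class_counts = table(table$role),
      species_counts = table(table$species),
      version = "1"
    ),
    class = "niche_model"
  )
  model$training_confusion <- confusion_matrix(
    table$role, predict_class(model, table, mode = "raw"))
  model
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf(
    "<niche_model> RBF-SVM (gamma=%g, C=%g) on %d variable(s): %s\n",
    x$config$gamma, x$config$C, length(x$variables),
    paste(x$variables, collapse = ", ")))
  cat(sprintf("  trained on %d invasive / %d native records; Platt A=%.4f B=%.4f\n",
              x$class_counts[["invasive"]], x$class_counts[["native"]],
              x$platt[["A"]], x$platt[["B"]]))
  invisible(x)
}

model_matrix <- function(model, newdata) {
  if (is.matrix(newdata)) {
    if (ncol(newdata) != length(model$variables)) {
      abort(sprintf("Expected %d columns (%s).", length(model$variables),
                    paste(model$variables, collapse = ", ")))
    }
    colnames(newdata) <- model$variables
    return(newdata)
  }
  missing <- setdiff(model$variables, names(newdata))
  if (length(missing)) {
    abort(sprintf("Missing covariate column(s): %s (model expects %s).",
                  paste(missing, collapse = ", "),
                  paste(model$variables, collapse = ", ")))
  }
  x <- as.matrix(newdata[, model$variables, drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Decision values of the fitted separator
#'
#' Signed distances to the separating hyperplane in kernel space, oriented so
#' that larger values point toward the invasive class.
#'
#' @param model a [niche_model()] fit from [train_niche_model()].
#' @param newdata feature tibble or numeric matrix.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, newdata) {
  x <- model_matrix(model, newdata)
  if (!is.null(model$fit)) {
    pr <- predict(model$fit, x, decision.values = TRUE)
    d <- as.numeric(attr(pr, "decision.values"))
  } else {
    d <- rbf_decision(model$params, x)
  }
  if (model$positive_first) d else -d
}

#' Calibrated occurrence probabilities
#'
#' The sigmoid-calibrated probability that a site with the given covariates
#' belongs to the invasive class, on a scale from 0 (very low probability of
#' occurrence) to 1 (very high).
#'
#' @inheritParams decision_values
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, newdata) {
  x <- model_matrix(model, newdata)
  if (!is.null(model$fit)) {
    pr <- predict(model$fit, x, probability = TRUE)
    p <- attr(pr, "probabilities")[, "invasive"]
  } else {
    d_raw <- rbf_decision(model$params, x)
    p_first <- 1 / (1 + exp(model$platt[["A"]] * d_raw + model$platt[["B"]]))
    p <- if (model$positive_first) p_first else 1 - p_first
  }
  unname(p)
}

#' Binary class predictions
#'
#' @inheritParams decision_values
#' @param threshold probability cut-off for the invasive label (default 0.5;
#'   sites at exactly the threshold are labelled invasive).
#' @param mode `"probability"` thresholds the calibrated probability;
#'   `"raw"` uses the sign of the uncalibrated decision value.
#' @return Character vector of `"invasive"`/`"native"` labels, with the mode
#'   recorded in the `"mode"` attribute.
#' @export
predict_class <- function(model, newdata, threshold = 0.5,
                          mode = c("probability", "raw")) {
  mode <- match.arg(mode)
  lab <- if (mode == "probability") {
    ifelse(predict_probability(model, newdata) >= threshold, "invasive", "native")
  } else {
    ifelse(decision_values(model, newdata) > 0, "invasive", "native")
  }
  structure(lab, mode = mode)
}

# Decision function replayed from stored support vectors:
# f(x) = sum_i coef_i * exp(-gamma ||sv_i - x||^2) - rho
# (support vectors are stored on the same scale predictions are made on;
# standardized models carry the centre/scale to apply first)
rbf_decision <- function(params, x) {
  if (!is.null(params$center)) {
    x <- scale(x, center = params$center, scale = params$scale)
  }
  sv <- params$sv
  cross <- x %*% t(sv)
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * cross
  K <- exp(-params$gamma * pmax(d2, 0))
  as.numeric(K %*% params$coefs - params$rho)
}

#' Save / load a calibrated niche model
#'
#' Models are stored as a self-describing, versioned JSON document holding
#' the support vectors, dual coefficients, bias, kernel parameters, sigmoid
#' calibration, variable list, configuration and training metadata. A loaded
#' model reproduces the predictions of the original exactly (the decision
#' function is replayed from the stored parameters).
#'
#' @param model a [niche_model()].
#' @param path output `.json` path.
#' @return `read_niche_model()` returns a `niche_model`;
#'   `write_niche_model()` returns `path` invisibly.
#' @export
write_niche_model <- function(model, path) {
  fit <- model$fit
  if (is.null(fit)) {
    params <- model$params
  } else {
    params <- list(sv = unname(as.matrix(fit$SV)),
                   coefs = as.numeric(fit$coefs),
                   rho = as.numeric(fit$rho), gamma = fit$gamma)
    if (model$config$standardize && !is.null(fit$x.scale)) {
      params$center <- as.numeric(fit$x.scale$`scaled:center`)
      params$scale <- as.numeric(fit$x.scale$`scaled:scale`)
    }
  }
  doc <- list(
    format = "nichesvm-model", version = model$version,
    variables = model$variables,
    config = unclass(model$config),
    platt = as.list(model$platt),
    positive_first = model$positive_first,
    class_counts = as.list(model$class_counts),
    params = list(sv = params$sv, coefs = params$coefs, rho = params$rho,
                  gamma = params$gamma, center = params$center,
                  scale = params$scale)
  )
  doc$params <- Filter(Negate(is.null), doc$params)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_niche_model
#' @export
read_niche_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "nichesvm-model")) {
    abort(sprintf("'%s' is not a niche model file.", path))
  }
  cfg <- doc$config
  config <- training_config(gamma = cfg$gamma, C = cfg$C,
                            tolerance = cfg$tolerance,
                            per_species_cap = cfg$per_species_cap,
                            subsample_seed = cfg$subsample_seed,
                            standardize = cfg$standardize)
  structure(
    list(
      fit = NULL,
      params = list(sv = matrix(doc$params$sv, ncol = length(doc$variables)),
                    coefs = as.numeric(doc$params$coefs),
                    rho = doc$params$rho, gamma = doc$params$gamma,
                    center = if (length(doc$params$center)) as.numeric(doc$params$center),
                    scale = if (length(doc$params$scale)) as.numeric(doc$params$scale)),
      variables = doc$variables,
      config = config,
      platt = c(A = doc$platt$A, B = doc$platt$B),
      positive_first = isTRUE(doc$positive_first),
      class_counts = unlist(doc$class_counts),
      version = doc$version
    ),
    class = "niche_model"
  )
}

#' Tidy summaries of a fitted niche model
#'
#' `tidy()` returns the per-class resubstitution metrics of the training
#' data; `glance()` returns a one-row model overview.
#'
#' @param x a [niche_model()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.niche_model <- function(x, ...) {
  if (is.null(x$training_confusion)) {
    abort("This model carries no training confusion matrix (loaded from file?).")
  }
  class_metrics(x$training_confusion)
}

#' @rdname tidy.niche_model
#' @export
glance.niche_model <- function(x, ...) {
  tibble::tibble(
    n_invasive = unname(x$class_counts[["invasive"]]),
    n_native = unname(x$class_counts[["native"]]),
    n_variables = length(x$variables),
    gamma = x$config$gamma,
    C = x$config$C,
    platt_A = unname(x$platt[["A"]]),
    platt_B = unname(x$platt[["B"]])
  )
}
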