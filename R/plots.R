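#' Plot an occurrence-probability map
#'
#' @param object a [probability_raster].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.probability_raster <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90",
                                  name = "P(occurrence)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Occurrence probability (%s)",
                                  as.character(object$label)),
                  x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot the fitness trace of a genetic covariate search
#'
#' @param object a `ga_selection` from [ga_select()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ga_selection <- function(object, ...) {
  if (is.null(object$trace)) {
    abort("This selection has no generation trace (exhaustive search?).")
  }
  df <- tidyr::pivot_longer(object$trace, c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Genetic search: weighted f1 fitness",
                  x = "generation", y = "weighted f1") +
    ggplot2::theme_minimal()
}

#' Violin plot of per-variable class contrasts
#'
#' Shows the distribution of each covariate at invasive vs pooled-native
#' collection sites — the visual companion to [class_contrast()].
#'
#' @param table labelled feature tibble.
#' @param variables covariates to plot; default all.
#' @return A ggplot, faceted by variable on free scales.
#' @export
plot_class_contrast <- function(table, variables = NULL) {
  table <- label_classes(table)
  variables <- variables %||% feature_variables(table)
  df <- tidyr::pivot_longer(table[, c("role", variables)],
                            dplyr::all_of(variables),
                            names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$role, .data$value, fill = .data$role)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Weather conditions at collection sites, by training class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Histogram of hold-out occurrence probabilities
#'
#' @param summary a [probability_summary()].
#' @return A ggplot.
#' @export
plot_probability_histogram <- function(summary) {
  df <- summary$histogram
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = df$upper[1] - df$lower[1], fill = "steelblue") +
    ggplot2::geom_vline(xintercept = summary$median, linetype = 2) +
    ggplot2::labs(x = "predicted occurrence probability", y = "validation points",
                  title = sprintf("Hold-out presences: median %.2f, IQR [%.2f, %.2f]",
                                  summary$median, summary$q1, summary$q3)) +
    ggplot2::theme_minimal()
}
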