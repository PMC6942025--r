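#' Confusion matrix with the invasive species as positive class
#'
#' Counts of true/false positives/negatives for binary labels over
#' `{"invasive", "native"}`, oriented so that the invasive class is
#' positive. The dual orientation (native positive) is obtained with
#' [swap_orientation()], which exchanges TP with TN and FP with FN.
#'
#' @param observed,predicted equal-length label vectors.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(observed, predicted) {
  observed <- as.character(observed)
  predicted <- as.character(predicted)
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  foreign <- setdiff(unique(c(observed, predicted)), c("invasive", "native"))
  if (length(foreign)) {
    abort(sprintf("Labels must be 'invasive'/'native'; found: %s.",
                  paste(foreign, collapse = ", ")))
  }
  new_confusion(
    tp = sum(observed == "invasive" & predicted == "invasive"),
    fn = sum(observed == "invasive" & predicted == "native"),
    fp = sum(observed == "native" & predicted == "invasive"),
    tn = sum(observed == "native" & predicted == "native")
  )
}

new_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) abort("Confusion counts must be non-negative.")
  structure(lapply(as.list(counts), as.integer), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param tp,fp,fn,tn counts, invasive-positive orientation.
#' @export
as_confusion_matrix <- function(tp, fp, fn, tn) new_confusion(tp, fp, fn, tn)

#' @rdname confusion_matrix
#' @param cm a `confusion_matrix`.
#' @export
swap_orientation <- function(cm) {
  new_confusion(tp = cm$tn, fp = cm$fn, fn = cm$fp, tn = cm$tp)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(observed = c("invasive", "native"),
                              predicted = c("invasive", "native")))
  cat("<confusion_matrix> (invasive = positive)\n")
  print(m)
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(observed = rep(c("invasive", "native"), each = 2),
                 predicted = rep(c("invasive", "native"), 2),
                 n = c(x$tp, x$fn, x$fp, x$tn))
}

# precision/recall/f1 for the positive orientation of one confusion matrix;
# zero denominators yield NA (flagged), never an error or a silent zero.
single_class_metrics <- function(cm) {
  precision <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  recall <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n = cm$tp + cm$fn,
                 undefined = is.na(precision) | is.na(recall) | is.na(f1))
}

#' Per-class precision, recall and f1
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN) and f1 = their harmonic mean,
#' computed for both orientations of the confusion matrix (invasive positive,
#' then native positive). Undefined ratios (zero denominators) are reported
#' as `NA` with the `undefined` flag set.
#'
#' @param cm a [confusion_matrix()].
#' @return A tibble with one row per class: `class`, `precision`, `recall`,
#'   `f1`, `n`, `undefined`.
#' @export
class_metrics <- function(cm) {
  dplyr::bind_rows(
    dplyr::mutate(single_class_metrics(cm), class = "invasive", .before = 1),
    dplyr::mutate(single_class_metrics(swap_orientation(cm)),
                  class = "native", .before = 1)
  )
}

#' Observation-weighted totals of the per-class metrics
#'
#' Each metric's total is the mean of its two class values weighted by the
#' observed class sizes:
#' `(x_inv * n_inv + x_nat * n_nat) / (n_inv + n_nat)`.
#'
#' @param metrics a two-row tibble from [class_metrics()].
#' @return A one-row tibble: weighted `precision`, `recall`, `f1`, plus
#'   `n_invasive` and `n_native`.
#' @export
weighted_metrics <- function(metrics) {
  inv <- metrics[metrics$class == "invasive", ]
  nat <- metrics[metrics$class == "native", ]
  if (nrow(inv) != 1 || nrow(nat) != 1) {
    abort("`metrics` must hold exactly one invasive and one native row.")
  }
  n_total <- inv$n + nat$n
  if (n_total == 0) abort("Zero total observations; weighted metrics undefined.")
  wavg <- function(a, b) (a * inv$n + b * nat$n) / n_total
  tibble::tibble(
    precision = wavg(inv$precision, nat$precision),
    recall = wavg(inv$recall, nat$recall),
    f1 = wavg(inv$f1, nat$f1),
    n_invasive = inv$n, n_native = nat$n
  )
}

#' Validation-table summary of a confusion matrix
#'
#' The standard reporting block: one row per class plus the
#' observation-weighted total row.
#'
#' @param cm a [confusion_matrix()].
#' @param digits round to this many decimals (half-up, report convention);
#'   `NULL` leaves full precision.
#' @return A tibble with rows `invasive`, `native`, `total`.
#' @export
metrics_table <- function(cm, digits = NULL) {
  per_class <- class_metrics(cm)
  total <- weighted_metrics(per_class)
  out <- dplyr::bind_rows(
    per_class[, c("class", "precision", "recall", "f1", "n")],
    tibble::tibble(class = "total", precision = total$precision,
                   recall = total$recall, f1 = total$f1,
                   n = total$n_invasive + total$n_native)
  )
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("precision", "recall", "f1"), ~round_half_up(.x, digits)))
  }
  out
}

#' Weighted f1 of observed vs predicted labels
#'
#' Convenience wrapper: confusion matrix, per-class f1, then the
#' observation-weighted mean.
#'
#' @inheritParams confusion_matrix
#' @return A single number.
#' @export
weighted_f1 <- function(observed, predicted) {
  weighted_metrics(class_metrics(confusion_matrix(observed, predicted)))$f1
}

#' Summary of predicted probabilities at known presence sites
#'
#' Predicts the calibrated occurrence probability for each row of a hold-out
#' presence table and summarises the distribution: median, first and third
#' quartile (linear-interpolation quantiles) and a 10-bin histogram on
#' `[0, 1]`.
#'
#' @param model a [niche_model()].
#' @param table hold-out feature tibble (presence records of the target
#'   species with the evaluation year's covariates), or a numeric vector of
#'   probabilities already computed.
#' @param bins number of histogram bins on `[0, 1]`.
#' @return An object of class `probability_summary`: `n`, `median`, `q1`,
#'   `q3` and a `histogram` tibble.
#' @export
probability_summary <- function(model, table = NULL, bins = 10) {
  p <- if (is.numeric(model) && is.null(table)) model else predict_probability(model, table)
  if (length(p) == 0) abort("No rows to summarise.")
  edges <- seq(0, 1, length.out = bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1),
                          bins), nbins = bins)
  q <- unname(quantile(p, c(0.25, 0.5, 0.75), type = 7))
  structure(
    list(n = length(p), median = q[2], q1 = q[1], q3 = q[3],
         histogram = tibble::tibble(lower = edges[-length(edges)],
                                    upper = edges[-1], count = counts)),
    class = "probability_summary"
  )
}

#' @export
print.probability_summary <- function(x, ...) {
  cat(sprintf("<probability_summary> n=%d | median %.2f | IQR [%.2f, %.2f]\n",
              x$n, x$median, x$q1, x$q3))
  invisible(x)
}

#' @export
tidy.probability_summary <- function(x, ...) x$histogram

#' @export
glance.probability_summary <- function(x, ...) {
  tibble::tibble(n = x$n, median = x$median, q1 = x$q1, q3 = x$q3)
}

#' Per-variable contrast between the two training classes
#'
#' For each covariate, compares its values at invasive vs pooled-native
#' collection sites with the unpaired two-sided Wilcoxon-Mann-Whitney test
#' (exact for small tie-free samples, otherwise the tie-corrected normal
#' approximation), alongside per-class medians — the statistical companion
#' to a violin plot of the two classes.
#'
#' @param table labelled feature tibble.
#' @param variables covariates to test; default all.
#' @param exact_max use the exact null distribution when both classes have
#'   at most this many values (and no ties).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (raw p-values are reported).
#' @return A tibble: `variable`, `n_invasive`, `n_native`,
#'   `median_invasive`, `median_native`, `statistic` (Mann-Whitney U of the
#'   invasive sample), `p_value`.
#' @export
class_contrast <- function(table, variables = NULL, exact_max = 20,
                           p_adjust = "none") {
  table <- label_classes(table)
  variables <- variables %||% feature_variables(table)
  out <- purrr::map_dfr(variables, function(v) {
    xi <- table[[v]][table$role == "invasive"]
    xn <- table[[v]][table$role == "native"]
    xi <- xi[!is.na(xi)]; xn <- xn[!is.na(xn)]
    if (length(xi) == 0 || length(xn) == 0) {
      abort(sprintf("Variable '%s' has a class with no values.", v))
    }
    use_exact <- length(xi) <= exact_max && length(xn) <= exact_max &&
      !any(duplicated(c(xi, xn)))
    wt <- suppressWarnings(
      wilcox.test(xi, xn, paired = FALSE, alternative = "two.sided",
                  exact = use_exact, correct = FALSE)
    )
    tibble::tibble(variable = v, n_invasive = length(xi),
                   n_native = length(xn),
                   median_invasive = median(xi), median_native = median(xn),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
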