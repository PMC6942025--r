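#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict quantile median rnorm runif rpois wilcox.test
#' @importFrom utils head
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Deterministically derive a stage seed from a master seed and a stage tag.
# Kept below 2^31 so it is always a valid argument to set.seed().
derive_seed <- function(master, ...) {
  tags <- vapply(list(...), function(t) {
    if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else as.numeric(t)
  }, numeric(1))
  x <- as.numeric(master) %% 2147483629
  for (t in tags) x <- (x * 48271 + (as.numeric(t) %% 2147483629) * 7919 + 12345) %% 2147483629
  as.integer(x)
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Round half away from zero at `digits` decimals (report-table convention;
# base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (nonnegative && x < 0) abort(sprintf("`%s` must be non-negative.", name))
  invisible(x)
}
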