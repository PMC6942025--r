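test_that("confusion counts are exact and orientation-symmetric", {
  cm <- confusion_matrix(rep("invasive", 5), rep("invasive", 5))
  expect_equal(unlist(cm), c(tp = 5L, fp = 0L, fn = 0L, tn = 0L))

  # the reference hold-out matrix: 241/67/24/91
  obs <- c(rep("invasive", 308), rep("native", 115))
  pred <- c(rep("invasive", 241), rep("native", 67),
            rep("invasive", 24), rep("native", 91))
  cm2 <- confusion_matrix(obs, pred)
  expect_equal(unlist(cm2), c(tp = 241L, fp = 24L, fn = 67L, tn = 91L))
  swapped <- swap_orientation(cm2)
  expect_equal(unlist(swapped), c(tp = 91L, fp = 67L, fn = 24L, tn = 241L))
  expect_equal(swap_orientation(swapped), cm2)

  expect_error(confusion_matrix("invasive", c("native", "native")), "equal length")
  expect_error(confusion_matrix("invasive", "weeds"), "weeds")
})

test_that("class metrics match brute-force recounts on random label sets", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      n <- sample(1:40, 1)
      obs <- sample(c("invasive", "native"), n, replace = TRUE)
      pred <- sample(c("invasive", "native"), n, replace = TRUE)
      cm <- confusion_matrix(obs, pred)
      # brute force from raw pairs
      expect_identical(cm$tp, sum(obs == "invasive" & pred == "invasive"))
      expect_identical(cm$tn, sum(obs == "native" & pred == "native"))
      m <- class_metrics(cm)
      inv <- m[m$class == "invasive", ]
      if (!inv$undefined) {
        p <- cm$tp / (cm$tp + cm$fp); r <- cm$tp / (cm$tp + cm$fn)
        expect_equal(inv$f1, 2 * p * r / (p + r))
        expect_gte(inv$f1, min(p, r) - 1e-12)
        expect_lte(inv$f1, max(p, r) + 1e-12)
      }
      # orientation symmetry: swapped-matrix invasive metrics = native metrics
      m_swap <- class_metrics(swap_orientation(cm))
      expect_equal(m_swap[m_swap$class == "invasive", -1],
                   m[m$class == "native", -1])
    }
  })
})

test_that("zero denominators are undefined, never zero or an error", {
  cm <- as_confusion_matrix(tp = 0, fp = 0, fn = 3, tn = 5)
  m <- class_metrics(cm)
  inv <- m[m$class == "invasive", ]
  expect_true(is.na(inv$precision))
  expect_true(inv$undefined)
  expect_equal(m[m$class == "native", ]$recall, 1)
})

test_that("weighted metrics equal the class-size-weighted mean exactly", {
  cm <- as_confusion_matrix(tp = 241, fp = 24, fn = 67, tn = 91)
  m <- class_metrics(cm)
  w <- weighted_metrics(m)
  # independent arithmetic
  inv <- m[m$class == "invasive", ]; nat <- m[m$class == "native", ]
  expect_identical(w$f1, (inv$f1 * 308 + nat$f1 * 115) / 423)
  expect_identical(w$precision, (inv$precision * 308 + nat$precision * 115) / 423)
  expect_true(w$f1 >= min(inv$f1, nat$f1) && w$f1 <= max(inv$f1, nat$f1))

  # equal class values give back that value regardless of n
  eq <- tibble::tibble(class = c("invasive", "native"),
                       precision = 0.4, recall = 0.6, f1 = 0.48,
                       n = c(17L, 400L), undefined = FALSE)
  expect_equal(weighted_metrics(eq)$f1, 0.48)

  # the explicit f1 pair from the hold-out evaluation
  pair <- tibble::tibble(class = c("invasive", "native"),
                         precision = c(0.9094, 0.5759),
                         recall = c(0.78, 0.79),
                         f1 = c(0.8411, 0.6666),
                         n = c(308L, 115L), undefined = FALSE)
  wp <- weighted_metrics(pair)
  expect_equal(round(wp$f1, 2), 0.79)
  expect_equal(round(wp$precision, 2), 0.82)

  zero <- dplyr::mutate(eq, n = 0L)
  expect_error(weighted_metrics(zero), "Zero total")
})

test_that("probability summaries use interpolated quartiles and clean bins", {
  s <- probability_summary(c(0.1, 0.5, 0.9))
  expect_equal(s$median, 0.5)
  s2 <- probability_summary(rep(0.37, 12))
  expect_equal(c(s2$q1, s2$median, s2$q3), rep(0.37, 3))
  expect_equal(sum(s2$histogram$count), 12)

  # quantiles agree with a sort-based oracle on random samples
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(3:200, 1))
      s3 <- probability_summary(p)
      sp <- sort(p); n <- length(sp)
      oracle <- function(q) {
        h <- (n - 1) * q + 1
        lo <- floor(h); hi <- ceiling(h)
        sp[lo] + (h - lo) * (sp[hi] - sp[lo])
      }
      expect_equal(s3$median, oracle(0.5))
      expect_equal(s3$q1, oracle(0.25))
      expect_equal(s3$q3, oracle(0.75))
      expect_true(s3$q1 <= s3$median && s3$median <= s3$q3)
      expect_equal(sum(s3$histogram$count), n)
    }
  })
  expect_error(probability_summary(numeric(0)), "No rows")
})

test_that("class contrasts reproduce the exact Mann-Whitney distribution", {
  mk_tab <- function(xi, xn) {
    tibble::tibble(species = rep(c("i", "n"), c(length(xi), length(xn))),
                   role = rep(c("invasive", "native"), c(length(xi), length(xn))),
                   year = 2011L, x = 0, y = 0, v = c(xi, xn))
  }
  # identical samples: p exactly 1
  tab <- mk_tab(c(1, 2, 3), c(1, 2, 3))
  expect_equal(class_contrast(tab)$p_value, 1)

  # exact-distribution oracle (complete enumeration) on tie-free samples
  withr::with_seed(3, {
    for (i in 1:15) {
      xi <- rnorm(sample(3:6, 1))
      xn <- rnorm(sample(3:7, 1), mean = runif(1, -1, 1))
      got <- class_contrast(mk_tab(xi, xn))
      expect_equal(got$p_value, exact_mw_pvalue(xi, xn), tolerance = 1e-12)
      expect_equal(got$statistic, sum(outer(xi, xn, ">")))
    }
  })

  # complete separation at n = 20 per group is overwhelming evidence
  sep <- class_contrast(mk_tab(1:20, 101:120))
  expect_lt(sep$p_value, 1e-6)

  # a class with no values is an input error
  bad <- mk_tab(numeric(0), 1:3)
  expect_error(class_contrast(bad), "no values")

  # optional multiplicity correction is available but off by default
  tab2 <- dplyr::mutate(mk_tab(rnorm(10), rnorm(10, 2)), v2 = v)
  raw <- class_contrast(tab2)
  bonf <- class_contrast(tab2, p_adjust = "bonferroni")
  expect_equal(bonf$p_value, pmin(raw$p_value * 2, 1))
})
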